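test_that("session files carry the semantic hierarchy", {
  f <- tmp_h5()
  s <- create_session_file(f)
  for (p in c("/data/internal", "/data/external", "/descriptors/static",
              "/descriptors/dynamic"))
    expect_true(neurofmt:::h5_object_exists(f, p))
  expect_true(verify_compliance(s)$compliant)
  expect_identical(wrap_managed_object(f)$managed_type, "BrainDataFile")
  expect_error(create_session_file(f), "exists")

  neurofmt:::h5_delete(f, "/descriptors")
  expect_false(verify_compliance(wrap_managed_object(f))$compliant)
})

test_that("ephys creation stores scales, units, and auto relationships", {
  f <- tmp_h5()
  create_session_file(f)
  e <- create_ephys(wrap_managed_object(f, "/data/internal"), "dev0",
                    raw = matrix(rnorm(400), 4, 100),
                    sampling_rate = 12200, electrode_ids = 0:3,
                    anatomy = list(name = rep("A1", 4), id = rep(1L, 4)))
  # time scale generated from the sampling rate: t_k = 1000 k / 12200
  tv <- ephys_aux(e, "time")$data
  expect_length(tv, 100)
  expect_equal(tv[1:3], 1000 * (0:2) / 12200, tolerance = 1e-12)
  expect_true(all(diff(tv) > 0))
  expect_identical(ephys_aux(e, "sampling_rate"), 12200)
  expect_identical(ephys_aux(e, "unit"), "Volt")
  expect_error(ephys_aux(e, "nonexistent"), "unknown auxiliary key")

  expect_identical(dim(read_ephys(e)), c(4L, 100L))
  sub <- read_ephys(e, selection(sel_indices(c(0, 2)), sel_range(0, 10)))
  expect_identical(dim(sub), c(2L, 10L))

  # every built-in scale carries an order relationship to the data
  for (sc in names(get_dimension_scales(e))) {
    rels <- find_relationships(
      wrap_managed_object(f, paste0(e$path, "/", sc)),
      paste0(e$path, "/raw_data"))
    expect_length(rels, 1)
    expect_identical(rels[[1]]$spec$relationship_type, "order")
  }

  expect_error(create_ephys(wrap_managed_object(f, "/data/internal"),
                            "dev_bad", raw = matrix(0, 4, 10),
                            sampling_rate = 1000, electrode_ids = 0:1),
               "electrode_ids")
  expect_error(create_ephys(wrap_managed_object(f, "/data/internal"),
                            "dev_bad", raw = matrix(0, 2, 10),
                            sampling_rate = -5, electrode_ids = 0:1),
               "sampling_rate")
})

test_that("auto-expand grows data and every time-axis scale consistently", {
  f <- tmp_h5()
  create_session_file(f)
  e <- create_ephys(wrap_managed_object(f, "/data/internal"), "acq",
                    sampling_rate = 1000, electrode_ids = 0:2,
                    auto_expand = TRUE)
  expect_true(verify_compliance(e)$compliant)   # zero appends, extent 0
  expect_identical(neurofmt:::h5_dataset_dims(f, paste0(e$path, "/raw_data")),
                   c(3, 0))

  set.seed(1)
  b1 <- matrix(rnorm(30), 3, 10)
  b2 <- matrix(rnorm(15), 3, 5)
  append_recordings(e, b1)
  append_recordings(e, b2)
  expect_identical(unname(neurofmt:::h5_dataset_dims(
    f, paste0(e$path, "/raw_data"))), c(3, 15))
  got <- read_ephys(e)
  expect_equal(got, cbind(b1, b2))
  tv <- ephys_aux(e, "time")$data
  expect_length(tv, 15)
  expect_equal(tv, 1000 * (0:14) / 1000)
  expect_true(all(diff(tv) > 0))
  expect_true(verify_compliance(e)$compliant)

  # appending an empty block leaves the extent unchanged
  append_recordings(e, matrix(numeric(), 3, 0))
  expect_identical(unname(neurofmt:::h5_dataset_dims(
    f, paste0(e$path, "/raw_data")))[2], 15)

  # space mismatch and non-expandable groups are refused
  expect_error(append_recordings(e, matrix(0, 2, 5)), "space extent")
  fixed <- create_ephys(wrap_managed_object(f, "/data/internal"), "fixed",
                        raw = matrix(0, 2, 4), sampling_rate = 1000,
                        electrode_ids = 0:1)
  expect_error(append_recordings(fixed, matrix(0, 2, 4)), "auto-expand")
})

test_that("custom dimension scales are stored, retrieved, and extended", {
  f <- tmp_h5()
  create_session_file(f)
  e <- create_ephys(wrap_managed_object(f, "/data/internal"), "dev0",
                    raw = matrix(0, 3, 10), sampling_rate = 1000,
                    electrode_ids = 0:2)
  rec <- add_dimension_scale(e, 0, "anatomy_name", "name",
                             c("A1", "A1", "A2"), "region per electrode")
  expect_identical(rec$axis, 0L)
  ax0 <- get_dimension_scales(e, axis = 0)
  expect_setequal(names(ax0), c("electrode_id", "anatomy_name"))
  expect_identical(ax0$anatomy_name$unit, "name")
  expect_identical(ax0$anatomy_name$data, c("A1", "A1", "A2"))
  # built-ins only on the untouched axis
  expect_identical(names(get_dimension_scales(e, axis = 1)), "time")
  expect_true(verify_compliance(e)$compliant)

  expect_error(add_dimension_scale(e, 0, "bad", "u", 1:2), "extent")
  expect_error(add_dimension_scale(e, 0, "anatomy_name", "u", 1:3),
               "already exists")

  # custom time-axis scales must be supplied on append
  e2 <- create_ephys(wrap_managed_object(f, "/data/internal"), "acq",
                     sampling_rate = 1000, electrode_ids = 0:1,
                     auto_expand = TRUE)
  add_dimension_scale(e2, 1, "trial", "id", integer(), "trial index")
  expect_error(append_recordings(e2, matrix(0, 2, 3)), "trial")
  append_recordings(e2, matrix(0, 2, 3),
                    scales = list(trial = c(0L, 0L, 1L)))
  expect_identical(length(ephys_aux(e2, "trial")$data), 3L)
  expect_true(verify_compliance(e2)$compliant)
})

test_that("processed groups link back to their raw recording", {
  f <- tmp_h5()
  create_session_file(f)
  internal <- wrap_managed_object(f, "/data/internal")
  raw <- create_ephys(internal, "dev0", raw = matrix(rnorm(200), 2, 100),
                      sampling_rate = 1000, electrode_ids = 0:1)
  proc <- create_processed_ephys(internal, "dev0",
                                 data = array(rnorm(2 * 50 * 3),
                                              c(2, 50, 3)),
                                 sampling_rate = 500,
                                 electrode_ids = 0:1,
                                 band = c(25, 50, 75), raw = raw)
  expect_identical(proc$managed_type, "BrainDataEphysProcessed")
  expect_true(verify_compliance(proc)$compliant)
  expect_identical(names(get_dimension_scales(proc, axis = 2)), "band")

  rels <- find_relationships(
    wrap_managed_object(f, paste0(proc$path, "/time")),
    paste0(raw$path, "/time"))
  expect_length(rels, 1)
  expect_identical(rels[[1]]$spec$relationship_type,
                   "shared_ascending_encoding")

  # the time alignment maps processed samples onto matching raw samples:
  # processed at 500 Hz covers every second raw sample at 1000 Hz
  m <- map_selection(rels[[1]], selection(sel_range(0, 5)))
  idx <- selection_indices(m, 100)
  expect_identical(idx, c(0, 1, 2, 3, 4, 5, 6, 7, 8))  # 0..8 ms window

  expect_error(create_processed_ephys(internal, "flat",
                                      data = matrix(0, 2, 10),
                                      sampling_rate = 500,
                                      electrode_ids = 0:1, band = 1),
               "rank-3")
  expect_error(create_processed_ephys(internal, "bands",
                                      data = array(0, c(2, 10, 3)),
                                      sampling_rate = 500,
                                      electrode_ids = 0:1, band = c(1, 2)),
               "band scale")
})
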