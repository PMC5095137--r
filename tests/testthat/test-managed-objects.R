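test_that("registration enforces uniqueness, bases, and spec validity", {
  reg <- neurofmt:::new_registry()
  register_managed_type("T1", function() group_spec(group = "t1"),
                        registry = reg)
  expect_error(register_managed_type("T1", function() group_spec(group = "z"),
                                     registry = reg), "already registered")
  expect_error(register_managed_type("T2", function() group_spec(),
                                     registry = reg), "invalid spec")
  expect_error(register_managed_type("T3", function() group_spec(group = "t3"),
                                     base = "NoSuch", registry = reg),
               "not registered")

  # derived spec of the built-in processed type carries the base's
  # auxiliary structure (sampling_rate, electrode_id, time)
  base <- neurofmt:::registry_spec(default_registry(), "BrainDataEphys")
  derived <- neurofmt:::registry_spec(default_registry(),
                                      "BrainDataEphysProcessed")
  for (nm in c("sampling_rate", "electrode_id", "time"))
    expect_true(nm %in% names(derived$datasets))
  expect_true(neurofmt:::registry_is_subtype(
    default_registry(), "BrainDataEphysProcessed", "BrainDataEphys"))
})

test_that("created objects are compliant, atomic on failure, and wrappable", {
  f <- tmp_h5()
  s <- create_session_file(f)
  internal <- wrap_managed_object(f, "/data/internal")
  e <- create_ephys(internal, "dev0", raw = matrix(rnorm(400), 4, 100),
                    sampling_rate = 12200, electrode_ids = 0:3)
  expect_true(verify_compliance(e)$compliant)
  expect_identical(e$managed_type, "BrainDataEphys")

  # sibling collision leaves the file unchanged
  before <- neurofmt:::h5_ls(f, "/data/internal")
  expect_error(create_ephys(internal, "dev0",
                            raw = matrix(0, 2, 2), sampling_rate = 1,
                            electrode_ids = 0:1), "collision")
  expect_identical(neurofmt:::h5_ls(f, "/data/internal"), before)

  # populate failure rolls the object back atomically
  expect_error(create_ephys(internal, "bad", raw = matrix(0, 2, 5),
                            sampling_rate = 1000, electrode_ids = 0:4),
               "electrode_ids")
  expect_false(neurofmt:::h5_link_exists(f, "/data/internal/ephys_data_bad"))

  # create-then-wrap yields identical descriptors
  w <- wrap_managed_object(f, e$path)
  expect_identical(w$descriptors, e$descriptors)

  # plain user group wraps as unmanaged; unknown stored type warns
  neurofmt:::h5_create_group(f, "/data/internal/usergrp")
  u <- wrap_managed_object(f, "/data/internal/usergrp")
  expect_true(u$unmanaged)
  neurofmt:::h5_write_attr(f, "/data/internal/usergrp", "MANAGED_TYPE",
                           "NotRegistered")
  expect_warning(wrap_managed_object(f, "/data/internal/usergrp"),
                 "unregistered")
})

test_that("verification is minimal and flags injected damage", {
  f <- tmp_h5()
  s <- create_session_file(f)
  e <- create_ephys(wrap_managed_object(f, "/data/internal"), "dev0",
                    raw = matrix(rnorm(100), 2, 50), sampling_rate = 1000,
                    electrode_ids = 0:1)
  expect_true(verify_compliance(s)$compliant)

  # extras never break compliance
  neurofmt:::h5_write_dataset(f, paste0(e$path, "/custom_extra"), 1:5)
  neurofmt:::h5_create_group(f, "/scratch_area/deep")
  expect_true(verify_compliance(wrap_managed_object(f, "/"))$compliant)

  # a missing required dataset is found at its path
  neurofmt:::h5_delete(f, paste0(e$path, "/raw_data"))
  rep <- verify_compliance(wrap_managed_object(f, e$path))
  expect_false(rep$compliant)
  expect_true(any(rep$findings$rule == "required-dataset" &
                    rep$findings$path == paste0(e$path, "/raw_data")))

  # verification without any resolvable spec is an error, not a report
  g <- tmp_h5()
  neurofmt:::h5_create_file(g)
  neurofmt:::h5_create_group(g, "/plain")
  expect_error(verify_compliance(g, path = "/plain"), "no resolvable")
})

test_that("discovery filters by type with subtype semantics", {
  f <- tmp_h5()
  s <- make_session(f)
  eph <- find_managed_objects(s, "BrainDataEphys", exact = TRUE)
  expect_length(eph, 2)
  both <- find_managed_objects(s, "BrainDataEphys")
  expect_length(both, 4)   # raw + processed per device
  # oracle: exhaustive walk over the type attribute
  walk_types <- function(path) {
    out <- character()
    for (ch in neurofmt:::h5_ls(f, path)) {
      p <- neurofmt:::h5_path_join(path, ch)
      if (neurofmt:::h5_obj_kind(f, p) != "group") next
      if (neurofmt:::h5_attr_exists(f, p, "MANAGED_TYPE") &&
          neurofmt:::h5_read_attr(f, p, "MANAGED_TYPE") %in%
            c("BrainDataEphys", "BrainDataEphysProcessed"))
        out <- c(out, p)
      out <- c(out, walk_types(p))
    }
    out
  }
  expect_setequal(vapply(both, function(h) h$path, character(1)),
                  walk_types("/"))

  # non-recursive search from root sees only top-level managed children
  top <- find_managed_objects(s, recursive = FALSE)
  expect_setequal(vapply(top, function(h) h$path, character(1)), character())

  empty <- create_session_file(tmp_h5())
  expect_length(find_managed_objects(empty, "BrainDataEphys"), 0)
})

test_that("external storage is transparent and broken links are detected", {
  fx <- make_session_with_external()
  found <- find_managed_objects(fx$main, "BrainDataEphys")
  expect_length(found, 1)
  expect_identical(found[[1]]$path, "/data/internal/ephys_data_dev_ext")
  expect_true(verify_compliance(found[[1]])$compliant)
  # the external container file is independently verifiable
  expect_true(verify_compliance(fx$ext)$compliant)

  # identical payload internal vs external: identical reports
  f2 <- tmp_h5()
  create_session_file(f2)
  set.seed(99)
  internal_twin <- create_ephys(wrap_managed_object(f2, "/data/internal"),
                                "dev_ext", raw = matrix(rnorm(60), 3, 20),
                                sampling_rate = 1000, electrode_ids = 0:2)
  rep_int <- verify_compliance(internal_twin)
  rep_ext <- verify_compliance(found[[1]])
  expect_identical(rep_int$findings$rule, rep_ext$findings$rule)
  expect_identical(rep_int$compliant, rep_ext$compliant)

  unlink(fx$ext)
  rep <- verify_compliance(fx$main)
  expect_false(rep$compliant)
  expect_true(any(rep$findings$rule == "broken-link"))
})

test_that("multi-file containers number entries densely in order", {
  dir <- tempfile(); dir.create(dir)
  members <- character(3)
  for (i in 1:3) {
    members[i] <- file.path(dir, sprintf("s%d.h5", i))
    create_session_file(members[i])
  }
  cont <- create_multifile_container(file.path(dir, "all.h5"))
  expect_true(verify_compliance(cont)$compliant)   # empty container
  for (i in 1:3)
    expect_identical(add_container_entry(cont, members[i]),
                     paste0("entry_", i - 1))
  # each entry resolves to the member's root
  h <- wrap_managed_object(cont$file, "/entry_1")
  expect_identical(h$managed_type, "BrainDataFile")
  expect_error(add_container_entry(cont, tempfile()), "not a managed")
})
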