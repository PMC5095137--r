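rel_fixture <- function() {
  f <- tmp_h5()
  neurofmt:::h5_create_file(f)
  neurofmt:::h5_write_dataset(f, "/src", as.double(0:9))
  neurofmt:::h5_write_dataset(f, "/tgt", as.double(0:9))
  f
}

test_that("relationship attributes store, list, and round-trip", {
  f <- rel_fixture()
  src <- wrap_managed_object(f, "/src")
  r <- create_relationship_attribute(src, "same_order", "order", "/tgt",
                                     source_axes = 0L, target_axes = 0L,
                                     description = "matched ordering")
  expect_true(neurofmt:::h5_attr_exists(f, "/src",
                                        "RELATIONSHIP_ATTR_same_order"))
  r2 <- get_relationship(src, "same_order")
  expect_spec_equal(r2$spec, r$spec)

  expect_error(create_relationship_attribute(src, "same_order", "order",
                                             "/tgt"), "already exists")
  expect_error(create_relationship_attribute(src, "x", "ordered", "/tgt"),
               "relationship_type")
  expect_error(create_relationship_attribute(src, "gone", "order",
                                             "/nowhere"), "does not resolve")
  rd <- create_relationship_attribute(src, "gone", "order", "/nowhere",
                                      allow_dangling = TRUE)
  expect_s3_class(rd, "neurofmt_relationship")

  # plain attributes are not listed as relationships
  neurofmt:::h5_write_attr(f, "/src", "plain", "x")
  neurofmt:::h5_write_attr(f, "/src", "unit", "ms")
  rels <- list_relationship_attributes(src)
  expect_length(rels, 2)

  expect_length(find_relationships(src, "/tgt"), 1)
  expect_length(find_relationships(src, "/src"), 0)
})

test_that("mapping follows the per-type rules on the worked examples", {
  f <- tmp_h5()
  neurofmt:::h5_create_file(f)
  neurofmt:::h5_write_dataset(f, "/ord_src", as.double(1:10))
  neurofmt:::h5_write_dataset(f, "/ord_tgt", as.double(1:10))
  neurofmt:::h5_write_dataset(f, "/imap", c(7L, 3L, 5L))
  neurofmt:::h5_write_dataset(f, "/ivals", as.double(100:109))
  neurofmt:::h5_write_dataset(f, "/stok", c("baa", "gaa", "baa"))
  neurofmt:::h5_write_dataset(f, "/ttok", c("gaa", "baa", "baa"))
  neurofmt:::h5_write_dataset(f, "/stime", c(0, 10, 20, 30))
  neurofmt:::h5_write_dataset(f, "/ttime", c(0, 5, 10, 15, 20, 25, 30))

  ord <- create_relationship_attribute(wrap_managed_object(f, "/ord_src"),
                                       "r", "order", "/ord_tgt")
  m <- map_selection(ord, selection(sel_range(1, 4)))
  expect_identical(m$selectors[[1]]$kind, "range")
  expect_identical(selection_indices(m, 10), c(1, 2, 3))

  idx <- create_relationship_attribute(wrap_managed_object(f, "/imap"),
                                       "r", "indexes", "/ivals")
  m <- map_selection(idx, selection(sel_indices(c(0, 2))))
  expect_identical(selection_indices(m, 10), c(5, 7))
  expect_identical(select_through(idx, selection(sel_indices(c(0, 2)))),
                   c(105, 107))
  expect_identical(select_through(idx, selection(sel_indices(numeric()))),
                   numeric(0))

  enc <- create_relationship_attribute(wrap_managed_object(f, "/stok"),
                                       "r", "shared_encoding", "/ttok")
  expect_identical(selection_indices(map_selection(
    enc, selection(sel_point(0))), 3), c(1, 2))

  asc <- create_relationship_attribute(wrap_managed_object(f, "/stime"),
                                       "r", "shared_ascending_encoding",
                                       "/ttime")
  m <- map_selection(asc, selection(sel_range(1, 3)))
  expect_identical(m$selectors[[1]]$kind, "range")
  expect_identical(m$selectors[[1]]$start, 2)
  expect_identical(m$selectors[[1]]$stop, 5)
  # point selections fall back to exact value matching
  expect_identical(selection_indices(map_selection(
    asc, selection(sel_point(1))), 7), 2)

  usr <- create_relationship_attribute(wrap_managed_object(f, "/stime"),
                                       "u", "user", "/ttime",
                                       properties = list(why = "custom"))
  expect_error(map_selection(usr, selection(sel_point(0))), "no implied")

  # zero value-match hits give an empty selection, not an error
  neurofmt:::h5_write_dataset(f, "/lonely", "zzz")
  lone <- create_relationship_attribute(wrap_managed_object(f, "/lonely"),
                                        "r", "shared_encoding", "/ttok")
  expect_length(selection_indices(map_selection(
    lone, selection(sel_point(0))), 3), 0)

  # out-of-bounds source selection
  expect_error(map_selection(ord, selection(sel_point(99))), "bounds")
})

test_that("order relationships on groups use alphabetic member order", {
  f <- tmp_h5()
  neurofmt:::h5_create_file(f)
  neurofmt:::h5_create_group(f, "/sg/bb")
  neurofmt:::h5_create_group(f, "/sg/aa")
  neurofmt:::h5_create_group(f, "/sg/cc")
  neurofmt:::h5_create_group(f, "/tg/z1")
  neurofmt:::h5_create_group(f, "/tg/z2")
  neurofmt:::h5_create_group(f, "/tg/z3")
  r <- create_relationship_attribute(wrap_managed_object(f, "/sg"),
                                     "g", "order", "/tg")
  m <- map_selection(r, selection(sel_members(c("aa", "cc"))))
  expect_identical(m$selectors[[1]]$members, c("z1", "z3"))
  expect_identical(select_through(r, selection(sel_indices(c(1)))), "z2")
})

test_that("map_selection agrees with brute-force oracles on random cases", {
  set.seed(202)
  f <- tmp_h5()
  neurofmt:::h5_create_file(f)
  types <- c("order", "equivalent", "indexes", "shared_encoding",
             "shared_ascending_encoding", "indexes_values")
  for (type in types) {
    for (case in 1:6) {
      n_s <- sample(2:50, 1)
      n_t <- if (type %in% c("order", "equivalent")) n_s else sample(2:50, 1)
      if (type == "indexes") {
        svals <- sample(0:(n_t - 1), n_s, replace = TRUE)
      } else if (type == "shared_ascending_encoding") {
        svals <- sort(sample(0:99, n_s))
      } else {
        svals <- sample(0:12, n_s, replace = TRUE)
      }
      tvals <- if (type == "shared_ascending_encoding")
        sort(sample(0:99, n_t)) else sample(0:12, n_t, replace = TRUE)
      sp <- sprintf("/%s_s%d", type, case)
      tp <- sprintf("/%s_t%d", type, case)
      neurofmt:::h5_write_dataset(f, sp, as.double(svals))
      neurofmt:::h5_write_dataset(f, tp, as.double(tvals))
      rel <- create_relationship_attribute(wrap_managed_object(f, sp),
                                           "r", type, tp)
      for (trial in 1:25) {
        rs <- random_selection_1d(n_s)
        want <- tryCatch(oracle_map(type, svals, tvals, rs$idx0, rs$ranged),
                         error = function(e) "error")
        if (identical(want, "error")) {
          expect_error(map_selection(rel, rs$sel))
        } else {
          got <- mapped_indices(map_selection(rel, rs$sel), n_t)
          expect_identical(got, as.double(want))
        }
      }
    }
  }
})

test_that("descriptors survive close/reopen bit-identically as documents", {
  f <- rel_fixture()
  r <- create_relationship_attribute(wrap_managed_object(f, "/src"),
                                     "keep", "indexes_values", "/tgt",
                                     source_axes = 0L, target_axes = 0L,
                                     properties = list(a = 1, b = "x"))
  json_before <- neurofmt:::h5_read_attr(f, "/src",
                                         "RELATIONSHIP_ATTR_keep")
  r2 <- get_relationship(wrap_managed_object(f, "/src"), "keep")
  expect_identical(neurofmt:::h5_read_attr(f, "/src",
                                           "RELATIONSHIP_ATTR_keep"),
                   json_before)
  expect_spec_equal(r2$spec, r$spec)
})

test_that("index map relationships create the reserved chain and map blocks", {
  fx <- make_image_fixture(rows = 8, cols = 6, factor = 3)
  f <- fx$path
  # without a user leg: exactly 3 relationship attributes
  attrs_a <- neurofmt:::h5_ls_attrs(f, "/A")
  attrs_m <- neurofmt:::h5_ls_attrs(f, "/M")
  rel_a <- attrs_a[startsWith(attrs_a, "RELATIONSHIP_ATTR_")]
  rel_m <- attrs_m[startsWith(attrs_m, "RELATIONSHIP_ATTR_")]
  expect_length(c(rel_a, rel_m), 3)
  expect_true(any(endsWith(rel_a, "_IMR_SOURCE_TO_MAP")))
  expect_setequal(substring(rel_m, nchar("RELATIONSHIP_ATTR_scaling") + 1),
                  c("_IMR_MAP_TO_SOURCE", "_IMR_MAP_TO_TARGET"))

  imr <- fx$imr
  ps <- imr_map(imr, "MAP_TO_TARGET", selection(sel_point(2), sel_point(4)))
  blk <- pointset_block(ps)
  expect_identical(unname(blk$side), c(3, 3))
  expect_true(blk$full)
  # fixture convention: source axis 0 -> target axis 1, factor 3
  expect_identical(unname(blk$bounds[, 1]), c(4 * 3, 4 * 3 + 2))  # rows
  expect_identical(unname(blk$bounds[, 2]), c(2 * 3, 2 * 3 + 2))  # cols

  # inverse order legs compose to the identity
  s <- selection(sel_range(1, 4), sel_indices(c(0, 5)))
  fwd <- imr_map(imr, "SOURCE_TO_MAP", s)
  back <- imr_map(imr, "MAP_TO_SOURCE", fwd)
  expect_identical(selection_indices(back, c(8, 6)),
                   selection_indices(
                     neurofmt:::canonical_result(
                       selection_indices(s, c(8, 6))), c(8, 6)))

  # user leg variant: 4 attributes, complete postfix set
  f2 <- tmp_h5()
  neurofmt:::h5_create_file(f2)
  neurofmt:::h5_write_dataset(f2, "/A", as.double(0:3))
  neurofmt:::h5_write_dataset(f2, "/M", as.integer(c(3, 2, 1, 0)))
  neurofmt:::h5_write_dataset(f2, "/B", as.double(0:3))
  imr2 <- create_index_map_relationship(
    wrap_managed_object(f2, "/A"), wrap_managed_object(f2, "/M"),
    wrap_managed_object(f2, "/B"), "rev",
    user_properties = list(note = "reversal"))
  expect_length(imr2$legs, 4)
  all_attrs <- c(neurofmt:::h5_ls_attrs(f2, "/A"),
                 neurofmt:::h5_ls_attrs(f2, "/M"))
  for (pf in neurofmt:::IMR_POSTFIXES)
    expect_true(any(endsWith(all_attrs, pf)))

  # identity map: SOURCE_TO_TARGET equals the identity
  f3 <- tmp_h5()
  neurofmt:::h5_create_file(f3)
  neurofmt:::h5_write_dataset(f3, "/A", as.double(0:5))
  neurofmt:::h5_write_dataset(f3, "/M", as.integer(0:5))
  neurofmt:::h5_write_dataset(f3, "/B", as.double(10:15))
  imr3 <- create_index_map_relationship(
    wrap_managed_object(f3, "/A"), wrap_managed_object(f3, "/M"),
    wrap_managed_object(f3, "/B"), "id")
  got <- imr_map(imr3, "SOURCE_TO_TARGET", selection(sel_indices(c(1, 4))))
  expect_identical(selection_indices(got, 6), c(1, 4))

  expect_error(imr_map(imr3, "NOPE", selection(sel_point(0))))
})

test_that("bundle discovery reports incomplete chains as findings", {
  fx <- make_image_fixture(rows = 5, cols = 4, factor = 2)
  b <- get_index_map_relationships(wrap_managed_object(fx$path, "/A"))
  expect_length(b, 1)
  expect_identical(b[[1]]$base_name, "scaling")
  expect_identical(nrow(attr(b, "findings")), 0L)

  # discovery from the map side, too
  bm <- get_index_map_relationships(wrap_managed_object(fx$path, "/M"))
  expect_length(bm, 1)

  mut <- inject_violation(fx$path, "drop_imr_leg")
  expect_identical(mut$rule, "incomplete-imr-bundle")
  b2 <- get_index_map_relationships(wrap_managed_object(fx$path, "/A"))
  expect_length(b2, 0)
  expect_identical(nrow(attr(b2, "findings")), 1L)

  # plain relationships only: no bundles
  f <- rel_fixture()
  create_relationship_attribute(wrap_managed_object(f, "/src"), "p",
                                "order", "/tgt")
  expect_length(get_index_map_relationships(wrap_managed_object(f, "/src")),
                0)
})
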