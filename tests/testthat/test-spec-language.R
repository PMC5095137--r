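test_that("builders produce valid documents and validation locates defects", {
  raw <- dataset_spec(dataset = "raw_data", optional = FALSE, primary = TRUE,
                      description = "Dataset with the Ephys recordings data")
  expect_identical(nrow(validate_spec_document(raw)), 0L)

  # name-XOR-prefix rule
  bad <- dataset_spec(dataset = NULL, prefix = NULL)
  rep <- validate_spec_document(bad)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$message, "exactly one of")

  # enum membership, error names the enum
  mis <- relationship_spec("r", "ordered", "/t")
  rep <- validate_spec_document(mis)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$message, "shared_ascending_encoding")

  # axis-shape agreement between source and target
  shp <- relationship_spec("r", "order", "/t", source_axes = c(0L, 1L),
                           target_axes = 0L)
  expect_gt(nrow(validate_spec_document(shp)), 0)

  # malformed input is a structural error, not a report
  expect_error(validate_spec_document(list(a = 1)), "kind")
})

test_that("incremental construction matches the worked ephys layout", {
  g <- group_spec(group = NULL, prefix = "ephys_data_",
                  description = "Managed group for storage of raw Ephys recordings.")
  raw <- dataset_spec(dataset = "raw_data", prefix = NULL, optional = FALSE,
                      primary = TRUE,
                      description = "Dataset with the Ephys recordings data")
  raw <- add_attribute(raw, attribute_spec(attribute = "unit", prefix = NULL,
                                           value = "Volt"))
  raw <- add_dimension(raw, dimension_spec(
    name = "space", unit = "id", dataset = "electrode_id", axis = 0,
    description = "Id of the recording electrode"))
  g <- add_dataset(g, raw, "ephys_data")
  expect_identical(nrow(validate_spec_document(g)), 0L)
  ds <- g$datasets$ephys_data
  expect_identical(ds$attributes[[1]]$value, "Volt")
  expect_identical(ds$dimensions[[1]]$dataset, "electrode_id")
  expect_identical(ds$dimensions[[1]]$axis, 0L)

  # collisions and kind errors
  expect_error(add_dataset(g, raw, "ephys_data"), "collision")
  expect_error(attach_child_spec(raw, group_spec(group = "g")), "cannot attach")
  expect_error(attach_child_spec(g, dimension_spec("t", "ms", "time", 1)),
               "cannot attach")
})

test_that("JSON serialization round-trips and carries the builder keys", {
  spec <- default_registry() |> (\(r) compile_recursive_spec("BrainDataEphys", r))()
  j <- spec_to_json(spec)
  expect_match(j, '"prefix":"ephys_data_"', fixed = TRUE)
  expect_spec_equal(spec_from_json(j), spec)

  # empty group round-trips to itself
  g <- group_spec(group = "empty")
  expect_spec_equal(spec_from_json(spec_to_json(g)), g)

  # pretty/compact chains parse to the same document
  d <- spec_from_json(spec_to_json(spec, pretty = TRUE))
  d2 <- spec_from_json(spec_to_json(d, pretty = FALSE))
  expect_spec_equal(d2, spec)

  expect_error(spec_from_json("{not json"), "parse")
})

test_that("recursive compilation inlines referenced types and flags cycles", {
  reg <- neurofmt:::new_registry()
  leaf <- function() {
    g <- group_spec(group = "leafgrp")
    add_dataset(g, dataset_spec(dataset = "payload"))
  }
  register_managed_type("Leaf", leaf, registry = reg)
  register_managed_type("Outer", function() {
    attach_child_spec(group_spec(group = "outer"), managed_ref("Leaf"),
                      "child")
  }, registry = reg)

  compiled <- compile_recursive_spec("Outer", reg)
  expect_identical(nrow(validate_spec_document(compiled)), 0L)
  expect_length(compiled$managed, 0)
  emb <- compiled$groups$child
  expect_identical(emb$managed_type, "Leaf")
  expect_identical(names(emb$datasets), "payload")

  # leaf type: recursive compile equals its basic spec
  expect_spec_equal(compile_recursive_spec("Leaf", reg),
                    neurofmt:::registry_spec(reg, "Leaf"))

  # basic spec strictly smaller than the recursive root spec
  basic <- neurofmt:::registry_spec(reg, "Outer")
  expect_lt(nchar(spec_to_json(basic)), nchar(spec_to_json(compiled)))

  # unknown ref
  register_managed_type("Dangling", function() {
    attach_child_spec(group_spec(group = "d"), managed_ref("Nowhere"), "x")
  }, registry = reg)
  expect_error(compile_recursive_spec("Dangling", reg), "Nowhere")

  # cycle X -> Y -> X reported with its path
  register_managed_type("X", function() {
    attach_child_spec(group_spec(group = "x"), managed_ref("Y"), "y")
  }, registry = reg)
  register_managed_type("Y", function() {
    attach_child_spec(group_spec(group = "y"), managed_ref("X"), "x")
  }, registry = reg)
  expect_error(compile_recursive_spec("X", reg), "X -> Y -> X")
})

test_that("format documents cover the registry and tolerate cycles", {
  reg <- neurofmt:::new_registry()
  register_managed_type("A", function() group_spec(group = "a"),
                        registry = reg)
  register_managed_type("B", function() {
    attach_child_spec(group_spec(group = "b"), managed_ref("A"), "a")
  }, registry = reg)
  doc <- compile_format_document(reg, format_name = "demo")
  expect_identical(names(doc$types), c("A", "B"))
  expect_identical(nrow(validate_spec_document(doc)), 0L)
  expect_true(jsonlite::validate(spec_to_json(doc)))

  # idempotent entry count; empty registry gives an empty valid document
  expect_length(compile_format_document(reg)$types, 2)
  empty <- compile_format_document(neurofmt:::new_registry())
  expect_length(empty$types, 0)
  expect_true(jsonlite::validate(spec_to_json(empty)))

  # built-in registry document has one entry per registered type
  full <- compile_format_document()
  expect_setequal(names(full$types), neurofmt:::registry_types(default_registry()))
})

test_that("round-trip identity holds on random meta-valid documents", {
  set.seed(11)
  for (i in 1:60) {
    doc <- random_spec_doc()
    expect_identical(nrow(validate_spec_document(doc)), 0L)
    expect_spec_equal(spec_from_json(spec_to_json(doc, pretty = i %% 2 == 0)),
                      doc)
  }
})
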