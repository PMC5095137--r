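#' Electrophysiology application format
#'
#' Managed types for neurophysiology sessions: `BrainDataFile` (session
#' files with a data/descriptors hierarchy), `BrainDataEphys` (raw
#' multi-electrode voltage recordings, a 2-D space x time array in Volts
#' with electrode-id and time dimension scales), `BrainDataEphysProcessed`
#' (derived space x time x band arrays), `BrainDataCollection` (device
#' collections), `BrainDataMultiFile` (multi-session containers), and
#' `ManagedObjectContainer` (the generic external-storage container).
#'
#' Time scales are in milliseconds and generated from the sampling rate
#' when not supplied: `t_k = start_time + 1000 * k / rate`. In
#' auto-expand acquisition mode the time axis starts empty and grows with
#' each appended block, keeping every time-axis scale consistent.
#'
#' @name ephys-format
NULL

EPHYS_PREFIX <- "ephys_data_"
EPHYS_PROCESSED_PREFIX <- "ephys_processed_"
COLLECTION_PREFIX <- "collection_"
ATTR_AUTO_EXPAND <- "AUTO_EXPAND"

# scale <-> data order relationships created automatically at population
SCALE_REL_NAME <- "describes_primary_data"

ephys_scale_dims <- function(primary) {
  list(
    space = dimension_spec("space", "id", "electrode_id", 0L,
                           description = "Id of the recording electrode"),
    time = dimension_spec("time", "ms", "time", 1L,
                          description = "Sample time in milliseconds"),
    anatomy_name = dimension_spec("anatomy_name", "name", "anatomy_name", 0L,
                                  optional = TRUE,
                                  description = "Anatomical region name per electrode"),
    anatomy_id = dimension_spec("anatomy_id", "id", "anatomy_id", 0L,
                                optional = TRUE,
                                description = "Anatomical region id per electrode"))
}

scale_dataset_spec <- function(name, primary, optional = FALSE,
                               description = "") {
  ds <- dataset_spec(dataset = name, optional = optional,
                     description = description)
  attach_child_spec(ds, relationship_spec(
    SCALE_REL_NAME, "order", primary, source_axes = 0L, target_axes = NULL,
    description = "scale elements are ordered like the described axis"))
}

spec_brain_data_ephys <- function() {
  g <- group_spec(prefix = EPHYS_PREFIX,
                  description = "Managed group for storage of raw Ephys recordings.")
  raw <- dataset_spec(dataset = "raw_data", optional = FALSE, primary = TRUE,
                      description = "Dataset with the Ephys recordings data")
  raw <- add_attribute(raw, attribute_spec(attribute = "unit", value = "Volt"))
  for (d in ephys_scale_dims("raw_data")) raw <- add_dimension(raw, d)
  g <- add_dataset(g, raw, "raw_data")
  sr <- dataset_spec(dataset = "sampling_rate",
                     description = "Sampling rate of the recording")
  sr <- add_attribute(sr, attribute_spec(attribute = "unit", value = "Hz"))
  g <- add_dataset(g, sr, "sampling_rate")
  g <- add_dataset(g, scale_dataset_spec(
    "electrode_id", "raw_data",
    description = "Identifier of each recording electrode"), "electrode_id")
  g <- add_dataset(g, scale_dataset_spec(
    "time", "raw_data",
    description = "Sample times in milliseconds"), "time")
  g
}

spec_brain_data_ephys_processed <- function() {
  # extends BrainDataEphys: same auxiliary structure, but the primary
  # dataset is the rank-3 space x time x band array 'data'
  g <- group_spec(prefix = EPHYS_PROCESSED_PREFIX,
                  description = "Managed group for processed Ephys data (space x time x band).")
  d <- dataset_spec(dataset = "data", optional = FALSE, primary = TRUE,
                    description = "Processed voltage data, space x time x band")
  d <- add_attribute(d, attribute_spec(attribute = "unit", value = "Volt"))
  for (ds in ephys_scale_dims("data")) d <- add_dimension(d, ds)
  d <- add_dimension(d, dimension_spec(
    "band", "Hz", "band", 2L, description = "Center frequency of each band"))
  g <- add_dataset(g, d, "data")
  sr <- dataset_spec(dataset = "sampling_rate",
                     description = "Sampling rate of the recording")
  sr <- add_attribute(sr, attribute_spec(attribute = "unit", value = "Hz"))
  g <- add_dataset(g, sr, "sampling_rate")
  for (nm in c("electrode_id", "time", "band"))
    g <- add_dataset(g, scale_dataset_spec(nm, "data"), nm)
  g
}

spec_brain_data_collection <- function() {
  g <- group_spec(prefix = COLLECTION_PREFIX,
                  description = "Collection grouping data of a single device.")
  g <- attach_child_spec(g, managed_ref("BrainDataEphys", optional = TRUE),
                         "ephys")
  g <- attach_child_spec(g, managed_ref("BrainDataEphysProcessed",
                                        optional = TRUE), "processed")
  g
}

spec_brain_data_file <- function() {
  root <- file_spec("Managed session file for neurophysiology recordings.")
  data <- group_spec(group = "data",
                     description = "Raw and processed measurement data")
  internal <- group_spec(group = "internal",
                         description = "Data recorded inside the brain")
  internal <- attach_child_spec(internal,
                                managed_ref("BrainDataCollection",
                                            optional = TRUE), "collections")
  internal <- attach_child_spec(internal,
                                managed_ref("BrainDataEphys",
                                            optional = TRUE), "ephys")
  internal <- attach_child_spec(internal,
                                managed_ref("BrainDataEphysProcessed",
                                            optional = TRUE), "processed")
  external <- group_spec(group = "external",
                         description = "Data recorded outside the brain (stimuli, audio, ...)")
  external <- attach_child_spec(external,
                                managed_ref("BrainDataCollection",
                                            optional = TRUE), "collections")
  data <- attach_child_spec(data, internal, "internal")
  data <- attach_child_spec(data, external, "external")
  descriptors <- group_spec(group = "descriptors",
                            description = "Globally accessible metadata")
  descriptors <- attach_child_spec(
    descriptors, group_spec(group = "static",
                            description = "Static acquisition metadata"),
    "static")
  descriptors <- attach_child_spec(
    descriptors, group_spec(group = "dynamic",
                            description = "Dynamic post-processing metadata"),
    "dynamic")
  root <- attach_child_spec(root, data, "data")
  root <- attach_child_spec(root, descriptors, "descriptors")
  root
}

spec_managed_object_container <- function() {
  file_spec("Generic storage container for one externally stored managed object.")
}

spec_brain_data_multi_file <- function() {
  root <- file_spec("Container grouping related session files via /entry_# links.")
  attach_child_spec(root, group_spec(prefix = "entry_", optional = TRUE,
                                     description = "External link to a member file root"),
                    "entries")
}

# ---- populate procedures -----------------------------------------------------

populate_brain_data_file <- function(handle, payload, registry) {
  for (p in c("/data/internal", "/data/external",
              "/descriptors/static", "/descriptors/dynamic"))
    h5_create_group(handle$file, h5_path_join(handle$path, p))
}

write_scale <- function(file, group, name, values, unit, axis, data_path,
                        description = "", unlimited = FALSE) {
  spath <- h5_path_join(group, name)
  h5_write_dataset(file, spath, values, dims = length(values),
                   unlimited = unlimited)
  h5_write_attr(file, spath, "unit", unit)
  h5_write_attr(file, spath, "description", description)
  h5_write_attr(file, spath, "axis", as.integer(axis))
  h5_ds_set_scale(file, spath, name)
  h5_ds_attach(file, spath, data_path, axis)
  # sibling-relative target so the link resolves identically whether the
  # group is stored internally or behind an external link
  create_relationship_attribute(
    new_handle(file, spath, "dataset"), SCALE_REL_NAME, "order",
    h5_basename(data_path), source_axes = 0L, target_axes = as.integer(axis),
    description = sprintf("scale '%s' orders axis %d of the primary data",
                          name, axis))
  invisible(spath)
}

time_scale_values <- function(n, rate, start_time = 0, offset = 0) {
  start_time + 1000 * (offset + seq_len(n) - 1) / rate
}

populate_ephys_common <- function(handle, payload, primary_name, rank) {
  file <- handle$file; path <- handle$path
  rate <- payload$sampling_rate
  if (is.null(rate) || rate <= 0) stop("sampling_rate must be > 0")
  electrode_ids <- payload$electrode_ids
  if (is.null(electrode_ids)) stop("electrode_ids is required")
  auto_expand <- isTRUE(payload$auto_expand)
  data <- payload[[primary_name]]
  if (auto_expand) {
    n_space <- length(electrode_ids)
    dims <- if (rank == 2) c(n_space, 0) else c(n_space, 0, payload$n_band)
    data <- array(numeric(), dims)
  } else {
    if (is.null(data) || length(dim(data)) != rank)
      stop(sprintf("'%s' must be a rank-%d array", primary_name, rank))
    dims <- dim(data)
    if (dims[1] != length(electrode_ids))
      stop("electrode_ids length must equal the space extent")
  }
  dpath <- h5_path_join(path, primary_name)
  h5_write_dataset(file, dpath, as.double(data), dims = dims,
                   unlimited = c(FALSE, TRUE, rep(FALSE, rank - 2)))
  h5_write_attr(file, dpath, "unit", "Volt")
  h5_write_attr(file, path, ATTR_AUTO_EXPAND, as.integer(auto_expand))
  srpath <- h5_path_join(path, "sampling_rate")
  h5_write_dataset(file, srpath, as.double(rate))
  h5_write_attr(file, srpath, "unit", "Hz")
  start_time <- payload$start_time %||% 0
  h5_write_attr(file, path, "start_time", as.double(start_time))
  write_scale(file, path, "electrode_id", as.integer(electrode_ids),
              "id", 0L, dpath, "Identifier of each recording electrode")
  tvals <- payload$time %||% time_scale_values(dims[2], rate, start_time)
  if (length(tvals) != dims[2]) stop("time scale length must match time extent")
  write_scale(file, path, "time", as.double(tvals), "ms", 1L, dpath,
              "Sample times in milliseconds", unlimited = TRUE)
  if (!is.null(payload$anatomy)) {
    an <- payload$anatomy
    if (length(an$name) != dims[1] || length(an$id) != dims[1])
      stop("anatomy vectors must have one entry per electrode")
    write_scale(file, path, "anatomy_name", as.character(an$name), "name",
                0L, dpath, "Anatomical region name per electrode")
    write_scale(file, path, "anatomy_id", as.integer(an$id), "id", 0L,
                dpath, "Anatomical region id per electrode")
  }
  dpath
}

populate_brain_data_ephys <- function(handle, payload, registry) {
  populate_ephys_common(handle, payload, "raw_data", 2L)
}

populate_brain_data_ephys_processed <- function(handle, payload, registry) {
  if (isTRUE(payload$auto_expand)) {
    if (is.null(payload$n_band)) stop("auto-expand processed data needs n_band")
  } else {
    d <- payload$data
    if (is.null(d) || length(dim(d)) != 3) stop("'data' must be a rank-3 array")
    if (length(payload$band) != dim(d)[3])
      stop("band scale length must equal the band extent")
  }
  dpath <- populate_ephys_common(handle, payload, "data", 3L)
  band <- payload$band
  write_scale(handle$file, handle$path, "band", as.double(band),
              payload$band_unit %||% "Hz", 2L, dpath,
              "Center frequency of each band")
  dpath
}

# ---- user-facing creation ----------------------------------------------------

#' Create a session file
#'
#' Creates a managed `BrainDataFile` with the semantic hierarchy
#' `/data/internal`, `/data/external`, `/descriptors/static`,
#' `/descriptors/dynamic`, separating measured data from metadata and
#' in-brain from external recordings.
#'
#' @param path Filesystem path of the new file.
#' @param overwrite Replace an existing file?
#' @param registry Managed type registry.
#' @return Handle onto the session file root.
#' @export
create_session_file <- function(path, overwrite = FALSE,
                                registry = default_registry()) {
  create_managed_file(path, "BrainDataFile", overwrite = overwrite,
                      registry = registry)
}

#' Create a raw electrophysiology group
#'
#' Stores a space x time voltage array in Volts together with its sampling
#' rate and dimension scales (`electrode_id` on the space axis, `time` in
#' milliseconds on the time axis, optional anatomy scales), and
#' automatically creates `order` relationships from every scale to the
#' data. With `auto_expand = TRUE` the time axis starts empty and is
#' grown by [append_recordings()].
#'
#' @param parent Handle of the containing group (e.g. `/data/internal` of
#'   a session file, or a device collection).
#' @param name Group name; prefixed with `"ephys_data_"`.
#' @param raw 2-D voltage array (space x time); ignored when
#'   `auto_expand`.
#' @param sampling_rate Sampling rate in Hz.
#' @param electrode_ids Integer electrode identifiers, one per row of
#'   `raw`.
#' @param start_time Time of the first sample in ms.
#' @param anatomy Optional `list(name=, id=)` per-electrode anatomy.
#' @param auto_expand Create the time axis empty and extendible?
#' @param registry Managed type registry.
#' @return Handle of the new `BrainDataEphys` group.
#' @export
create_ephys <- function(parent, name, raw = NULL, sampling_rate,
                         electrode_ids, start_time = 0, anatomy = NULL,
                         auto_expand = FALSE,
                         registry = default_registry()) {
  create_managed_object(parent, "BrainDataEphys", name = name,
                        payload = list(raw_data = raw,
                                       sampling_rate = sampling_rate,
                                       electrode_ids = electrode_ids,
                                       start_time = start_time,
                                       anatomy = anatomy,
                                       auto_expand = auto_expand),
                        registry = registry)
}

#' Create a processed electrophysiology group
#'
#' Stores a space x time x band array derived from a raw recording, with
#' an additional `band` dimension scale. When `raw` names the source
#' recording, an `order` relationship on the shared space axis and a
#' `shared_ascending_encoding` relationship between the two time scales
#' are created, so selections can be mapped between processed and raw
#' data even under differing sampling rates.
#'
#' @inheritParams create_ephys
#' @param data 3-D array (space x time x band).
#' @param band Numeric band scale (e.g. center frequencies).
#' @param band_unit Unit of the band scale.
#' @param raw Optional handle of the raw `BrainDataEphys` group this data
#'   derives from.
#' @return Handle of the new `BrainDataEphysProcessed` group.
#' @export
create_processed_ephys <- function(parent, name, data, sampling_rate,
                                   electrode_ids, band, band_unit = "Hz",
                                   start_time = 0, raw = NULL,
                                   registry = default_registry()) {
  h <- create_managed_object(parent, "BrainDataEphysProcessed", name = name,
                             payload = list(data = data,
                                            sampling_rate = sampling_rate,
                                            electrode_ids = electrode_ids,
                                            band = band,
                                            band_unit = band_unit,
                                            start_time = start_time),
                             registry = registry)
  if (!is.null(raw)) {
    raw <- as_handle(raw)
    create_relationship_attribute(
      new_handle(h$file, h5_path_join(h$path, "electrode_id"), "dataset"),
      "matches_raw_space", "order",
      h5_path_join(raw$path, "electrode_id"), source_axes = 0L,
      target_axes = 0L,
      description = "electrodes ordered as in the source raw recording")
    create_relationship_attribute(
      new_handle(h$file, h5_path_join(h$path, "time"), "dataset"),
      "aligns_raw_time", "shared_ascending_encoding",
      h5_path_join(raw$path, "time"), source_axes = 0L, target_axes = 0L,
      description = "both time scales are ascending milliseconds")
  }
  h
}

primary_dataset_path <- function(ephys) {
  nm <- if (identical(ephys$managed_type, "BrainDataEphysProcessed"))
    "data" else "raw_data"
  h5_path_join(ephys$path, nm)
}

#' Append an acquisition block to an auto-expanding recording
#'
#' Grows the primary data along the time axis and every time-axis
#' dimension scale consistently; previously written samples are
#' unchanged. The built-in `time` scale continues the
#' `start_time + 1000 k / rate` series.
#'
#' @param ephys Handle of a `BrainDataEphys` group created with
#'   `auto_expand = TRUE`.
#' @param block space x t_new voltage array (its space extent must match).
#' @param scales Named list of values for custom time-axis scales, one
#'   entry of length `t_new` per custom scale.
#' @return The new time extent, invisibly.
#' @export
append_recordings <- function(ephys, block, scales = list()) {
  ephys <- as_handle(ephys)
  if (!h5_attr_exists(ephys$file, ephys$path, ATTR_AUTO_EXPAND) ||
      h5_read_attr(ephys$file, ephys$path, ATTR_AUTO_EXPAND) != 1L)
    stop("group was not created in auto-expand mode")
  dpath <- primary_dataset_path(ephys)
  dims <- h5_dataset_dims(ephys$file, dpath)
  if (is.null(dim(block))) block <- matrix(block, nrow = dims[1])
  if (dim(block)[1] != dims[1])
    stop(sprintf("block space extent %d != %d", dim(block)[1], dims[1]))
  t_new <- dim(block)[2]
  if (t_new == 0) return(invisible(dims[2]))
  rate <- h5_read_dataset(ephys$file, h5_path_join(ephys$path,
                                                   "sampling_rate"))
  start_time <- h5_read_attr(ephys$file, ephys$path, "start_time")
  # validate every time-axis scale before touching the file, so a refused
  # append leaves all extents unchanged
  appends <- list()
  for (rec in get_dimension_scales(ephys, axis = 1)) {
    vals <- if (rec$name == "time") {
      time_scale_values(t_new, rate, start_time, offset = dims[2])
    } else if (rec$name %in% names(scales)) {
      scales[[rec$name]]
    } else {
      stop(sprintf("no appended values supplied for custom time scale '%s'",
                   rec$name))
    }
    if (length(vals) != t_new)
      stop(sprintf("scale '%s': %d values for %d new samples",
                   rec$name, length(vals), t_new))
    if (length(rec$data) != dims[2])
      stop(sprintf("scale '%s' is inconsistent with the time extent",
                   rec$name))
    appends[[rec$name]] <- vals
  }
  new_dims <- dims
  new_dims[2] <- dims[2] + t_new
  h5_set_extent(ephys$file, dpath, new_dims)
  start <- rep(0, length(dims)); start[2] <- dims[2]
  count <- new_dims; count[2] <- t_new
  h5_write_hyperslab(ephys$file, dpath, as.double(block), start, count)
  for (nm in names(appends)) {
    spath <- h5_path_join(ephys$path, nm)
    h5_set_extent(ephys$file, spath, dims[2] + t_new)
    h5_write_hyperslab(ephys$file, spath, as.double(appends[[nm]]),
                       dims[2], t_new)
  }
  invisible(new_dims[2])
}

#' Add and retrieve dimension scales
#'
#' Scales follow the HDF5 dimension-scale convention (visible to
#' third-party tools) and carry a five-field record: data array, unit,
#' description, name, and axis.
#'
#' @param ephys Handle of an ephys group.
#' @param axis 0-based axis of the primary dataset.
#' @param name Scale name (also the scale dataset's name in the group).
#' @param unit Unit of the scale values.
#' @param data Scale values; length must equal the axis extent.
#' @param description Human-readable description.
#' @return `add_dimension_scale()` the scale record;
#'   `get_dimension_scales()` a list of records (optionally filtered by
#'   axis).
#' @export
add_dimension_scale <- function(ephys, axis, name, unit, data,
                                description = "") {
  ephys <- as_handle(ephys)
  dpath <- primary_dataset_path(ephys)
  dims <- h5_dataset_dims(ephys$file, dpath)
  if (axis < 0 || axis >= length(dims)) stop("axis out of range")
  if (length(data) != dims[axis + 1])
    stop(sprintf("scale length %d != axis extent %d", length(data),
                 dims[axis + 1]))
  if (h5_link_exists(ephys$file, h5_path_join(ephys$path, name)))
    stop(sprintf("scale '%s' already exists", name))
  unlim <- axis == 1 && h5_read_attr(ephys$file, ephys$path,
                                     ATTR_AUTO_EXPAND) == 1L
  write_scale(ephys$file, ephys$path, name, data, unit, axis, dpath,
              description, unlimited = unlim)
  list(name = name, unit = unit, description = description,
       axis = as.integer(axis), data = data)
}

#' @rdname add_dimension_scale
#' @export
get_dimension_scales <- function(ephys, axis = NULL) {
  ephys <- as_handle(ephys)
  dpath <- primary_dataset_path(ephys)
  out <- list()
  for (ch in h5_ls(ephys$file, ephys$path)) {
    p <- h5_path_join(ephys$path, ch)
    if (h5_obj_kind(ephys$file, p) != "dataset") next
    if (!h5_attr_exists(ephys$file, p, "CLASS")) next
    if (!identical(h5_read_attr(ephys$file, p, "CLASS"), "DIMENSION_SCALE"))
      next
    ax <- h5_read_attr(ephys$file, p, "axis")
    if (!is.null(axis) && ax != axis) next
    out[[ch]] <- list(
      name = ch,
      unit = h5_read_attr(ephys$file, p, "unit"),
      description = h5_read_attr(ephys$file, p, "description"),
      axis = as.integer(ax),
      data = h5_read_dataset(ephys$file, p))
  }
  out
}

#' Array- and key-based access to a recording
#'
#' `read_ephys()` reads the primary dataset (optionally with a
#' [selection()]); `ephys_aux()` exposes auxiliary data by key:
#' `"sampling_rate"`, `"unit"`, `"start_time"`, or any dimension-scale
#' name.
#'
#' @param ephys Handle of an ephys group.
#' @param sel Optional selection; `NULL` reads everything.
#' @param key Auxiliary data key.
#' @return `read_ephys()` an array; `ephys_aux()` the requested value.
#' @export
read_ephys <- function(ephys, sel = NULL) {
  ephys <- as_handle(ephys)
  dpath <- primary_dataset_path(ephys)
  vals <- h5_read_dataset(ephys$file, dpath)
  if (is.null(sel)) return(vals)
  dims <- h5_dataset_dims(ephys$file, dpath)
  idx <- selection_indices(sel, dims)
  if (is.matrix(idx)) {
    args <- lapply(seq_len(ncol(idx)), function(k) unique(idx[, k]) + 1)
    do.call(`[`, c(list(vals), args, list(drop = FALSE)))
  } else {
    vals[idx + 1]
  }
}

#' @rdname read_ephys
#' @export
ephys_aux <- function(ephys, key) {
  ephys <- as_handle(ephys)
  if (key == "sampling_rate")
    return(h5_read_dataset(ephys$file, h5_path_join(ephys$path,
                                                    "sampling_rate")))
  if (key == "unit")
    return(h5_read_attr(ephys$file, primary_dataset_path(ephys), "unit"))
  if (key == "start_time")
    return(h5_read_attr(ephys$file, ephys$path, "start_time"))
  scales <- get_dimension_scales(ephys)
  if (key %in% names(scales)) return(scales[[key]])
  stop(sprintf("unknown auxiliary key '%s'", key))
}

# ---- built-in type registration ---------------------------------------------

register_builtin_types <- function(registry) {
  register_managed_type("BrainDataEphys", spec_brain_data_ephys,
                        populate_brain_data_ephys, registry = registry)
  register_managed_type("BrainDataEphysProcessed",
                        spec_brain_data_ephys_processed,
                        populate_brain_data_ephys_processed,
                        base = "BrainDataEphys", registry = registry)
  register_managed_type("BrainDataCollection", spec_brain_data_collection,
                        registry = registry)
  register_managed_type("BrainDataFile", spec_brain_data_file,
                        populate_brain_data_file, kind = "file",
                        registry = registry)
  register_managed_type("ManagedObjectContainer",
                        spec_managed_object_container, kind = "file",
                        registry = registry)
  register_managed_type("BrainDataMultiFile", spec_brain_data_multi_file,
                        kind = "file", registry = registry)
  invisible(registry)
}

.onLoad <- function(libname, pkgname) {
  if (!registry_has(.neurofmt_registry, "BrainDataEphys"))
    register_builtin_types(.neurofmt_registry)
}
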