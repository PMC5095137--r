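#' Deterministic synthetic fixtures
#'
#' Generators for fully synthetic test data: an electrophysiology session
#' emulating a dual-device experiment (surface micro-electrode grid plus
#' laminar polytrode, tone stimuli of varying frequency and attenuation),
#' and an image-scaling index-map fixture (a low-resolution image mapped
#' pixel-to-block into a higher-resolution image). A violation injector
#' mutates compliant files in controlled ways so the verifier can be
#' exercised. All generators are pure functions of their parameters and
#' seed.
#'
#' @name fixtures
NULL

#' Session generator parameters
#'
#' Defaults describe a dual-device tone-mapping experiment: a 16-electrode
#' surface grid plus a 4-site polytrode sampled at 12200 Hz; tone
#' frequencies spanning 0.5 to 32 kHz at attenuations 0 to -70 dB, each
#' condition presented 20 times for 300 ms. The recording duration is
#' `n_conditions * repetitions * stimulus_duration`. Note the full default
#' session is acquisition-scale (several minutes of multi-channel data);
#' tests pass reduced parameters.
#'
#' @param n_electrodes_grid,n_electrodes_polytrode Electrode counts.
#' @param sampling_rate Sampling rate in Hz.
#' @param frequencies Stimulus tone frequencies in kHz.
#' @param attenuations Stimulus attenuations in dB (0 is loudest).
#' @param repetitions Presentations per condition.
#' @param stimulus_duration Duration of each presentation in ms.
#' @param n_bands Number of processed frequency bands.
#' @param seed Seed fixing every random draw.
#' @return Parameter list.
#' @export
session_params <- function(n_electrodes_grid = 16,
                           n_electrodes_polytrode = 4,
                           sampling_rate = 12200,
                           frequencies = c(0.5, 1, 2, 4, 8, 16, 32),
                           attenuations = seq(0, -70, by = -10),
                           repetitions = 20,
                           stimulus_duration = 300,
                           n_bands = 3,
                           seed = 1) {
  stopifnot(n_electrodes_grid > 0, n_electrodes_polytrode > 0,
            sampling_rate > 0, repetitions > 0, stimulus_duration > 0,
            length(frequencies) > 0, length(attenuations) > 0)
  list(n_electrodes_grid = n_electrodes_grid,
       n_electrodes_polytrode = n_electrodes_polytrode,
       sampling_rate = sampling_rate, frequencies = frequencies,
       attenuations = attenuations, repetitions = repetitions,
       stimulus_duration = stimulus_duration, n_bands = n_bands,
       seed = seed)
}

# per-electrode sinusoid + Gaussian noise, amplitudes ~1e-4 V; purely to
# make plots legible, no physiological claim
synth_voltages <- function(n_electrodes, n_samples, rate) {
  t <- seq_len(n_samples) / rate
  freqs <- 5 + 3 * seq_len(n_electrodes)
  sig <- 1e-4 * sin(outer(freqs, t, function(f, tt) 2 * pi * f * tt))
  sig + matrix(rnorm(n_electrodes * n_samples, sd = 2e-5),
               n_electrodes, n_samples)
}

#' Generate a synthetic electrophysiology session
#'
#' Creates a compliant session file holding two device collections (grid
#' and polytrode), a raw recording and a processed space x time x band
#' group per device, and a stimulus schedule under the external-data
#' group: onset times (ms, drawn from the grid time scale, hence an
#' `indexes_values` relationship into it), with the condition table
#' (frequency, attenuation) in row-major condition order and onsets
#' evenly spaced at `stimulus_duration`.
#'
#' @param params A [session_params()] list.
#' @param path Filesystem path of the session file.
#' @param registry Managed type registry.
#' @return Handle onto the session file root.
#' @export
generate_ephys_session <- function(params = session_params(), path,
                                   registry = default_registry()) {
  set.seed(params$seed)
  rate <- params$sampling_rate
  conditions <- expand.grid(attenuation = params$attenuations,
                            frequency = params$frequencies)[, 2:1]
  conditions <- conditions[order(match(conditions$frequency,
                                       params$frequencies)), ]
  n_cond <- nrow(conditions)
  n_onsets <- n_cond * params$repetitions
  duration_ms <- n_onsets * params$stimulus_duration
  n_samples <- max(1L, round(duration_ms * rate / 1000))

  session <- create_session_file(path, overwrite = TRUE,
                                 registry = registry)
  internal <- new_handle(path, "/data/internal", "group")
  devices <- list(grid = params$n_electrodes_grid,
                  polytrode = params$n_electrodes_polytrode)
  for (dev in names(devices)) {
    n_el <- devices[[dev]]
    coll <- create_managed_object(internal, "BrainDataCollection",
                                  name = dev, registry = registry)
    raw <- create_ephys(coll, dev,
                        raw = synth_voltages(n_el, n_samples, rate),
                        sampling_rate = rate,
                        electrode_ids = seq_len(n_el) - 1L,
                        registry = registry)
    bands <- 25 * seq_len(params$n_bands)
    proc_data <- array(rnorm(n_el * n_samples * params$n_bands, sd = 1e-5),
                       c(n_el, n_samples, params$n_bands))
    create_processed_ephys(coll, dev, data = proc_data,
                           sampling_rate = rate,
                           electrode_ids = seq_len(n_el) - 1L,
                           band = bands, raw = raw, registry = registry)
  }
  # stimulus schedule: onsets evenly spaced, conditions row-major
  onset_samples <- round(seq(0, n_onsets - 1) * params$stimulus_duration *
                           rate / 1000)
  onset_ms <- 1000 * onset_samples / rate    # equals time-scale values
  sched <- "/data/external/stimulus"
  h5_create_group(path, sched)
  h5_write_dataset(path, h5_path_join(sched, "onset_time"),
                   as.double(onset_ms))
  h5_write_attr(path, h5_path_join(sched, "onset_time"), "unit", "ms")
  cond_idx <- rep(seq_len(n_cond) - 1L, times = params$repetitions)
  h5_write_dataset(path, h5_path_join(sched, "condition"),
                   as.integer(cond_idx))
  h5_write_dataset(path, h5_path_join(sched, "frequency"),
                   as.double(conditions$frequency))
  h5_write_attr(path, h5_path_join(sched, "frequency"), "unit", "kHz")
  h5_write_dataset(path, h5_path_join(sched, "attenuation"),
                   as.double(conditions$attenuation))
  h5_write_attr(path, h5_path_join(sched, "attenuation"), "unit", "dB")
  grid_path <- find_managed_objects(session, "BrainDataEphys",
                                    exact = TRUE)[[1]]$path
  create_relationship_attribute(
    new_handle(path, h5_path_join(sched, "onset_time"), "dataset"),
    "selects_recording_times", "indexes_values",
    h5_path_join(grid_path, "time"), source_axes = 0L, target_axes = 0L,
    description = "onset times select matching samples of the grid time scale")
  create_relationship_attribute(
    new_handle(path, h5_path_join(sched, "condition"), "dataset"),
    "indexes_conditions", "indexes",
    h5_path_join(sched, "frequency"), source_axes = 0L, target_axes = 0L,
    description = "per-onset index into the condition table")
  wrap_managed_object(path, "/", registry)
}

#' Image-map fixture parameters
#'
#' @param rows,cols Source image shape.
#' @param factor Integer scale factor; each source pixel maps to a
#'   `factor x factor` block of target pixels.
#' @param seed Seed for the random image contents.
#' @return Parameter list. The target shape is the transposed source
#'   shape times `factor` (source axis 0 maps to target axis 1 and vice
#'   versa).
#' @export
image_map_params <- function(rows = 120, cols = 122, factor = 5, seed = 1) {
  stopifnot(rows > 0, cols > 0, factor >= 1)
  list(rows = rows, cols = cols, factor = factor, seed = seed)
}

#' Generate the image-scaling index-map fixture
#'
#' Writes a source image `A` of shape `(rows, cols)`, a target image `B`
#' of shape `(cols * factor, rows * factor)` (the axis-swap convention),
#' and a 4-dimensional index map `M` of shape
#' `(rows, cols, 2, factor^2)`: two spatial axes, an index axis of
#' length 2 (each target pixel is a row/column pair), and a stacking axis
#' listing every corresponding target pixel. Source pixel `(i, j)` maps
#' to target rows `j*factor .. (j+1)*factor - 1` and columns
#' `i*factor .. (i+1)*factor - 1`. The full index-map relationship chain
#' is created with one call.
#'
#' @param params An [image_map_params()] list.
#' @param path Filesystem path of the fixture file.
#' @return The created index map relationship bundle; the file holds
#'   `/A`, `/M`, and `/B`.
#' @export
generate_image_scaling_fixture <- function(params = image_map_params(),
                                           path) {
  set.seed(params$seed)
  r <- params$rows; c <- params$cols; f <- params$factor
  h5_create_file(path, overwrite = TRUE)
  A <- matrix(runif(r * c), r, c)
  B <- matrix(runif(c * f * r * f), c * f, r * f)
  M <- array(-1L, c(r, c, 2L, f * f))
  block <- as.matrix(expand.grid(dr = seq_len(f) - 1L, dc = seq_len(f) - 1L))
  for (i in seq_len(r)) {
    for (j in seq_len(c)) {
      # target tuples (row, col) for source pixel (i-1, j-1), 0-based
      M[i, j, 1L, ] <- (j - 1L) * f + block[, "dr"]
      M[i, j, 2L, ] <- (i - 1L) * f + block[, "dc"]
    }
  }
  h5_write_dataset(path, "/A", A)
  h5_write_dataset(path, "/B", B)
  h5_write_dataset(path, "/M", M)
  create_index_map_relationship(
    new_handle(path, "/A", "dataset"), new_handle(path, "/M", "dataset"),
    new_handle(path, "/B", "dataset"), base_name = "scaling",
    source_axes = c(0L, 1L))
}

#' Inject a single compliance violation into a fixture file
#'
#' Applies exactly one mutation and returns where and under which rule the
#' verifier must flag it.
#'
#' @param path A compliant fixture file.
#' @param kind One of `delete_required`, `wrong_attribute_value`,
#'   `scale_length_mismatch`, `broken_external_link`, `drop_imr_leg`.
#' @return List with the mutated `path` and the expected finding `rule`.
#' @export
inject_violation <- function(path,
                             kind = c("delete_required",
                                      "wrong_attribute_value",
                                      "scale_length_mismatch",
                                      "broken_external_link",
                                      "drop_imr_leg")) {
  kind <- match.arg(kind)
  ephys <- find_managed_objects(path, "BrainDataEphys")
  if (kind == "delete_required") {
    if (!length(ephys)) stop("no ephys group to mutate")
    p <- h5_path_join(ephys[[1]]$path, "raw_data")
    h5_delete(path, p)
    return(list(path = p, rule = "required-dataset"))
  }
  if (kind == "wrong_attribute_value") {
    if (!length(ephys)) stop("no ephys group to mutate")
    p <- h5_path_join(ephys[[1]]$path, "raw_data")
    h5_write_attr(path, p, "unit", "mV")
    return(list(path = p, rule = "fixed-value"))
  }
  if (kind == "scale_length_mismatch") {
    if (!length(ephys)) stop("no ephys group to mutate")
    p <- h5_path_join(ephys[[1]]$path, "electrode_id")
    vals <- h5_read_dataset(path, p)
    h5_delete(path, p)
    h5_write_dataset(path, p, c(vals, max(vals) + 1L))
    h5_write_attr(path, p, "unit", "id")
    h5_write_attr(path, p, "description", "mutated scale")
    h5_write_attr(path, p, "axis", 0L)
    h5_ds_set_scale(path, p, "electrode_id")
    h5_ds_attach(path, p, h5_path_join(ephys[[1]]$path, "raw_data"), 0L)
    create_relationship_attribute(
      new_handle(path, p, "dataset"), SCALE_REL_NAME, "order",
      h5_path_join(ephys[[1]]$path, "raw_data"), source_axes = 0L)
    return(list(path = p, rule = "scale-length"))
  }
  if (kind == "broken_external_link") {
    links <- find_external_links(path, "/")
    if (!length(links)) stop("file has no external links to break")
    tgt <- h5_external_link_target(path, links[[1]])
    tfile <- tgt$file
    if (!file.exists(tfile))
      tfile <- file.path(dirname(path), tgt$file)
    if (!file.exists(tfile)) stop("cannot locate external member file")
    unlink(tfile)
    return(list(path = links[[1]], rule = "broken-link"))
  }
  if (kind == "drop_imr_leg") {
    dropped <- FALSE
    for (obj in c("/M", "/A")) {
      if (!h5_link_exists(path, obj)) next
      for (a in h5_ls_attrs(path, obj)) {
        if (endsWith(a, IMR_POSTFIXES[["MAP_TO_TARGET"]])) {
          h5_delete_attr(path, obj, a)
          return(list(path = obj, rule = "incomplete-imr-bundle"))
        }
      }
    }
    stop("no index map relationship found to mutate")
  }
}

# depth-first listing of external-link paths
find_external_links <- function(file, root) {
  out <- character()
  walk <- function(path) {
    children <- tryCatch(h5_ls(file, path), error = function(e) character())
    for (ch in children) {
      p <- h5_path_join(path, ch)
      if (h5_link_kind(file, p) == "external") {
        out[[length(out) + 1L]] <<- p
        next   # do not descend through external links
      }
      if (h5_object_exists(file, p) && h5_obj_kind(file, p) == "group")
        walk(p)
    }
  }
  walk(root)
  out
}
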