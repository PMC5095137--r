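# Shared fixture builders. Everything is generated in code at test time;
# session parameters are scaled down from the acquisition-scale defaults
# purely to keep the suite fast (structure is unchanged).

tmp_h5 <- function() tempfile(fileext = ".h5")

small_session_params <- function(seed = 42) {
  session_params(n_electrodes_grid = 4, n_electrodes_polytrode = 2,
                 sampling_rate = 1000,
                 frequencies = c(0.5, 32), attenuations = c(0, -70),
                 repetitions = 2, stimulus_duration = 20,
                 n_bands = 2, seed = seed)
}

make_session <- function(path = tmp_h5(), seed = 42) {
  generate_ephys_session(small_session_params(seed), path)
}

make_image_fixture <- function(path = tmp_h5(), rows = 12, cols = 10,
                               factor = 3, seed = 7) {
  imr <- generate_image_scaling_fixture(
    image_map_params(rows = rows, cols = cols, factor = factor,
                     seed = seed), path)
  list(path = path, imr = imr)
}

# session with one externally stored ephys group (for broken-link and
# storage-transparency checks)
make_session_with_external <- function(dir = tempfile()) {
  dir.create(dir)
  main <- file.path(dir, "main.h5")
  ext <- file.path(dir, "member.h5")
  s <- create_session_file(main)
  set.seed(99)
  create_external_managed_object(
    wrap_managed_object(main, "/data/internal"), "BrainDataEphys", ext,
    name = "dev_ext",
    payload = list(raw_data = matrix(rnorm(60), 3, 20),
                   sampling_rate = 1000, electrode_ids = 0:2))
  list(main = main, ext = ext, session = s)
}
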