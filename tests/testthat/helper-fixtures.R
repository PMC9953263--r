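# Shared fixture builders for the test suite.

# Minimal hand-built OFT recording: one angle trace per plateau, given as
# a named list osmolality -> numeric vector of samples.
make_recording <- function(traces_by_plateau, angle = 2.5,
                           sampling_rate = 10) {
  osms <- as.numeric(names(traces_by_plateau))
  sli <- unlist(traces_by_plateau, use.names = FALSE)
  osm_col <- rep(osms, lengths(traces_by_plateau))
  structure(list(
    time = seq_along(sli) / sampling_rate,
    osmolality = osm_col,
    sli = matrix(sli, ncol = 1,
                 dimnames = list(NULL, paste0("sli_", angle))),
    angles = angle,
    sampling_rate = sampling_rate,
    schedule = data.frame(osmolality = osms,
                          duration_s = lengths(traces_by_plateau) /
                            sampling_rate)),
    class = "oft_recording")
}

# Population with every SD zero: all cells identical.
constant_population <- function(n, v300 = 90, vs = 49.5,
                                lysis_osm = 142, axis_ratio = 0.3) {
  sample_population(population_spec(
    n_cells = n,
    v300 = list(mean = v300, sd = 0),
    vs = list(mean = vs, sd = 0),
    lysis_osm = list(mean = lysis_osm, sd = 0),
    axis_ratio = list(mean = axis_ratio, sd = 0),
    seed = 1))
}

# Two-component slow/main velocity mixture spec used across tests.
mixture_spec <- function(n_cells, slow_weight, seed,
                         main_sd = 0.15) {
  population_spec(
    n_cells = n_cells,
    velocity = list(
      main = list(weight = 1 - slow_weight, mean = 1.0, sd = main_sd,
                  lower = 0, upper = Inf),
      slow = list(weight = slow_weight, mean = 0.10, sd = 0.03,
                  lower = 0, upper = 0.175),
      fast = list(weight = 0, mean = 1.6, sd = 0.1)),
    seed = seed)
}
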