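# Reduced-rate protocol configurations used throughout the tests; small
# enough that full sessions generate in well under a second.

reduced_config <- function(movements = default_movements(),
                           n_channels = 7, trials = 2, cycles = 5,
                           sampling_rate = 500, relax = 4, contract = 3) {
  protocol_config(sampling_rate = sampling_rate,
                  n_channels_unaffected = n_channels,
                  n_channels_affected = n_channels,
                  movements = movements,
                  relax_duration = relax, contract_duration = contract,
                  cycles_per_trial = cycles, trials = trials,
                  band = c(20, 200), f_max = 240, bin_width = 0.4)
}

# A very small config for fast end-to-end runs: 5 movements, 4 channels,
# 4 repetitions, short phases.
tiny_config <- function(movements = c("IF", "KP", "PP", "IP", "CW")) {
  reduced_config(movements = movements, n_channels = 4, trials = 2,
                 cycles = 2, relax = 1, contract = 0.75)
}

# Hand-built channel_summary data frame for RDM construction tests:
# `vectors` is a named list movement -> channel vector.
manual_summary <- function(vectors, measure = "RMS", stat = "median",
                           limb = "unaffected") {
  rows <- do.call(rbind, lapply(names(vectors), function(mv) {
    v <- vectors[[mv]]
    df <- data.frame(limb = limb, movement = mv, channel = seq_along(v),
                     measure = measure, median = NA_real_, iqr = NA_real_,
                     stringsAsFactors = FALSE)
    df[[stat]] <- v
    df
  }))
  class(rows) <- c("channel_summary", class(rows))
  rows
}

# Normalized features for one seeded reduced session (both limbs)
session_features <- function(cfg, seed = 1, measures = c("rms", "mnf"), ...) {
  sess <- generate_cohort(cfg, seed = seed, ...)
  normalize_features(rbind(compute_features(sess$unaffected, cfg, measures),
                           compute_features(sess$affected, cfg, measures)))
}
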