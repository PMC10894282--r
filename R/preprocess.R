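# Segmentation and onset/recession trimming --------------------------------

#' Trim the onset and recession of a phase segment
#'
#' Removes `trim_fraction` of the samples from each end of a series, keeping
#' the central `1 - 2 * trim_fraction` portion. This guards feature
#' computations against reaction-time contamination at the start and end of
#' each cued phase. The kept length is `floor(L * (1 - 2 * trim_fraction))`;
#' when the removal cannot be split evenly the surplus sample comes off the
#' end. At the default 15% trim a 3 s contraction sampled at 6000 Hz keeps
#' 6000 * 3 * 0.7 = 12,600 samples.
#'
#' @param samples Numeric vector.
#' @param trim_fraction Fraction in \[0, 0.5) removed from each end.
#' @return The trimmed numeric vector.
#' @examples
#' length(trim_segment(numeric(18000), 0.15))  # 12600
#' @export
trim_segment <- function(samples, trim_fraction) {
  if (length(trim_fraction) != 1 || !is.finite(trim_fraction) ||
      trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must lie in [0, 0.5)", call. = FALSE)
  n <- length(samples)
  keep <- floor(n * (1 - 2 * trim_fraction))
  lead <- floor(n * trim_fraction)
  samples[(lead + 1):(lead + keep)]
}

#' Segment a recording into trimmed per-repetition phase segments
#'
#' Cuts the recording along its schedule into one segment per (movement,
#' trial, cycle, phase), applies the configured onset/recession trim to each,
#' and assigns a global repetition index: trial 1's cycles are repetitions
#' 1..cycles, trial 2's continue at cycles+1, and so on. Repetitions are kept
#' as separate segments (features are computed per repetition); grouping
#' across repetitions is logical, not a concatenation of sample arrays.
#'
#' @param recording A `raw_recording`.
#' @param config The `protocol_config` the recording was collected under.
#' @return A list of `phase_segment` objects, each a list with `limb`,
#'   `movement`, `repetition`, `phase`, `channel_data` (channels x samples,
#'   trimmed), and `n_samples`.
#' @export
segment_phases <- function(recording, config) {
  stopifnot(inherits(recording, "raw_recording"))
  validate_protocol_config(config)
  sched <- recording$schedule
  if (is.null(sched) || nrow(sched) == 0) return(list())
  expect_len <- c(relaxation = phase_samples(config, "relaxation"),
                  contraction = phase_samples(config, "contraction"))
  seg_len <- sched$end_sample - sched$start_sample
  if (any(seg_len != expect_len[sched$phase]))
    stop("schedule intervals do not match the configured phase durations",
         call. = FALSE)
  if (any(sched$end_sample > ncol(recording$signal)))
    stop("schedule extends beyond the recorded signal", call. = FALSE)

  lapply(seq_len(nrow(sched)), function(k) {
    row <- sched[k, ]
    idx <- (row$start_sample + 1L):row$end_sample
    dat <- recording$signal[, idx, drop = FALSE]
    trimmed <- t(apply(dat, 1, trim_segment, trim_fraction = config$trim_fraction))
    if (nrow(dat) == 1) trimmed <- matrix(trimmed, nrow = 1)
    structure(
      list(limb = recording$limb,
           movement = row$movement,
           repetition = (row$trial - 1L) * config$cycles_per_trial + row$cycle,
           phase = row$phase,
           channel_data = trimmed,
           n_samples = ncol(trimmed)),
      class = "phase_segment"
    )
  })
}
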