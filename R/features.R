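# RMS / MNF feature extraction ---------------------------------------------

#' Root-mean-square amplitude of a segment
#'
#' `sqrt(sum(x_i^2) / N)` over the N samples of one trimmed repetition.
#'
#' @param samples Non-empty numeric vector (mV).
#' @return RMS amplitude in mV.
#' @examples
#' compute_rms(c(1, -2, 3))  # sqrt(14/3)
#' @export
compute_rms <- function(samples) {
  if (length(samples) == 0) stop("empty series", call. = FALSE)
  sqrt(mean(samples^2))
}

#' Binned power spectrum of a segment
#'
#' Single untapered periodogram of the segment, with raw spectral power
#' summed into contiguous bins of width `bin_width` from 0 Hz up to `f_max`;
#' total binned power equals total raw periodogram power below `f_max`. No
#' zero-padding is applied: padding a truncated segment smears a pure tone's
#' power across neighboring bins (rectangular-window leakage), whereas the
#' raw resolution of the trimmed phases (1/2.1 s at the default trim) is
#' already finer than the bin width. The default 0-1000 Hz range at 0.4 Hz
#' width yields M = 2500 bins.
#'
#' @param samples Non-empty numeric vector.
#' @param sampling_rate Sampling rate in Hz; must exceed `2 * f_max`.
#' @param f_max Upper frequency of interest, Hz.
#' @param bin_width Bin width in Hz.
#' @return List with `frequencies` (bin centers, Hz), `power` (non-negative
#'   bin powers), `bin_width`, and `f_max`.
#' @export
compute_binned_spectrum <- function(samples, sampling_rate, f_max = 1000,
                                    bin_width = 0.4) {
  if (length(samples) == 0) stop("empty series", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (sampling_rate <= 2 * f_max)
    stop("sampling_rate must exceed 2 * f_max", call. = FALSE)
  m <- f_max / bin_width
  if (abs(m - round(m)) > 1e-8)
    stop("f_max must be an integer multiple of bin_width", call. = FALSE)
  m <- as.integer(round(m))
  nfft <- length(samples)
  X <- stats::fft(samples)
  k <- 0:(nfft %/% 2)
  f_raw <- k * sampling_rate / nfft
  p_raw <- Mod(X[k + 1])^2 / (length(samples) * nfft)
  keep <- f_raw < f_max
  bin <- pmin(floor(f_raw[keep] / bin_width) + 1L, m)
  power <- numeric(m)
  agg <- tapply(p_raw[keep], bin, sum)
  power[as.integer(names(agg))] <- agg
  list(frequencies = (seq_len(m) - 0.5) * bin_width, power = power,
       bin_width = bin_width, f_max = f_max)
}

#' Mean frequency of a binned spectrum
#'
#' The power-weighted mean of the bin frequencies,
#' `sum(f_j * p_j) / sum(p_j)`.
#'
#' @param frequencies Bin frequencies in Hz.
#' @param powers Non-negative bin powers; must not be all zero.
#' @return Mean frequency in Hz, within the range of `frequencies`.
#' @export
compute_mnf <- function(frequencies, powers) {
  stopifnot(length(frequencies) == length(powers))
  tot <- sum(powers)
  if (tot <= 0)
    stop("undefined MNF: spectrum has zero total power", call. = FALSE)
  sum(frequencies * powers) / tot
}

#' Per-repetition feature table for a recording
#'
#' Segments the recording (see [segment_phases()]) and computes RMS and/or
#' MNF per channel for every trimmed repetition of every phase.
#'
#' @param recording A `raw_recording`, or an already-segmented list of
#'   `phase_segment` objects.
#' @param config The `protocol_config`.
#' @param measures Which features to compute: subset of `c("rms", "mnf")`.
#'   Skipping `"mnf"` avoids the spectral estimation entirely.
#' @return A data frame keyed by (limb, movement, repetition, phase, channel)
#'   with columns `rms` (mV) and/or `mnf` (Hz).
#' @export
compute_features <- function(recording, config, measures = c("rms", "mnf")) {
  measures <- match.arg(measures, several.ok = TRUE)
  segs <- if (inherits(recording, "raw_recording"))
    segment_phases(recording, config) else recording
  if (length(segs) == 0) {
    out <- data.frame(limb = character(), movement = character(),
                      repetition = integer(), phase = character(),
                      channel = integer())
    for (msr in measures) out[[msr]] <- numeric()
    return(out)
  }
  rows <- lapply(segs, function(s) {
    n_ch <- nrow(s$channel_data)
    df <- data.frame(limb = s$limb, movement = s$movement,
                     repetition = s$repetition, phase = s$phase,
                     channel = seq_len(n_ch), stringsAsFactors = FALSE)
    if ("rms" %in% measures)
      df$rms <- apply(s$channel_data, 1, compute_rms)
    if ("mnf" %in% measures)
      df$mnf <- apply(s$channel_data, 1, function(x) {
        sp <- compute_binned_spectrum(x, config$sampling_rate,
                                      f_max = config$f_max,
                                      bin_width = config$bin_width)
        compute_mnf(sp$frequencies, sp$power)
      })
    df
  })
  do.call(rbind, rows)
}

#' Normalize features to the per-channel maximum
#'
#' For each (limb, channel) group, divides every feature value by the group
#' maximum across all movements, repetitions, and (by default) both phases,
#' times 100, so each channel's maximum is exactly 100%. Adds `rms_norm` /
#' `mnf_norm` columns; already-normalized tables pass through unchanged
#' (the operation is idempotent).
#'
#' @param table A feature table from [compute_features()].
#' @param include_relaxation Include relaxation-phase values in the maximum
#'   (default `TRUE`, so relaxed-state baselines share the percent scale).
#' @return The table with `*_norm` percentage columns added/recomputed.
#' @export
normalize_features <- function(table, include_relaxation = TRUE) {
  for (msr in intersect(c("rms", "mnf"), names(table))) {
    key <- interaction(table$limb, table$channel, drop = TRUE)
    vals <- table[[msr]]
    ref <- vals
    if (!include_relaxation) ref[table$phase != "contraction"] <- NA
    grp_max <- ave(ref, key, FUN = function(v) max(v, na.rm = TRUE))
    if (any(!is.finite(grp_max)) || any(grp_max <= 0))
      stop("degenerate channel: non-positive per-channel maximum for ", msr,
           call. = FALSE)
    table[[paste0(msr, "_norm")]] <- 100 * vals / grp_max
  }
  table
}

#' Per-channel movement summaries (box-plot statistics)
#'
#' Summarizes the normalized contraction-phase feature values per (limb,
#' movement, channel, measure) across repetitions: quartiles (linear
#' interpolation between order statistics), IQR, Tukey whisker bounds
#' (furthest observation within 1.5 x IQR of the box), and the matching
#' relaxation-phase baseline median. `split` selects all repetitions or only
#' the even-indexed / odd-indexed ones (repetition-index parity), the two
#' halves used to build the split-data RDM.
#'
#' @param table A normalized feature table (see [normalize_features()]).
#' @param split `"all"`, `"even"`, or `"odd"`.
#' @param phase Which phase's repetitions to summarize (default contraction;
#'   the relaxation baseline median accompanies either choice).
#' @return A `channel_summary` data frame with columns limb, movement,
#'   channel, measure (`"RMS"`/`"MNF"`), phase, n, q1, median, q3, iqr,
#'   whisker_lo, whisker_hi, baseline_median.
#' @export
summarize_channels <- function(table, split = c("all", "even", "odd"),
                               phase = c("contraction", "relaxation")) {
  split <- match.arg(split)
  phase <- match.arg(phase)
  measures <- intersect(c("rms", "mnf"), names(table))
  norm_cols <- paste0(measures, "_norm")
  if (!all(norm_cols %in% names(table)))
    stop("table must be normalized first (see normalize_features)", call. = FALSE)
  sel <- switch(split,
                all = rep(TRUE, nrow(table)),
                even = table$repetition %% 2 == 0,
                odd = table$repetition %% 2 == 1)
  tab <- table[sel, , drop = FALSE]
  con <- tab[tab$phase == phase, , drop = FALSE]
  rel <- tab[tab$phase == "relaxation", , drop = FALSE]
  if (nrow(con) == 0) stop("no rows selected for phase ", phase, call. = FALSE)

  key <- interaction(con$limb, con$movement, con$channel, drop = TRUE)
  if (split != "all" && min(table(key)) < 2)
    stop("need at least 2 repetitions per group for a split summary",
         call. = FALSE)
  groups <- split(seq_len(nrow(con)), key)

  out <- lapply(groups, function(idx) {
    g <- con[idx, , drop = FALSE]
    base <- rel[rel$limb == g$limb[1] & rel$movement == g$movement[1] &
                  rel$channel == g$channel[1], , drop = FALSE]
    do.call(rbind, lapply(seq_along(measures), function(i) {
      v <- g[[norm_cols[i]]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      data.frame(limb = g$limb[1], movement = g$movement[1],
                 channel = g$channel[1], measure = toupper(measures[i]),
                 phase = phase,
                 n = length(v), q1 = q[1], median = q[2], q3 = q[3],
                 iqr = iqr,
                 whisker_lo = min(v[v >= lo_fence]),
                 whisker_hi = max(v[v <= hi_fence]),
                 baseline_median = if (nrow(base))
                   stats::median(base[[norm_cols[i]]]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # keep the protocol's movement order, not the alphabetical group order
  out <- out[order(match(out$limb, unique(table$limb)),
                   match(out$movement, unique(table$movement)),
                   out$channel), ]
  rownames(out) <- NULL
  attr(out, "split") <- split
  class(out) <- c("channel_summary", class(out))
  out
}

# movements x channels matrix of a summary statistic for one limb/measure;
# rows ordered by `movements` (defaults to order of appearance).
summary_matrix <- function(summary, measure, stat = c("median", "iqr"),
                           limb = NULL, movements = NULL) {
  stat <- match.arg(stat)
  s <- summary[summary$measure == measure, , drop = FALSE]
  if (!is.null(limb)) s <- s[s$limb == limb, , drop = FALSE]
  if (nrow(s) == 0) stop("no summary rows for measure ", measure, call. = FALSE)
  if (is.null(movements)) movements <- unique(s$movement)
  channels <- sort(unique(s$channel))
  m <- matrix(NA_real_, length(movements), length(channels),
              dimnames = list(movements, channels))
  m[cbind(match(s$movement, movements), match(s$channel, channels))] <- s[[stat]]
  if (anyNA(m)) stop("summary is missing movement/channel combinations", call. = FALSE)
  m
}
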