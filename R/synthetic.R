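# Synthetic two-limb sEMG session generator --------------------------------
#
# Stands in for restricted clinical recordings. Contraction excitation is
# modeled as Gaussian white noise band-passed to the configured band with a
# movement-by-channel spectral tilt (a Gaussian weighting centered at a
# per-movement, per-channel frequency) so that movements differ in both
# amplitude (RMS) and spectral center of mass (MNF). Repetition-to-repetition
# variability is multiplicative log-normal jitter on the contraction gain.

#' Construct an activation profile
#'
#' An activation profile describes how strongly each movement excites each
#' channel (`weights`, in \[0, 1\]) and where in the analog band each
#' movement/channel pair concentrates its spectral power (`spectral_centers`,
#' Hz). Repetition jitter, baseline noise level, and the contraction gain
#' complete the generative model: during a contraction the per-channel signal
#' standard deviation is `baseline_sd * (1 + gain * weight * jitter)` with
#' `jitter` drawn log-normally per repetition and channel.
#'
#' @param weights movements x channels matrix in \[0, 1\].
#' @param spectral_centers movements x channels matrix of Hz values strictly
#'   inside `band`.
#' @param rep_jitter_sd Log-scale SD of the per-repetition jitter (>= 0).
#' @param baseline_sd Baseline (relaxation) noise SD in mV (> 0).
#' @param gain Contraction gain multiplier (>= 0).
#' @param band Length-2 numeric band edges in Hz.
#' @return An `activation_profile` object.
#' @export
activation_profile <- function(weights, spectral_centers,
                               rep_jitter_sd = 0.15, baseline_sd = 0.05,
                               gain = 3, band = c(20, 450)) {
  weights <- as.matrix(weights)
  spectral_centers <- as.matrix(spectral_centers)
  if (!all(dim(weights) == dim(spectral_centers)))
    stop("weights and spectral_centers must have identical dimensions", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (any(spectral_centers <= band[1]) || any(spectral_centers >= band[2]))
    stop("spectral_centers must lie strictly inside the band", call. = FALSE)
  if (rep_jitter_sd < 0) stop("rep_jitter_sd must be >= 0", call. = FALSE)
  if (baseline_sd <= 0) stop("baseline_sd must be > 0", call. = FALSE)
  if (gain < 0) stop("gain must be >= 0", call. = FALSE)
  structure(
    list(weights = weights, spectral_centers = spectral_centers,
         rep_jitter_sd = rep_jitter_sd, baseline_sd = baseline_sd,
         gain = gain, band = as.numeric(band)),
    class = "activation_profile"
  )
}

#' Generate a random activation profile with controllable distinctness
#'
#' Each movement's channel-weight row is a convex mixture of one shared base
#' row and a movement-specific row: `(1 - distinctness) * base +
#' distinctness * own`. At `distinctness = 0` all movements share the same
#' activation pattern (no structure to recover); as distinctness grows the
#' expected pairwise distance between movement patterns grows linearly.
#' Spectral centers are mixed the same way within the central 70% of the band.
#'
#' @param n_movements,n_channels Matrix dimensions (>= 1).
#' @param distinctness Movement separability knob in \[0, 1\].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param ... Passed on to [activation_profile()] (`rep_jitter_sd`,
#'   `baseline_sd`, `gain`, `band`).
#' @return An `activation_profile`.
#' @examples
#' p <- generate_activation_profile(10, 7, distinctness = 0.8, seed = 1)
#' dim(p$weights)
#' @export
generate_activation_profile <- function(n_movements, n_channels, distinctness,
                                        seed, ...) {
  if (n_movements < 1 || n_channels < 1)
    stop("n_movements and n_channels must be >= 1", call. = FALSE)
  if (length(distinctness) != 1 || !is.finite(distinctness) ||
      distinctness < 0 || distinctness > 1)
    stop("distinctness must be a finite number in [0, 1]", call. = FALSE)
  dots <- list(...)
  band <- if (!is.null(dots$band)) dots$band else c(20, 450)
  with_seed(derive_seed(seed, "profile"), {
    base_w <- stats::runif(n_channels)
    own_w <- matrix(stats::runif(n_movements * n_channels), n_movements)
    w <- (1 - distinctness) * matrix(base_w, n_movements, n_channels, byrow = TRUE) +
      distinctness * own_w
    lo <- band[1] + 0.15 * diff(band)
    hi <- band[1] + 0.85 * diff(band)
    base_c <- stats::runif(n_channels, lo, hi)
    own_c <- matrix(stats::runif(n_movements * n_channels, lo, hi), n_movements)
    ctr <- (1 - distinctness) * matrix(base_c, n_movements, n_channels, byrow = TRUE) +
      distinctness * own_c
    activation_profile(w, ctr, ...)
  })
}

#' Derive a degraded activation profile for the affected limb
#'
#' Models the affected limb's activation structure as a noisy, attenuated
#' version of the unaffected limb's: weights (and spectral centers) are a
#' convex mixture of the input profile and an independent fresh draw, with
#' mixing weight `fidelity`, and the mixed weights are then scaled by
#' `attenuation` and clipped to \[0, 1\]. `fidelity = 1, attenuation = 1`
#' returns the input unchanged; `fidelity = 0` yields a profile independent
#' of the input.
#'
#' @param profile An `activation_profile`.
#' @param fidelity Structural similarity to the input, in \[0, 1\].
#' @param attenuation Amplitude scaling of the weights, in (0, 1\].
#' @param seed Integer seed for the fresh draw.
#' @return An `activation_profile` with the same dimensions.
#' @export
derive_affected_profile <- function(profile, fidelity, attenuation = 1, seed = 1) {
  stopifnot(inherits(profile, "activation_profile"))
  if (length(fidelity) != 1 || !is.finite(fidelity) || fidelity < 0 || fidelity > 1)
    stop("fidelity must be a finite number in [0, 1]", call. = FALSE)
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must lie in (0, 1]", call. = FALSE)
  nm <- nrow(profile$weights); nc <- ncol(profile$weights)
  band <- profile$band
  with_seed(derive_seed(seed, "affected-profile"), {
    fresh_w <- matrix(stats::runif(nm * nc), nm)
    lo <- band[1] + 0.15 * diff(band)
    hi <- band[1] + 0.85 * diff(band)
    fresh_c <- matrix(stats::runif(nm * nc, lo, hi), nm)
    w <- fidelity * profile$weights + (1 - fidelity) * fresh_w
    w <- pmin(pmax(w * attenuation, 0), 1)
    ctr <- fidelity * profile$spectral_centers + (1 - fidelity) * fresh_c
    activation_profile(w, ctr,
                       rep_jitter_sd = profile$rep_jitter_sd,
                       baseline_sd = profile$baseline_sd,
                       gain = profile$gain, band = band)
  })
}

# Unit-SD Gaussian noise band-limited to `band` by frequency-domain shaping,
# optionally tilted by a Gaussian weighting centered at `center` Hz. The hard
# band mask guarantees (up to clipping) that all power lies inside the band.
band_noise <- function(n, fs, band, center = NULL, width = NULL) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to two-sided physical frequency
  g <- as.numeric(f > band[1] & f < band[2])
  if (!is.null(center)) {
    if (is.null(width)) width <- diff(band) / 6
    g <- g * exp(-(f - center)^2 / (2 * width^2))
  }
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band mask: no frequency content", call. = FALSE)
  y / s
}

#' Generate a synthetic sEMG recording for one limb
#'
#' Lays out the full trial schedule (per movement: `trials` trials of
#' `cycles_per_trial` relaxation+contraction cycles) and fills each scheduled
#' interval with band-limited Gaussian noise. Relaxation intervals carry
#' baseline noise; contraction intervals carry noise whose per-channel SD is
#' `baseline_sd * (1 + gain * weight * jitter)` with the movement/channel
#' weight from `profile` and per-repetition log-normal jitter. The signal is
#' clipped to the configured ADC range and the clipped-sample fraction is
#' recorded.
#'
#' @param config A [protocol_config()].
#' @param profile An [activation_profile()] whose channel count matches the
#'   configured count for `limb`.
#' @param limb `"unaffected"` or `"affected"`.
#' @param seed Integer seed. All noise is drawn from sub-streams derived from
#'   this seed per (movement, trial, cycle, phase, channel), so the same seed
#'   and profile always reproduce the same signal regardless of limb label.
#' @return A `raw_recording`: list with `limb`, `signal` (channels x samples
#'   matrix, mV), `sampling_rate`, `schedule` (data frame with 0-based
#'   half-open sample intervals), and `clipped_fraction`.
#' @export
generate_recording <- function(config, profile, limb = c("unaffected", "affected"),
                               seed = 1) {
  limb <- match.arg(limb)
  validate_protocol_config(config)
  stopifnot(inherits(profile, "activation_profile"))
  n_ch <- if (limb == "affected") config$n_channels_affected else config$n_channels_unaffected
  if (ncol(profile$weights) != n_ch)
    stop(sprintf("profile has %d channels but config expects %d for the %s limb",
                 ncol(profile$weights), n_ch, limb), call. = FALSE)
  if (nrow(profile$weights) != length(config$movements))
    stop("profile movement count does not match config movements", call. = FALSE)

  fs <- config$sampling_rate
  n_relax <- phase_samples(config, "relaxation")
  n_contract <- phase_samples(config, "contraction")
  sched <- build_schedule(config, n_relax, n_contract)
  total <- max(sched$end_sample)
  sig <- matrix(0, n_ch, total)
  n_clipped <- 0

  for (k in seq_len(nrow(sched))) {
    row <- sched[k, ]
    m_idx <- match(row$movement, config$movements)
    rep_idx <- (row$trial - 1L) * config$cycles_per_trial + row$cycle
    idx <- (row$start_sample + 1L):row$end_sample
    n_seg <- length(idx)
    for (ch in seq_len(n_ch)) {
      sseed <- derive_seed(seed, row$movement, row$trial, row$cycle, row$phase, ch)
      seg <- with_seed(sseed, {
        if (row$phase == "contraction") {
          jitter <- if (profile$rep_jitter_sd > 0)
            stats::rlnorm(1, meanlog = -profile$rep_jitter_sd^2 / 2,
                          sdlog = profile$rep_jitter_sd)
          else 1
          amp <- profile$baseline_sd *
            (1 + profile$gain * profile$weights[m_idx, ch] * jitter)
          amp * band_noise(n_seg, fs, config$band,
                           center = profile$spectral_centers[m_idx, ch])
        } else {
          profile$baseline_sd * band_noise(n_seg, fs, config$band)
        }
      })
      n_clipped <- n_clipped + sum(abs(seg) > config$adc_range)
      sig[ch, idx] <- pmin(pmax(seg, -config$adc_range), config$adc_range)
    }
  }

  structure(
    list(limb = limb, signal = sig, sampling_rate = fs, schedule = sched,
         clipped_fraction = n_clipped / (n_ch * total)),
    class = "raw_recording"
  )
}

# Schedule: movements in protocol order, each a block of trials x cycles of
# relaxation then contraction. Sample intervals are 0-based, half-open.
build_schedule <- function(config, n_relax, n_contract) {
  rows <- list()
  pos <- 0L
  i <- 1L
  for (mv in config$movements) {
    for (tr in seq_len(config$trials)) {
      for (cy in seq_len(config$cycles_per_trial)) {
        rows[[i]] <- data.frame(movement = mv, trial = tr, cycle = cy,
                                phase = "relaxation", start_sample = pos,
                                end_sample = pos + n_relax,
                                stringsAsFactors = FALSE)
        pos <- pos + n_relax
        rows[[i + 1L]] <- data.frame(movement = mv, trial = tr, cycle = cy,
                                     phase = "contraction", start_sample = pos,
                                     end_sample = pos + n_contract,
                                     stringsAsFactors = FALSE)
        pos <- pos + n_contract
        i <- i + 2L
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %s limb, %d channels x %d samples @ %g Hz\n",
              x$limb, nrow(x$signal), ncol(x$signal), x$sampling_rate))
  cat(sprintf("  %d scheduled phases, clipped fraction %.2g\n",
              nrow(x$schedule), x$clipped_fraction))
  invisible(x)
}

#' Generate a paired two-limb synthetic session
#'
#' Draws one activation profile for the unaffected limb, derives a degraded
#' profile for the affected limb via [derive_affected_profile()], and renders
#' both limbs' recordings over the identical trial schedule. The affected
#' profile is truncated to the configured affected channel count when that is
#' smaller.
#'
#' @inheritParams generate_recording
#' @param distinctness Movement separability of the unaffected profile.
#' @param fidelity,attenuation Affected-limb degradation knobs; see
#'   [derive_affected_profile()].
#' @param seed Integer master seed.
#' @param shared_noise If `TRUE`, both limbs use the same noise sub-streams
#'   (so identical profiles yield identical signals); default `FALSE` gives
#'   each limb an independent noise stream.
#' @param ... Profile parameters passed to [generate_activation_profile()]
#'   (`rep_jitter_sd`, `baseline_sd`, `gain`; the band is taken from
#'   `config`).
#' @return List with elements `unaffected` and `affected` (both
#'   `raw_recording`) and `profiles` (the two activation profiles).
#' @examples
#' cfg <- protocol_config(sampling_rate = 500, band = c(20, 200),
#'                        f_max = 240, movements = c("IF", "KP", "PP"),
#'                        cycles_per_trial = 2)
#' sess <- generate_cohort(cfg, distinctness = 0.8, fidelity = 0.9,
#'                         attenuation = 0.8, seed = 7)
#' sess$unaffected
#' @export
generate_cohort <- function(config, distinctness = 0.8, fidelity = 0.9,
                            attenuation = 0.7, seed = 1, shared_noise = FALSE,
                            ...) {
  validate_protocol_config(config)
  prof_u <- generate_activation_profile(length(config$movements),
                                        config$n_channels_unaffected,
                                        distinctness,
                                        seed = derive_seed(seed, "unaffected"),
                                        band = config$band, ...)
  prof_a <- derive_affected_profile(prof_u, fidelity, attenuation,
                                    seed = derive_seed(seed, "affected"))
  if (config$n_channels_affected < config$n_channels_unaffected) {
    keep <- seq_len(config$n_channels_affected)
    prof_a <- activation_profile(prof_a$weights[, keep, drop = FALSE],
                                 prof_a$spectral_centers[, keep, drop = FALSE],
                                 rep_jitter_sd = prof_a$rep_jitter_sd,
                                 baseline_sd = prof_a$baseline_sd,
                                 gain = prof_a$gain, band = prof_a$band)
  }
  seed_u <- derive_seed(seed, "noise", "u")
  seed_a <- if (shared_noise) seed_u else derive_seed(seed, "noise", "a")
  list(
    unaffected = generate_recording(config, prof_u, "unaffected", seed = seed_u),
    affected = generate_recording(config, prof_a, "affected", seed = seed_a),
    profiles = list(unaffected = prof_u, affected = prof_a)
  )
}

#' Write a session to a directory store
#'
#' Persists a two-limb session as plain text: one whitespace-delimited
#' channels x samples matrix per limb (`signal_<limb>.tsv`), the schedule
#' table (`schedule.tsv`), and the protocol as YAML (`protocol.yaml`).
#' Intended for small (reduced-rate) sessions; full-rate signals are large
#' and are normally regenerated from the seed instead.
#'
#' @param session A list as returned by [generate_cohort()].
#' @param config The `protocol_config` used to generate it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (limb in c("unaffected", "affected")) {
    utils::write.table(session[[limb]]$signal,
                       file.path(dir, paste0("signal_", limb, ".tsv")),
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(session$unaffected$schedule, file.path(dir, "schedule.tsv"),
                     row.names = FALSE, sep = "\t", quote = FALSE)
  write_protocol_config(config, file.path(dir, "protocol.yaml"))
  invisible(dir)
}

#' Read a session from a directory store
#'
#' @param dir Directory written by [write_session()].
#' @return List with `unaffected`, `affected` (`raw_recording`) and `config`.
#' @export
read_session <- function(dir) {
  config <- read_protocol_config(file.path(dir, "protocol.yaml"))
  sched <- utils::read.table(file.path(dir, "schedule.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  out <- list(config = config)
  for (limb in c("unaffected", "affected")) {
    sig <- as.matrix(utils::read.table(file.path(dir, paste0("signal_", limb, ".tsv"))))
    dimnames(sig) <- NULL
    out[[limb]] <- structure(
      list(limb = limb, signal = sig, sampling_rate = config$sampling_rate,
           schedule = sched, clipped_fraction = NA_real_),
      class = "raw_recording"
    )
  }
  out
}
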