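#' Default movement set
#'
#' The ten hand movements used throughout the package: index flexion (IF),
#' key pinch (KP), pulp pinch (PP), index point (IP), cylindrical wrap (CW),
#' cylindrical wrap with wrist rotated (CR), tripod pinch (TP), wrist
#' extension (WE), wrist flexion (WF), and wrist rotation (WR).
#'
#' @return Character vector of the ten movement codes, in protocol order.
#' @export
default_movements <- function() {
  c("IF", "KP", "PP", "IP", "CW", "CR", "TP", "WE", "WF", "WR")
}

#' Recording protocol configuration
#'
#' Describes the acquisition protocol for a bilateral sEMG session: sampling
#' rate, channel counts per limb, movement set, phase durations, trial
#' structure, analog band limits, ADC range, and the onset/recession trim
#' fraction applied before feature extraction. Defaults describe a session
#' with seven circumferential forearm electrodes per limb sampled at 6000 Hz,
#' band-limited to 20-450 Hz within a +/-11 mV input range, where each of ten
#' movements is performed over two trials of five cycles, a cycle being 4 s
#' of relaxation followed by 3 s of contraction.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels_unaffected Number of sEMG channels on the unaffected limb.
#' @param n_channels_affected Number of sEMG channels on the affected limb
#'   (a short residual limb may only accommodate 4).
#' @param movements Character vector of unique movement codes.
#' @param relax_duration Relaxation phase duration in seconds.
#' @param contract_duration Contraction phase duration in seconds.
#' @param cycles_per_trial Relax+contract cycles per trial.
#' @param trials Number of trials per movement.
#' @param band Length-2 numeric, analog band edges in Hz.
#' @param adc_range Half-range of the ADC input in mV; signals are clipped to
#'   `[-adc_range, adc_range]`.
#' @param trim_fraction Fraction of each phase discarded from both the onset
#'   and the recession before computing features (reaction-time guard).
#' @param f_max Upper frequency of interest for the binned spectrum, Hz.
#' @param bin_width Spectral bin width in Hz.
#'
#' @return An object of class `protocol_config` (a validated list).
#' @examples
#' cfg <- protocol_config()
#' cfg$sampling_rate
#' @export
protocol_config <- function(sampling_rate = 6000,
                            n_channels_unaffected = 7,
                            n_channels_affected = 7,
                            movements = default_movements(),
                            relax_duration = 4,
                            contract_duration = 3,
                            cycles_per_trial = 5,
                            trials = 2,
                            band = c(20, 450),
                            adc_range = 11,
                            trim_fraction = 0.15,
                            f_max = 1000,
                            bin_width = 0.4) {
  cfg <- structure(
    list(
      sampling_rate = as.numeric(sampling_rate),
      n_channels_unaffected = as.integer(n_channels_unaffected),
      n_channels_affected = as.integer(n_channels_affected),
      movements = as.character(movements),
      relax_duration = as.numeric(relax_duration),
      contract_duration = as.numeric(contract_duration),
      cycles_per_trial = as.integer(cycles_per_trial),
      trials = as.integer(trials),
      band = as.numeric(band),
      adc_range = as.numeric(adc_range),
      trim_fraction = as.numeric(trim_fraction),
      f_max = as.numeric(f_max),
      bin_width = as.numeric(bin_width)
    ),
    class = "protocol_config"
  )
  validate_protocol_config(cfg)
}

#' @rdname protocol_config
#' @param cfg A `protocol_config` object to validate.
#' @export
validate_protocol_config <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  with(cfg, {
    if (!is.finite(sampling_rate) || sampling_rate <= 0)
      stop("sampling_rate must be a positive number", call. = FALSE)
    if (relax_duration <= 0 || contract_duration <= 0)
      stop("phase durations must be positive", call. = FALSE)
    if (trim_fraction < 0 || trim_fraction >= 0.5)
      stop("trim_fraction must lie in [0, 0.5)", call. = FALSE)
    if (length(movements) < 1 || anyDuplicated(movements))
      stop("movements must be non-empty and unique", call. = FALSE)
    if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
        band[2] >= sampling_rate / 2)
      stop("band must satisfy 0 < low < high < sampling_rate/2", call. = FALSE)
    if (n_channels_unaffected < 1 || n_channels_affected < 1)
      stop("channel counts must be >= 1", call. = FALSE)
    if (cycles_per_trial < 1 || trials < 1)
      stop("cycles_per_trial and trials must be >= 1", call. = FALSE)
    if (adc_range <= 0) stop("adc_range must be positive", call. = FALSE)
    if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
    if (f_max <= 0 || sampling_rate <= 2 * f_max)
      stop("f_max must satisfy 0 < f_max < sampling_rate/2", call. = FALSE)
  })
  cfg
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("sEMG protocol configuration\n")
  cat(sprintf("  sampling rate : %g Hz, band %g-%g Hz, ADC +/-%g mV\n",
              x$sampling_rate, x$band[1], x$band[2], x$adc_range))
  cat(sprintf("  channels      : %d unaffected / %d affected\n",
              x$n_channels_unaffected, x$n_channels_affected))
  cat(sprintf("  movements (%d) : %s\n", length(x$movements),
              paste(x$movements, collapse = " ")))
  cat(sprintf("  schedule      : %d trials x %d cycles of %g s relax + %g s contract\n",
              x$trials, x$cycles_per_trial, x$relax_duration, x$contract_duration))
  cat(sprintf("  trim fraction : %g\n", x$trim_fraction))
  invisible(x)
}

#' Read a protocol configuration from a YAML file
#'
#' The file is a flat key-value mapping whose keys match the arguments of
#' [protocol_config()]; absent keys take the defaults. Unknown keys are an
#' error so typos do not pass silently.
#'
#' @param path Path to a YAML file.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(protocol_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown protocol keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(protocol_config, raw)
}

#' Write a protocol configuration to a YAML file
#'
#' @param cfg A `protocol_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "protocol_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Samples per phase at the configured rate (must be integral in practice;
# fractional sample counts are floored).
phase_samples <- function(cfg, phase) {
  dur <- if (phase == "contraction") cfg$contract_duration else cfg$relax_duration
  as.integer(floor(dur * cfg$sampling_rate))
}
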