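# End-to-end pipeline orchestration ----------------------------------------

#' Run the full synthetic-session analysis pipeline
#'
#' Generates a paired two-limb synthetic session, extracts and normalizes
#' RMS/MNF features, and produces every downstream analysis artifact as
#' delimited text in `output_dir`: per-repetition feature tables, per-channel
#' box-plot summaries for both phases, within-movement concordance tables
#' (W with strength categories), unsplit and split-data RDMs per limb and
#' measure, EDI randomization-test results, the across-limb Wilcoxon
#' comparison of W values, RDM relatedness results, and nonmetric MDS
#' coordinates. A JSON manifest records the configuration snapshot, seeds,
#' package version, per-file MD5 digests, and diagnostic counters (clipped
#' sample fractions, dropped zero differences, MDS convergence), so a rerun
#' with the same configuration and seed is digest-identical.
#'
#' @param config A `protocol_config`, or the path of a YAML protocol file.
#' @param output_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param distinctness,fidelity,attenuation Generator knobs, see
#'   [generate_cohort()].
#' @param measures Features to analyze: subset of `c("rms", "mnf")`.
#' @param edi_mode `"exhaustive"` (n <= 10 movements) or `"monte_carlo"`.
#' @param n_draws Monte-Carlo draws for the EDI test when not exhaustive.
#' @param n_permutations Permutations for the RDM relatedness test.
#' @param mds_dims Embedding dimension for the MDS visualizations.
#' @param ... Further generator arguments passed to [generate_cohort()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = protocol_config(), output_dir, seed = 1,
                         distinctness = 0.8, fidelity = 0.9, attenuation = 0.7,
                         measures = c("rms", "mnf"),
                         edi_mode = NULL, n_draws = 10000,
                         n_permutations = 50000, mds_dims = 3, ...) {
  if (is.character(config)) config <- read_protocol_config(config)
  validate_protocol_config(config)
  measures <- match.arg(measures, several.ok = TRUE)
  n_mov <- length(config$movements)
  if (is.null(edi_mode))
    edi_mode <- if (n_mov <= 10) "exhaustive" else "monte_carlo"
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  log <- list()
  files <- character()
  emit <- function(obj, name) {
    path <- file.path(output_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  tryCatch({
    session <- generate_cohort(config, distinctness = distinctness,
                               fidelity = fidelity, attenuation = attenuation,
                               seed = seed, ...)
    log$clipped_fraction <- list(
      unaffected = session$unaffected$clipped_fraction,
      affected = session$affected$clipped_fraction)

    stage <- "features"
    feats <- rbind(compute_features(session$unaffected, config, measures),
                   compute_features(session$affected, config, measures))
    feats <- normalize_features(feats)
    emit(feats, "features.tsv")

    stage <- "summaries"
    sum_all <- summarize_channels(feats, split = "all")
    sum_even <- summarize_channels(feats, split = "even")
    sum_odd <- summarize_channels(feats, split = "odd")
    emit(sum_all, "channel_summary_all.tsv")
    emit(sum_even, "channel_summary_even.tsv")
    emit(sum_odd, "channel_summary_odd.tsv")
    export_boxplot_data(feats, file.path(output_dir, "boxplot_data.tsv"))
    files <- c(files, "boxplot_data.tsv")

    stage <- "consistency"
    cons <- do.call(rbind, lapply(measures, function(msr)
      movement_consistency(feats, msr)))
    emit(cons, "consistency.tsv")

    stage <- "dissimilarity"
    rdm_names <- rdm_measures()[c("rms" %in% measures, "rms" %in% measures,
                                  "mnf" %in% measures, "mnf" %in% measures)]
    limbs <- c("unaffected", "affected")
    rdms <- list()
    edi_rows <- list()
    mds_flags <- list()
    for (limb in limbs) {
      for (msr in rdm_names) {
        key <- paste(limb, msr, sep = ".")
        rdms[[key]] <- build_rdm(sum_all, msr, limb = limb)
        sdrdm <- build_split_rdm(sum_even, sum_odd, msr, limb = limb)
        write_rdm(rdms[[key]], file.path(output_dir,
                  sprintf("rdm_%s_%s.tsv", limb, msr)))
        write_rdm(sdrdm, file.path(output_dir,
                  sprintf("sdrdm_%s_%s.tsv", limb, msr)))
        files <- c(files, sprintf("rdm_%s_%s.tsv", limb, msr),
                   sprintf("sdrdm_%s_%s.tsv", limb, msr))
        ed <- edi_randomization_test(sdrdm, mode = edi_mode,
                                     n_draws = n_draws,
                                     seed = derive_seed(seed, "edi", limb, msr))
        edi_rows[[key]] <- data.frame(limb = limb, measure = msr,
                                      edi = ed$edi, p = ed$p,
                                      null_size = ed$null_size,
                                      mode = ed$mode,
                                      stringsAsFactors = FALSE)
        emb <- nonmetric_mds(rdms[[key]], dims = mds_dims,
                             seed = derive_seed(seed, "mds", limb, msr))
        mds_flags[[key]] <- emb$converged
        coords <- data.frame(movement = rownames(emb$coordinates),
                             emb$coordinates, stress = emb$stress,
                             row.names = NULL)
        names(coords)[2:(1 + mds_dims)] <- paste0("dim", seq_len(mds_dims))
        emit(coords, sprintf("mds_%s_%s.tsv", limb, msr))
      }
    }
    emit(do.call(rbind, edi_rows), "edi_results.tsv")
    log$mds_converged <- mds_flags

    stage <- "compare-limbs"
    cmp_rows <- lapply(measures, function(msr) {
      cw <- cons[cons$measure == toupper(msr), ]
      wu <- cw$W[cw$limb == "unaffected"][match(config$movements,
              cw$movement[cw$limb == "unaffected"])]
      wa <- cw$W[cw$limb == "affected"][match(config$movements,
              cw$movement[cw$limb == "affected"])]
      res <- compare_limb_consistency(wu, wa)
      data.frame(measure = toupper(msr), statistic = res$statistic, p = res$p,
                 median_unaffected = res$median_unaffected,
                 median_affected = res$median_affected,
                 direction = res$direction, n_used = res$n_used,
                 n_zero_dropped = length(config$movements) - res$n_used,
                 stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, cmp_rows), "limb_comparison.tsv")

    stage <- "relatedness"
    rel_rows <- lapply(rdm_names, function(msr) {
      res <- rdm_relatedness_test(rdms[[paste("affected", msr, sep = ".")]],
                                  rdms[[paste("unaffected", msr, sep = ".")]],
                                  n_permutations = n_permutations,
                                  seed = derive_seed(seed, "rel", msr))
      data.frame(measure = msr, tau_a = res$tau_a, p = res$p,
                 n_permutations = res$n_permutations, stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rel_rows), "relatedness.tsv")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "manifest"
  digests <- tools::md5sum(file.path(output_dir, files))
  manifest <- list(
    package = "semgrsa",
    version = as.character(utils::packageVersion("semgrsa")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    parameters = list(distinctness = distinctness, fidelity = fidelity,
                      attenuation = attenuation, measures = measures,
                      edi_mode = edi_mode, n_draws = n_draws,
                      n_permutations = n_permutations, mds_dims = mds_dims),
    config = unclass(config),
    log = log,
    files = data.frame(file = files, md5 = unname(digests),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Export box-and-whisker data for every channel and movement
#'
#' One row per (limb, movement, channel, measure, phase) with quartiles,
#' IQR, and Tukey whisker bounds (furthest observation within 1.5 x IQR of
#' the box), for both the contraction and relaxation phases, from a
#' normalized feature table. These are the numbers behind per-channel
#' box-plot panels of muscle excitation including the relaxed state.
#'
#' @param features A normalized feature table ([normalize_features()]).
#' @param path Output path (tab-separated).
#' @param movements Optional movement filter; an empty selection yields a
#'   header-only file.
#' @return The exported data frame, invisibly.
#' @export
export_boxplot_data <- function(features, path, movements = NULL) {
  if (!is.null(movements))
    features <- features[features$movement %in% movements, , drop = FALSE]
  if (nrow(features) == 0) {
    out <- data.frame(limb = character(), movement = character(),
                      channel = integer(), measure = character(),
                      phase = character(), n = integer(), q1 = numeric(),
                      median = numeric(), q3 = numeric(), iqr = numeric(),
                      whisker_lo = numeric(), whisker_hi = numeric())
  } else {
    out <- rbind(summarize_channels(features, "all", phase = "contraction"),
                 summarize_channels(features, "all", phase = "relaxation"))
    out$baseline_median <- NULL
    class(out) <- "data.frame"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
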