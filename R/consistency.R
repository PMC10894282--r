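# Within-movement consistency and across-limb comparison -------------------

#' Kendall's coefficient of concordance
#'
#' Agreement among m judges each ranking the same n objects, in \[0, 1\].
#' In the default orientation each repetition of a movement acts as a judge
#' ranking the sEMG channels, so W measures how reproducible the across-
#' channel excitation pattern is over repetitions. Ties receive mid-ranks
#' with the standard per-judge correction term `sum(t^3 - t)`:
#' `W = 12 S / (m^2 (n^3 - n) - m * sum(T))` with S the sum of squared
#' deviations of the object rank sums from their mean.
#'
#' @param values Repetitions x channels numeric matrix.
#' @param rank_over Which axis the judges rank: `"channels"` (default; rows
#'   are judges) or `"repetitions"` (the transposed reading: columns judge
#'   the repetitions).
#' @return W in \[0, 1\].
#' @examples
#' m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 3, 4))
#' kendalls_w(m)  # 0.9111
#' @export
kendalls_w <- function(values, rank_over = c("channels", "repetitions")) {
  rank_over <- match.arg(rank_over)
  values <- as.matrix(values)
  if (rank_over == "repetitions") values <- t(values)
  m <- nrow(values)  # judges
  n <- ncol(values)  # objects
  if (m < 2 || n < 2)
    stop("need at least 2 repetitions and 2 channels", call. = FALSE)
  ranks <- t(apply(values, 1, rank))  # mid-ranks within each judge
  tie_T <- apply(values, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(tie_T)
  if (denom <= 0)
    stop("undefined W: all values tied within every repetition", call. = FALSE)
  R <- colSums(ranks)
  S <- sum((R - m * (n + 1) / 2)^2)
  min(max(12 * S / denom, 0), 1)  # guard float roundoff at the boundaries
}

#' Categorize a concordance value
#'
#' Maps W to the consistency strength bands: poor (W < 0.20), minimal
#' (0.20 <= W < 0.40), weak (0.40 <= W < 0.60), moderate (0.60 <= W < 0.80),
#' strong (W >= 0.80).
#'
#' @param W Numeric value(s) in \[0, 1\].
#' @return Factor with levels poor < minimal < weak < moderate < strong.
#' @export
categorize_w <- function(W) {
  if (any(!is.finite(W)) || any(W < 0) || any(W > 1))
    stop("W must lie in [0, 1]", call. = FALSE)
  cut(W, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("poor", "minimal", "weak", "moderate", "strong"),
      ordered_result = TRUE)
}

#' Per-movement concordance table
#'
#' Computes Kendall's W per (limb, movement) from the normalized
#' contraction-phase values of one measure: the repetitions x channels
#' matrix of per-repetition feature values.
#'
#' @param table A normalized feature table.
#' @param measure `"rms"` or `"mnf"`.
#' @param rank_over Passed to [kendalls_w()].
#' @return Data frame with limb, movement, measure, W, category.
#' @export
movement_consistency <- function(table, measure = c("rms", "mnf"),
                                 rank_over = c("channels", "repetitions")) {
  measure <- match.arg(measure)
  rank_over <- match.arg(rank_over)
  col <- paste0(measure, "_norm")
  if (!col %in% names(table))
    stop("table must be normalized first (see normalize_features)", call. = FALSE)
  con <- table[table$phase == "contraction", , drop = FALSE]
  key <- interaction(con$limb, con$movement, drop = TRUE)
  out <- do.call(rbind, lapply(split(con, key), function(g) {
    mat <- summary_like_matrix(g, col)
    data.frame(limb = g$limb[1], movement = g$movement[1],
               measure = toupper(measure),
               W = kendalls_w(mat, rank_over = rank_over),
               stringsAsFactors = FALSE)
  }))
  out$category <- categorize_w(out$W)
  rownames(out) <- NULL
  out[order(out$limb, match(out$movement, unique(table$movement))), ]
}

# repetitions x channels matrix from long-format rows of one group
summary_like_matrix <- function(g, col) {
  reps <- sort(unique(g$repetition))
  chans <- sort(unique(g$channel))
  m <- matrix(NA_real_, length(reps), length(chans))
  m[cbind(match(g$repetition, reps), match(g$channel, chans))] <- g[[col]]
  if (anyNA(m)) stop("incomplete repetition/channel grid", call. = FALSE)
  m
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over the standard Shapiro-Wilk test, used to justify the
#' nonparametric analyses: in this pipeline the downstream tests are
#' rank-based regardless of the outcome, and the result only gates reporting
#' text.
#'
#' @param values Numeric sample, 3 <= n <= 5000, not all equal.
#' @return List with `statistic` and `p`.
#' @export
assess_normality <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("constant sample: normality is undefined", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

# Exact null CDF of the signed-rank sum W+ for given |d| mid-ranks, via
# convolution over doubled ranks (doubling makes mid-ranks integral). Returns
# P(W+ = k/2) for k = 0..sum(2r).
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  probs <- 1
  for (r in r2) {
    shifted <- c(numeric(r), probs)
    probs <- c(probs, numeric(r)) + shifted
  }
  probs / 2^length(r2)
}

#' Exact Wilcoxon signed-rank comparison of paired consistency values
#'
#' Paired two-sided Wilcoxon signed-rank test of the movement-wise W values
#' of the two limbs. Zero differences are dropped before ranking (classical
#' convention); absolute differences receive mid-ranks, and the null
#' distribution of the positive-rank sum is computed exactly by convolution
#' (valid for ties, exact for all usable n), so `p` agrees with full
#' enumeration of the 2^n sign assignments. The two-sided p doubles the
#' smaller tail (capped at 1). Direction reports which limb has the larger
#' median, stated separately from the two-sided p.
#'
#' @param w_unaffected,w_affected Equal-length (>= 5) numeric vectors of
#'   per-movement W values, paired by movement.
#' @return List with `statistic` (positive-rank sum for unaffected minus
#'   affected differences), `p`, `median_unaffected`, `median_affected`,
#'   `direction` (`"unaffected"`, `"affected"`, or `"equal"`), `n_used`
#'   (pairs after zero removal), and `degenerate` (all differences zero).
#' @examples
#' compare_limb_consistency(c(.8, .7, .9, .6, .75), c(.7, .5, .6, .65, .6))
#' @export
compare_limb_consistency <- function(w_unaffected, w_affected) {
  if (length(w_unaffected) != length(w_affected))
    stop("inputs must be paired (equal length)", call. = FALSE)
  if (length(w_unaffected) < 5)
    stop("need at least 5 paired values", call. = FALSE)
  d <- w_unaffected - w_affected
  med_u <- stats::median(w_unaffected)
  med_a <- stats::median(w_affected)
  direction <- if (med_u > med_a) "unaffected" else if (med_a > med_u) "affected" else "equal"
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(statistic = 0, p = 1, median_unaffected = med_u,
                median_affected = med_a, direction = direction,
                n_used = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  null <- signed_rank_null(r)  # P(W+ = k/2), k = 0..2*sum(r)
  k <- as.integer(round(2 * w_plus))
  p_le <- sum(null[seq_len(k + 1)])
  p_ge <- sum(null[(k + 1):length(null)])
  p <- min(1, 2 * min(p_le, p_ge))
  list(statistic = w_plus, p = p, median_unaffected = med_u,
       median_affected = med_a, direction = direction,
       n_used = length(d), degenerate = FALSE)
}
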