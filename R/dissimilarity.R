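# Representational dissimilarity analysis ----------------------------------

#' Rank-correlation distance between two channel vectors
#'
#' `1 - tau_b`, Kendall's rank correlation with the tie-adjusted
#' denominator, giving a distance in \[0, 2\]: 0 for identically ordered
#' vectors, 2 for exactly reversed strict orders.
#'
#' @param u,v Equal-length numeric vectors (length >= 2), neither fully tied.
#' @return Distance in \[0, 2\].
#' @examples
#' rank_distance(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 1/3
#' @export
rank_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2)
    stop("u and v must have equal length >= 2", call. = FALSE)
  if (length(unique(u)) == 1 || length(unique(v)) == 1)
    stop("undefined tau_b: fully tied vector", call. = FALSE)
  1 - stats::cor(u, v, method = "kendall")
}

new_rdm <- function(mat, conditions, measure, split = FALSE) {
  dimnames(mat) <- list(conditions, conditions)
  structure(list(conditions = conditions, matrix = mat, measure = measure,
                 split = split),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("%s (%s): %d conditions\n",
              if (x$split) "split-data RDM" else "RDM", x$measure,
              length(x$conditions)))
  print(round(x$matrix, 3))
  invisible(x)
}

parse_measure <- function(measure) {
  parts <- strsplit(measure, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("RMS", "MNF") ||
      !parts[2] %in% c("median", "IQR"))
    stop("measure must be one of RMS-median, RMS-IQR, MNF-median, MNF-IQR",
         call. = FALSE)
  list(feature = parts[1], stat = tolower(parts[2]))
}

#' All four RDM measures
#' @return Character vector `c("RMS-median", "RMS-IQR", "MNF-median", "MNF-IQR")`.
#' @export
rdm_measures <- function() c("RMS-median", "RMS-IQR", "MNF-median", "MNF-IQR")

#' Build a representational dissimilarity matrix
#'
#' Entry (i, j) is the rank-correlation distance ([rank_distance()]) between
#' movement i's and movement j's per-channel vectors of the chosen summary
#' measure (median or IQR of the normalized RMS or MNF), from an unsplit
#' channel summary. The result is symmetric with a zero diagonal.
#'
#' @param summary A `channel_summary` with `split = "all"`.
#' @param measure One of [rdm_measures()].
#' @param limb Which limb to use when the summary contains both.
#' @return An `rdm` object.
#' @export
build_rdm <- function(summary, measure = "RMS-median", limb = NULL) {
  pm <- parse_measure(measure)
  vecs <- summary_matrix(summary, pm$feature, pm$stat, limb = limb)
  n <- nrow(vecs)
  mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mat[i, j] <- mat[j, i] <- rank_distance(vecs[i, ], vecs[j, ])
    }
  }
  new_rdm(mat, rownames(vecs), measure, split = FALSE)
}

#' Build a split-data RDM
#'
#' Entry (i, j) is the rank-correlation distance between the even-split
#' channel vector of movement i and the odd-split vector of movement j. The
#' matrix is not symmetric; its diagonal holds the within-movement
#' (even vs odd) distances, so small diagonals indicate reliable movement
#' patterns and large off-diagonals indicate distinguishable ones.
#'
#' @param even_summary,odd_summary `channel_summary` objects for the even and
#'   odd repetition splits, covering the same movements and channels.
#' @param measure One of [rdm_measures()].
#' @param limb Which limb to use when the summaries contain both.
#' @return An `rdm` object with `split = TRUE`.
#' @export
build_split_rdm <- function(even_summary, odd_summary, measure = "RMS-median",
                            limb = NULL) {
  pm <- parse_measure(measure)
  ev <- summary_matrix(even_summary, pm$feature, pm$stat, limb = limb)
  od <- summary_matrix(odd_summary, pm$feature, pm$stat, limb = limb,
                       movements = rownames(ev))
  n <- nrow(ev)
  mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mat[i, j] <- rank_distance(ev[i, ], od[j, ])
    }
  }
  new_rdm(mat, rownames(ev), measure, split = TRUE)
}

rdm_mat <- function(x) {
  if (inherits(x, "rdm")) x$matrix else as.matrix(x)
}

#' Exemplar discriminability index
#'
#' Mean of the off-diagonal entries of a split-data RDM minus the mean of
#' its diagonal. Positive values indicate that movements are more dissimilar
#' to each other than to their own split half, i.e. that the movement set is
#' discriminable.
#'
#' @param sdrdm A split `rdm` object or a square numeric matrix.
#' @return The EDI (unitless).
#' @export
compute_edi <- function(sdrdm) {
  m <- rdm_mat(sdrdm)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 conditions", call. = FALSE)
  mean(m[row(m) != col(m)]) - mean(diag(m))
}

#' EDI condition-label randomization test
#'
#' Tests the null of no movement structure (exchangeable condition labels)
#' by recomputing the EDI under permutations of the rows of the split-data
#' RDM. In `"exhaustive"` mode every one of the n! row permutations is
#' enumerated (vectorized through the identity that the EDI under a row
#' permutation depends only on the permuted diagonal sum, since the total
#' entry sum is permutation-invariant); in `"monte_carlo"` mode `n_draws`
#' uniform random permutations plus the identity form the null. The p-value
#' is the fraction of null EDIs at least as large as the observed one; the
#' identity permutation is always included, so p is never 0 and a constant
#' matrix gives p = 1.
#'
#' @param sdrdm A split `rdm` or square numeric matrix.
#' @param mode `"exhaustive"` (requires n <= 10) or `"monte_carlo"`.
#' @param n_draws Number of random permutations in Monte-Carlo mode.
#' @param seed Seed for the Monte-Carlo draws.
#' @return An `edi_result`: list with `edi`, `null_size`, `p`, `mode`,
#'   `seed`.
#' @export
edi_randomization_test <- function(sdrdm, mode = c("exhaustive", "monte_carlo"),
                                   n_draws = 10000, seed = 1) {
  mode <- match.arg(mode)
  m <- rdm_mat(sdrdm)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 conditions", call. = FALSE)
  edi <- compute_edi(m)
  if (mode == "exhaustive") {
    if (n > 10)
      stop("exhaustive mode supports at most 10 conditions; use monte_carlo",
           call. = FALSE)
    res <- .edi_exhaustive_count_cpp(m)
    p <- res$count / res$total
    null_size <- res$total
  } else {
    s_id <- sum(diag(m))
    s_null <- with_seed(derive_seed(seed, "edi-mc"), {
      vapply(seq_len(n_draws), function(i) {
        perm <- sample.int(n)
        sum(m[cbind(perm, seq_len(n))])
      }, numeric(1))
    })
    # EDI is decreasing in the permuted diagonal sum
    p <- (sum(s_null <= s_id + 1e-12) + 1) / (n_draws + 1)
    null_size <- n_draws + 1
  }
  structure(list(edi = edi, null_size = null_size, p = p, mode = mode,
                 seed = seed),
            class = "edi_result")
}

#' @export
print.edi_result <- function(x, ...) {
  cat(sprintf("EDI = %.4f, p = %.4g (%s null of size %g)\n",
              x$edi, x$p, x$mode, x$null_size))
  invisible(x)
}

#' Kendall's tau-a rank correlation
#'
#' `(concordant - discordant) / (n (n - 1) / 2)`; tied pairs count in
#' neither term, and the denominator is not tie-adjusted.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\].
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 1, 2, 3))  # 5/6
#' @export
kendall_tau_a <- function(x, y) {
  .tau_a_cpp(as.numeric(x), as.numeric(y))
}

#' RDM relatedness randomization test across limbs
#'
#' Tests whether the movement dissimilarity structures of the two limbs are
#' related. The observed statistic is Kendall's tau-a between the
#' upper-triangular off-diagonal entries of the two RDMs. The null is built
#' by applying a random condition permutation simultaneously to the rows and
#' columns of the affected RDM and recomputing tau-a, `n_permutations`
#' times; `p = (#\{null >= observed\} + 1) / (n_permutations + 1)`.
#'
#' @param rdm_affected,rdm_unaffected `rdm` objects (or square matrices) over
#'   the same conditions in the same order.
#' @param n_permutations Number of random permutations (default 50,000).
#' @param seed Seed for the permutation draws.
#' @return A `relatedness_result`: list with `tau_a`, `p`, `n_permutations`,
#'   `seed`.
#' @export
rdm_relatedness_test <- function(rdm_affected, rdm_unaffected,
                                 n_permutations = 50000, seed = 1) {
  a <- rdm_mat(rdm_affected)
  u <- rdm_mat(rdm_unaffected)
  if (!all(dim(a) == dim(u)))
    stop("RDMs must have the same dimensions", call. = FALSE)
  if (inherits(rdm_affected, "rdm") && inherits(rdm_unaffected, "rdm") &&
      !identical(rdm_affected$conditions, rdm_unaffected$conditions))
    stop("RDMs must share the same condition set and order", call. = FALSE)
  obs <- kendall_tau_a(a[upper.tri(a)], u[upper.tri(u)])
  null <- with_seed(derive_seed(seed, "relatedness"), {
    .tau_a_perm_null_cpp(a, u, as.integer(n_permutations))
  })
  p <- (sum(null >= obs - 1e-12) + 1) / (n_permutations + 1)
  structure(list(tau_a = obs, p = p, n_permutations = n_permutations,
                 seed = seed),
            class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  cat(sprintf("RDM relatedness: tau_a = %.4f, p = %.4g (%d permutations)\n",
              x$tau_a, x$p, x$n_permutations))
  invisible(x)
}

#' Round-trip an RDM to delimited text
#'
#' Writes the square matrix with a condition-order header row/column.
#'
#' @param rdm An `rdm` object.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  utils::write.table(rdm$matrix, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @param measure,split Metadata to attach to the re-read object.
#' @export
read_rdm <- function(path, measure = "RMS-median", split = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  new_rdm(m, rownames(m), measure, split = split)
}
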