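# Nonmetric MDS under the squared-stress criterion -------------------------
#
# Minimizes sstress = sqrt( sum((d^2 - dhat^2)^2) / sum(d^4) ), where d are
# configuration distances and dhat^2 are disparities obtained by monotone
# (isotonic) regression of d^2 on the rank order of the input
# dissimilarities. Descent alternates isotonic regression with backtracking
# gradient steps on the coordinates, so the stress never increases; the
# search starts from a classical-scaling configuration plus random restarts.

# squared objective (sstress^2) and its gradient at fixed disparities
sstress_eval <- function(X, ord, pair_i, pair_j) {
  diffs <- X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE]
  d2 <- rowSums(diffs^2)
  dhat2 <- numeric(length(d2))
  dhat2[ord] <- stats::isoreg(d2[ord])$yf
  den <- sum(d2^2)
  if (den <= 0) return(list(value = Inf, d2 = d2, dhat2 = dhat2, den = den))
  list(value = sum((d2 - dhat2)^2) / den, d2 = d2, dhat2 = dhat2, den = den,
       diffs = diffs)
}

sstress_grad <- function(X, ev, pair_i, pair_j) {
  num <- sum((ev$d2 - ev$dhat2)^2)
  # d(value)/d(d2_k) with disparities held fixed (envelope), denominator free
  coef <- (2 * (ev$d2 - ev$dhat2) * ev$den - num * 2 * ev$d2) / ev$den^2
  G <- matrix(0, nrow(X), ncol(X))
  contrib <- coef * 2 * ev$diffs
  for (col in seq_len(ncol(X))) {
    G[, col] <- G[, col] +
      tapply(c(contrib[, col], -contrib[, col]),
             factor(c(pair_i, pair_j), levels = seq_len(nrow(X))),
             sum, default = 0)
  }
  G
}

descend_sstress <- function(X, ord, pair_i, pair_j, max_iterations, tolerance) {
  ev <- sstress_eval(X, ord, pair_i, pair_j)
  step <- 0.1 * mean(ev$d2 + 1e-12)
  converged <- FALSE
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    G <- sstress_grad(X, ev, pair_i, pair_j)
    gn <- sqrt(sum(G^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    improved <- FALSE
    for (bt in 1:30) {
      X_new <- X - (step / gn) * G
      ev_new <- sstress_eval(X_new, ord, pair_i, pair_j)
      if (ev_new$value < ev$value) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (ev$value - ev_new$value) / max(ev$value, 1e-30)
    X <- X_new; ev <- ev_new
    step <- step * 1.5
    if (rel < tolerance) { converged <- TRUE; break }
  }
  list(X = X, value = ev$value, iterations = iter, converged = converged)
}

#' Nonmetric multidimensional scaling (squared-stress criterion)
#'
#' Embeds a dissimilarity matrix in `dims` dimensions so that the rank order
#' of the configuration distances matches that of the input dissimilarities,
#' minimizing the squared-stress criterion (residuals between squared
#' distances and monotone-regressed squared disparities, normalized by the
#' sum of fourth powers of the distances). Initialization is classical
#' (metric) scaling of the input plus `n_restarts` random configurations;
#' the best final stress is kept. The descent never increases the stress.
#'
#' @param rdm An `rdm` object or symmetric dissimilarity matrix.
#' @param dims Embedding dimension (default 3); needs `n >= dims + 1`.
#' @param max_iterations Iteration cap per start.
#' @param tolerance Relative stress-change convergence threshold.
#' @param seed Seed for the random restarts.
#' @param n_restarts Number of random restarts beyond the classical start.
#' @return An `mds_embedding`: list with `coordinates` (n x dims, condition
#'   rownames), `stress`, `iterations`, `converged`.
#' @export
nonmetric_mds <- function(rdm, dims = 3, max_iterations = 500,
                          tolerance = 1e-6, seed = 1, n_restarts = 4) {
  m <- rdm_mat(rdm)
  n <- nrow(m)
  if (n < dims + 1)
    stop("need at least dims + 1 conditions", call. = FALSE)
  conditions <- if (inherits(rdm, "rdm")) rdm$conditions else rownames(m)
  ut <- upper.tri(m)
  delta <- m[ut]
  pair_i <- row(m)[ut]
  pair_j <- col(m)[ut]
  ord <- order(delta)

  if (all(delta == 0)) {
    coords <- matrix(0, n, dims, dimnames = list(conditions, NULL))
    return(structure(list(coordinates = coords, stress = 0, iterations = 0L,
                          converged = TRUE),
                     class = "mds_embedding"))
  }

  starts <- list()
  cs <- suppressWarnings(stats::cmdscale(m, k = dims))
  if (ncol(cs) < dims) cs <- cbind(cs, matrix(0, n, dims - ncol(cs)))
  starts[[1]] <- cs
  with_seed(derive_seed(seed, "mds"), {
    for (r in seq_len(n_restarts)) {
      starts[[r + 1]] <- matrix(stats::rnorm(n * dims, sd = mean(delta)), n, dims)
    }
  })

  best <- NULL
  for (X0 in starts) {
    fit <- descend_sstress(X0, ord, pair_i, pair_j, max_iterations, tolerance)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  coords <- best$X
  coords <- sweep(coords, 2, colMeans(coords))
  dimnames(coords) <- list(conditions, NULL)
  structure(list(coordinates = coords, stress = sqrt(max(best$value, 0)),
                 iterations = best$iterations, converged = best$converged),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("nonmetric MDS embedding: %d points in %d-D, sstress = %.3g%s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
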