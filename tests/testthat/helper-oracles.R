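# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# Kendall tau-b by literal pair counting with tie-adjusted denominator
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (sign(dx) == sign(dy)) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Kendall tau-a: untied denominator, ties count in neither term
oracle_tau_a <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (n * (n - 1) / 2)
}

# Kendall's W from the definition: mid-ranks per judge, literal rank-sum
# deviations, tie term accumulated by explicit counting
oracle_w <- function(values) {
  m <- nrow(values); n <- ncol(values)
  ranks <- matrix(0, m, n)
  tie_term <- 0
  for (i in seq_len(m)) {
    v <- values[i, ]
    for (j in seq_len(n)) {
      ranks[i, j] <- sum(v < v[j]) + (sum(v == v[j]) + 1) / 2
    }
    for (val in unique(v)) {
      t <- sum(v == val)
      tie_term <- tie_term + t^3 - t
    }
  }
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  12 * S / (m^2 * (n^3 - n) - m * tie_term)
}

# All permutations of 1..n as a list
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive EDI permutation p-value by literally permuting matrix rows
oracle_edi_p <- function(m) {
  edi <- function(x) mean(x[row(x) != col(x)]) - mean(diag(x))
  obs <- edi(m)
  nulls <- vapply(all_perms(nrow(m)), function(p) edi(m[p, , drop = FALSE]),
                  numeric(1))
  sum(nulls >= obs - 1e-12) / length(nulls)
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_null <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
}

# Exact relatedness p over all condition permutations (tau-a on upper
# triangles), no Monte-Carlo smoothing
oracle_relatedness_p <- function(a, u) {
  ut <- upper.tri(a)
  obs <- oracle_tau_a(a[ut], u[ut])
  nulls <- vapply(all_perms(nrow(a)), function(p) {
    ap <- a[p, p]
    oracle_tau_a(ap[ut], u[ut])
  }, numeric(1))
  sum(nulls >= obs - 1e-12) / length(nulls)
}
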