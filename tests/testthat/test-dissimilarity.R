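test_that("rank distance is 1 - tau_b and matches pair-counting", {
  u <- c(1, 2, 3, 4)
  expect_equal(rank_distance(u, u), 0)
  expect_equal(rank_distance(u, rev(u)), 2)
  expect_equal(rank_distance(u, c(1, 3, 2, 4)), 1 / 3)
  expect_error(rank_distance(u, rep(2, 4)), "tied")
  expect_error(rank_distance(1:3, 1:4), "equal length")

  set.seed(5)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(rank_distance(x, y), 1 - oracle_tau_b(x, y),
                 info = paste("case", i))
  }
})

test_that("tau-a matches pair counting with untied denominator", {
  expect_equal(kendall_tau_a(1:4, 1:4), 1)
  expect_equal(kendall_tau_a(1:4, 4:1), -1)
  expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 1, 2, 3)), 5 / 6)
  set.seed(6)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(kendall_tau_a(x, y), oracle_tau_a(x, y),
                 info = paste("case", i))
  }
})

test_that("RDM construction mirrors pairwise rank distances", {
  same <- manual_summary(list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3)))
  expect_true(all(build_rdm(same, "RMS-median")$matrix == 0))

  rev2 <- manual_summary(list(A = c(1, 2, 3), B = c(3, 2, 1)))
  expect_equal(build_rdm(rev2, "RMS-median")$matrix[1, 2], 2)

  vecs <- list(A = c(5, 1, 4, 2), B = c(1, 2, 3, 4), C = c(2, 1, 4, 3))
  rdm <- build_rdm(manual_summary(vecs), "RMS-median")
  for (i in 1:3) {
    for (j in 1:3) {
      expected <- if (i == j) 0 else 1 - oracle_tau_b(vecs[[i]], vecs[[j]])
      expect_equal(rdm$matrix[i, j], expected)
    }
  }
  expect_equal(rdm$matrix, t(rdm$matrix))
})

test_that("split RDM compares even vectors to odd vectors", {
  ev <- list(A = c(1, 3, 2), B = c(3, 1, 2))
  od <- list(A = c(1, 3, 2), B = c(3, 1, 2))
  sd0 <- build_split_rdm(manual_summary(ev), manual_summary(od), "RMS-median")
  expect_true(sd0$split)
  expect_equal(unname(diag(sd0$matrix)), c(0, 0))

  same <- list(A = c(1, 2, 3), B = c(1, 2, 3))
  sd1 <- build_split_rdm(manual_summary(same), manual_summary(same), "RMS-median")
  expect_true(all(sd1$matrix == 0))

  ev2 <- list(A = c(2, 5, 1), B = c(1, 2, 9))
  od2 <- list(A = c(3, 4, 2), B = c(9, 1, 2))
  sd2 <- build_split_rdm(manual_summary(ev2), manual_summary(od2), "RMS-median")
  for (i in 1:2) {
    for (j in 1:2) {
      expect_equal(sd2$matrix[i, j], 1 - oracle_tau_b(ev2[[i]], od2[[j]]))
    }
  }
})

test_that("EDI is mean off-diagonal minus mean diagonal", {
  expect_equal(compute_edi(matrix(0.7, 3, 3)), 0)
  m <- matrix(1, 4, 4); diag(m) <- 0
  expect_equal(compute_edi(m), 1)
  m3 <- matrix(0.6, 3, 3); diag(m3) <- c(0.1, 0.2, 0.3)
  expect_equal(compute_edi(m3), 0.4)
})

test_that("EDI randomization matches exhaustive enumeration", {
  const <- matrix(0.5, 4, 4)
  expect_equal(edi_randomization_test(const, "exhaustive")$p, 1)
  expect_equal(edi_randomization_test(const, "monte_carlo", n_draws = 200)$p, 1)

  m2 <- matrix(1, 2, 2); diag(m2) <- 0
  res2 <- edi_randomization_test(m2, "exhaustive")
  expect_equal(res2$p, 1 / 2)
  expect_equal(res2$null_size, 2)

  set.seed(8)
  for (n in 3:5) {
    m <- matrix(runif(n * n), n, n)
    res <- edi_randomization_test(m, "exhaustive")
    expect_equal(res$p, oracle_edi_p(m), info = paste("n =", n))
    expect_equal(res$null_size, factorial(n))
  }
  expect_error(edi_randomization_test(matrix(0, 11, 11), "exhaustive"),
               "monte_carlo")
})

test_that("Monte-Carlo EDI p agrees with the exhaustive null", {
  set.seed(9)
  m <- matrix(runif(25), 5, 5)
  p_ex <- edi_randomization_test(m, "exhaustive")$p
  p_mc <- edi_randomization_test(m, "monte_carlo", n_draws = 10000, seed = 2)$p
  se <- sqrt(p_ex * (1 - p_ex) / 10000)
  expect_lt(abs(p_mc - p_ex), 3 * se + 2 / 10001)
  # determinism under a fixed seed
  expect_identical(p_mc,
                   edi_randomization_test(m, "monte_carlo",
                                          n_draws = 10000, seed = 2)$p)
})

test_that("RDM relatedness test recovers identity and degenerate cases", {
  set.seed(10)
  d <- matrix(runif(100, 0.2, 1.8), 10, 10)
  d <- (d + t(d)) / 2; diag(d) <- 0
  rdm <- semgrsa:::new_rdm(d, letters[1:10], "RMS-median")
  res <- rdm_relatedness_test(rdm, rdm, n_permutations = 2000, seed = 1)
  expect_equal(res$tau_a, 1)
  expect_lt(res$p, 0.01)

  const <- semgrsa:::new_rdm(matrix(0.5, 10, 10), letters[1:10], "RMS-median")
  expect_equal(rdm_relatedness_test(const, rdm, n_permutations = 500)$p, 1)

  # 4-condition toy vs exact enumeration over all 24 permutations
  a <- matrix(runif(16), 4, 4); a <- (a + t(a)) / 2; diag(a) <- 0
  u <- matrix(runif(16), 4, 4); u <- (u + t(u)) / 2; diag(u) <- 0
  p_exact <- oracle_relatedness_p(a, u)
  res <- rdm_relatedness_test(a, u, n_permutations = 20000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 20001)

  expect_error(rdm_relatedness_test(a, matrix(0, 5, 5)), "dimensions")
})

test_that("RDMs round-trip through delimited text", {
  vecs <- list(IF = c(5, 1, 4, 2), KP = c(1, 2, 3, 4), PP = c(2, 1, 4, 3))
  rdm <- build_rdm(manual_summary(vecs), "RMS-median")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(rdm, path)
  back <- read_rdm(path, "RMS-median")
  expect_equal(back$matrix, rdm$matrix, tolerance = 1e-12)
  expect_identical(back$conditions, rdm$conditions)
})
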