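test_that("Kendall's W matches hand-worked cases", {
  # every repetition ranks the channels identically
  perfect <- matrix(rep(c(5, 1, 3, 9), each = 4), 4, byrow = FALSE)
  perfect <- t(replicate(4, c(5, 1, 3, 9)))
  expect_equal(kendalls_w(perfect), 1)

  # two repetitions with exactly reversed orderings
  expect_equal(kendalls_w(rbind(1:5, 5:1)), 0)

  # 3 judges x 4 objects worked example: W = 12 * 41 / (9 * 60)
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 3, 4))
  expect_equal(kendalls_w(m), 12 * 41 / (9 * 60))

  expect_error(kendalls_w(matrix(1, 3, 4)), "tied")
  expect_error(kendalls_w(matrix(1:3, 1, 3)), "at least 2")
})

test_that("Kendall's W agrees with definition-level and vegan oracles", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(sample(1:4, 12, replace = TRUE), 3, 4)  # heavy ties
    if (any(apply(m, 1, function(r) length(unique(r))) == 1)) next
    expect_equal(kendalls_w(m), oracle_w(m), info = paste("case", i))
  }
  skip_if_not_installed("vegan")
  for (i in 1:10) {
    m <- matrix(rnorm(20), 4, 5)
    vw <- unname(vegan::kendall.global(t(m))$Concordance_analysis["W", 1])
    expect_equal(kendalls_w(m), vw, tolerance = 1e-10)
  }
})

test_that("W is invariant to per-repetition monotone transforms", {
  set.seed(7)
  m <- matrix(runif(40), 5, 8)
  tm <- m
  tm[1, ] <- exp(m[1, ]); tm[2, ] <- m[2, ]^3; tm[3, ] <- 10 * m[3, ] - 4
  tm[4, ] <- log(m[4, ] + 1); tm[5, ] <- rank(m[5, ])
  expect_equal(kendalls_w(tm), kendalls_w(m))
  # transposed orientation is exposed and differs in general
  expect_equal(kendalls_w(m, rank_over = "repetitions"), kendalls_w(t(m)))
})

test_that("W categories use the printed half-open intervals", {
  expect_equal(as.character(categorize_w(c(0.14, 0.25, 1.0))),
               c("poor", "minimal", "strong"))
  expect_equal(as.character(categorize_w(c(0.2, 0.4, 0.6, 0.8))),
               c("minimal", "weak", "moderate", "strong"))
  expect_error(categorize_w(1.2), "W must lie")
})

test_that("per-movement consistency degrades with repetition jitter", {
  cfg <- reduced_config(movements = c("IF", "KP", "PP", "IP", "CW"),
                        trials = 1, cycles = 5, relax = 0.4, contract = 0.4)
  w_at <- function(jit) {
    mean(vapply(1:30, function(s) {
      prof <- generate_activation_profile(5, 7, 0.9, seed = 1000 + s,
                                          band = cfg$band,
                                          rep_jitter_sd = jit, gain = 3)
      rec <- generate_recording(cfg, prof, seed = s)
      feats <- normalize_features(compute_features(rec, cfg, "rms"))
      mean(movement_consistency(feats, "rms")$W)
    }, numeric(1)))
  }
  w_lo <- w_at(0.05); w_hi <- w_at(0.8)
  expect_gt(w_lo, w_hi)
  expect_gt(w_lo, 0.6)
})

test_that("normality screen wraps Shapiro-Wilk with guarded preconditions", {
  set.seed(3)
  x <- rnorm(50)
  res <- assess_normality(x)
  sw <- shapiro.test(x)
  expect_equal(res$statistic, unname(sw$statistic))
  expect_equal(res$p, sw$p.value)
  expect_error(assess_normality(c(1, 2)), "3 <= n")
  expect_error(assess_normality(rep(1, 10)), "constant")
})

test_that("exact Wilcoxon matches sign-pattern enumeration", {
  # worked example: differences (0.1, 0.2, 0.3, -0.05, 0.15)
  u <- c(0.5, 0.6, 0.7, 0.40, 0.55)
  a <- u - c(0.1, 0.2, 0.3, -0.05, 0.15)
  res <- compare_limb_consistency(u, a)
  expect_equal(res$p, 4 / 32)
  expect_equal(res$direction, "unaffected")

  swapped <- compare_limb_consistency(a, u)
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$direction, "affected")

  same <- compare_limb_consistency(u, u)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)

  # oracle equivalence on random inputs, including tied |differences|
  set.seed(11)
  for (n in c(5, 6, 8, 10, 12)) {
    for (rep in 1:5) {
      x <- round(runif(n), 1)
      y <- round(runif(n), 1)
      if (all(x == y)) next
      expect_equal(compare_limb_consistency(x, y)$p, oracle_wilcoxon_p(x, y),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
  expect_error(compare_limb_consistency(1:4 / 10, 1:3 / 10), "paired")
  expect_error(compare_limb_consistency(1:4 / 10, 2:5 / 10), "at least 5")
})
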