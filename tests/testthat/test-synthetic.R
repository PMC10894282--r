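test_that("activation profile distinctness controls movement separation", {
  p0 <- generate_activation_profile(10, 7, 0, seed = 11)
  expect_true(all(abs(sweep(p0$weights, 2, p0$weights[1, ])) < 1e-12))

  pa <- generate_activation_profile(10, 7, 0.6, seed = 5)
  pb <- generate_activation_profile(10, 7, 0.6, seed = 5)
  expect_identical(pa, pb)

  mean_pairdist <- function(w) mean(dist(w))
  d_hi <- d_lo <- numeric(20)
  for (s in 1:20) {
    d_hi[s] <- mean_pairdist(generate_activation_profile(10, 7, 0.9, s)$weights)
    d_lo[s] <- mean_pairdist(generate_activation_profile(10, 7, 0.1, s)$weights)
  }
  expect_gt(mean(d_hi), mean(d_lo))

  expect_error(generate_activation_profile(10, 7, 1.2, 1), "distinctness")
  expect_error(generate_activation_profile(10, 7, NaN, 1), "distinctness")
  expect_error(generate_activation_profile(0, 7, 0.5, 1), ">= 1")
})

test_that("affected profile derivation degrades a copy of the unaffected one", {
  p <- generate_activation_profile(10, 7, 0.8, seed = 3)
  expect_equal(derive_affected_profile(p, 1, 1, seed = 9), p)

  half <- derive_affected_profile(p, 1, 0.5, seed = 9)
  expect_equal(half$weights, p$weights / 2)

  cors <- vapply(1:50, function(s) {
    q <- derive_affected_profile(p, 0, 1, seed = s)
    mean(vapply(1:10, function(i) cor(p$weights[i, ], q$weights[i, ]),
                numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)

  expect_error(derive_affected_profile(p, -0.1, 1, 1), "fidelity")
  expect_error(derive_affected_profile(p, 0.5, 0, 1), "attenuation")
})

test_that("recording schedule arithmetic matches the protocol exactly", {
  cfg <- protocol_config(movements = "CW", trials = 1)
  prof <- generate_activation_profile(1, 7, 0.5, seed = 1, band = cfg$band)
  rec <- generate_recording(cfg, prof, seed = 1)
  # 5 cycles x (4 s + 3 s) at 6000 Hz
  expect_identical(ncol(rec$signal), 210000L)
  expect_identical(nrow(rec$schedule), 10L)

  # intervals are non-overlapping, contiguous, inside the signal
  sched <- rec$schedule
  expect_true(all(sched$start_sample[-1] == head(sched$end_sample, -1)))
  expect_true(max(sched$end_sample) <= ncol(rec$signal))
  expect_true(all(abs(rec$signal) <= cfg$adc_range))

  prof4 <- generate_activation_profile(1, 4, 0.5, seed = 1, band = cfg$band)
  expect_error(generate_recording(cfg, prof4, seed = 1), "channels")
})

test_that("gain 0 leaves contraction amplitude at the baseline level", {
  cfg <- reduced_config(movements = "CW", trials = 1, cycles = 1,
                        n_channels = 2, relax = 1, contract = 1)
  prof <- activation_profile(matrix(0.8, 1, 2), matrix(110, 1, 2),
                             gain = 0, rep_jitter_sd = 0, band = cfg$band)
  ratios <- vapply(1:10, function(s) {
    rec <- generate_recording(cfg, prof, seed = s)
    segs <- segment_phases(rec, cfg)
    rms <- vapply(segs, function(x) compute_rms(x$channel_data[1, ]), numeric(1))
    rms[2] / rms[1]  # contraction / relaxation
  }, numeric(1))
  # single trimmed segments carry a few percent of RMS estimation noise;
  # the mean ratio over the 10 repetitions must sit at 1
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("contraction RMS increases with activation weight", {
  cfg <- reduced_config(movements = c("A", "B", "C"), trials = 1, cycles = 1,
                        n_channels = 1, relax = 0.5, contract = 0.5)
  prof <- activation_profile(matrix(c(0.2, 0.5, 0.9), 3, 1),
                             matrix(110, 3, 1), rep_jitter_sd = 0.1,
                             band = cfg$band)
  rms_by_w <- rowMeans(vapply(1:50, function(s) {
    rec <- generate_recording(cfg, prof, seed = s)
    segs <- segment_phases(rec, cfg)
    con <- Filter(function(x) x$phase == "contraction", segs)
    vapply(con, function(x) compute_rms(x$channel_data[1, ]), numeric(1))
  }, numeric(3)))
  expect_true(all(diff(rms_by_w) > 0))
})

test_that("contraction power is confined to the configured band", {
  cfg <- reduced_config(movements = "CW", trials = 1, cycles = 1,
                        n_channels = 1, relax = 0.5, contract = 2,
                        sampling_rate = 2000)
  prof <- generate_activation_profile(1, 1, 0.5, seed = 1, band = cfg$band)
  for (s in 1:10) {
    rec <- generate_recording(cfg, prof, seed = s)
    seg <- Filter(function(x) x$phase == "contraction",
                  segment_phases(rec, cfg))[[1]]
    x <- seg$channel_data[1, ]
    pw <- Mod(fft(x))^2
    f <- (seq_along(pw) - 1) * cfg$sampling_rate / length(pw)
    f <- pmin(f, cfg$sampling_rate - f)
    in_band <- f >= cfg$band[1] & f <= cfg$band[2]
    expect_gt(sum(pw[in_band]) / sum(pw), 0.95)
  }
})

test_that("cohorts are deterministic and degrade gracefully", {
  cfg <- tiny_config()
  s1 <- generate_cohort(cfg, seed = 99)
  s2 <- generate_cohort(cfg, seed = 99)
  expect_identical(s1, s2)

  # identical profiles + shared noise stream => identical limbs
  s3 <- generate_cohort(cfg, fidelity = 1, attenuation = 1, seed = 7,
                        shared_noise = TRUE)
  expect_identical(s3$unaffected$signal, s3$affected$signal)

  # full protocol structure: 10 contraction reps per movement per limb
  cfg10 <- reduced_config(relax = 0.5, contract = 0.5)
  sess <- generate_cohort(cfg10, seed = 1)
  segs <- segment_phases(sess$affected, cfg10)
  con <- Filter(function(x) x$phase == "contraction", segs)
  per_mv <- table(vapply(con, `[[`, "", "movement"))
  expect_identical(length(per_mv), 10L)
  expect_true(all(per_mv == 10))
})

test_that("session directory store round-trips", {
  cfg <- tiny_config(movements = c("IF", "KP"))
  sess <- generate_cohort(cfg, seed = 4)
  dir <- withr::local_tempdir()
  write_session(sess, cfg, dir)
  back <- read_session(dir)
  expect_equal(back$unaffected$signal, sess$unaffected$signal, tolerance = 1e-12)
  expect_equal(back$config$movements, cfg$movements)
  expect_equal(back$affected$schedule$end_sample, sess$affected$schedule$end_sample)
})
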