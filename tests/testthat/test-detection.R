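# Windowed energy, adaptive binarization, run localization, and the
# full beat detector on annotated synthetic records.

test_that("windowed energy matches the trailing-sum definition", {
  expect_true(all(windowed_energy(numeric(50), 3) == 0))
  E <- windowed_energy(rep(2, 40), 5)
  expect_equal(E[10], 6 * 4)                    # (L+1) c^2 in the interior
  expect_equal(E[1], 4)                          # truncated at the edge
  # brute-force oracle on a unit impulse
  chi <- numeric(30); chi[11] <- 1               # 0-based index 10
  E <- windowed_energy(chi, 3)
  brute <- vapply(seq_along(chi), function(t)
    sum(chi[max(1, t - 3):t]^2), numeric(1))
  expect_equal(E, brute)
  expect_equal(which(E == 1), 11:14)
  # random-sequence oracle
  set.seed(3)
  chi <- rnorm(100)
  expect_equal(windowed_energy(chi, 7),
               vapply(1:100, function(t) sum(chi[max(1, t - 7):t]^2),
                      numeric(1)))
})

test_that("adaptive binarization triggers and updates as defined", {
  E <- rep(0.5, 100)
  r <- binarize_adaptive(E, m0 = 1)              # all below m0^2
  expect_true(all(r$Z == 0))
  expect_equal(r$m_final, 1)

  # lambda = 0: threshold frozen
  E2 <- c(rep(0.5, 10), rep(2, 10))
  r2 <- binarize_adaptive(E2, m0 = 1, lambda = 0)
  expect_equal(r2$Z, rep(c(0L, 1L), each = 10))
  expect_equal(r2$m_final, 1)

  # rectangular burst: hand-iterated recursion as oracle
  m0 <- 0.5; lam <- 0.125
  E3 <- c(rep(0, 20), rep(4 * m0^2, 5), rep(0, 20))
  r3 <- binarize_adaptive(E3, m0, lam)
  runs <- rle(r3$Z)
  expect_equal(sum(r3$Z), 5)
  expect_equal(runs$lengths[runs$values == 1L], 5L)
  m2 <- m0^2
  for (i in 1:5) m2 <- m2 * (1 - lam) + lam * 4 * m0^2
  expect_equal(r3$m_final, sqrt(m2), tolerance = 1e-12)

  expect_error(binarize_adaptive(E, m0 = 0), "positive")
})

test_that("binarization is invariant under joint amplitude rescaling", {
  set.seed(11)
  chi <- rnorm(500) * rep(c(1, 6), each = 250)
  E <- windowed_energy(chi, 4)
  base <- binarize_adaptive(E, m0 = 2)
  for (c_scale in c(0.01, 3, 250)) {
    Ec <- windowed_energy(c_scale * chi, 4)
    r <- binarize_adaptive(Ec, m0 = 2 * c_scale)
    expect_identical(r$Z, base$Z)
  }
})

test_that("run midpoints are located and merged correctly", {
  Z <- integer(120)
  Z[4:8] <- 1L                                   # 0-based run 3..7
  expect_identical(localize_midpoints(Z), 5L)
  Z[101:105] <- 1L                               # 0-based run 100..104
  expect_identical(localize_midpoints(Z), c(5L, 102L))
  expect_identical(localize_midpoints(integer(50)), integer(0))
  # merging keeps the higher-energy run
  Z2 <- integer(60); Z2[11:14] <- 1L; Z2[21:22] <- 1L
  E2 <- numeric(60); E2[11:14] <- 1; E2[21:22] <- 5
  expect_identical(localize_midpoints(Z2, refractory_samples = 15, E = E2),
                   20L)
  # output strictly increasing on random inputs
  set.seed(4)
  for (i in 1:10) {
    Zr <- as.integer(runif(300) > 0.7)
    mids <- localize_midpoints(Zr, refractory_samples = 5)
    expect_true(all(diff(mids) > 0))
  }
})

test_that("clean 60 bpm record yields one beat per second within 40 ms", {
  rec <- generate_beats(sim_config(duration = 30, seed = 5))
  beats <- detect_beats(rec$signal, rec$fs)
  expect_lte(abs(nrow(beats) - nrow(rec$annotations)), 1)
  gaps <- vapply(rec$annotations$r_time,
                 function(r) min(abs(beats$r_time - r)), numeric(1))
  expect_lt(max(gaps), 0.040)
  # T waves paired inside the same RR interval, after the R peak
  expect_true(all(beats$t_time > beats$r_time, na.rm = TRUE))
  expect_true(all(beats$latency_s < 0.6, na.rm = TRUE))
})

test_that("detector keeps sensitivity at 10 dB SNR", {
  rec <- generate_beats(sim_config(duration = 30, noise_snr_db = 10,
                                   seed = 6))
  expect_gte(se_on_record(rec), 0.95)
})

test_that("flat-line input produces an empty flagged beat table", {
  beats <- detect_beats(numeric(1000), 200)
  expect_identical(nrow(beats), 0L)
  expect_true(attr(beats, "flatline"))
  expect_error(detect_beats(numeric(100), 200), "2 seconds")
})

test_that("detection is deterministic and degrades monotonically with noise", {
  cfg <- sim_config(duration = 20, noise_snr_db = 15, seed = 42)
  r1 <- generate_beats(cfg); r2 <- generate_beats(cfg)
  expect_identical(r1$signal, r2$signal)
  b1 <- detect_beats(r1$signal, r1$fs); b2 <- detect_beats(r2$signal, r2$fs)
  expect_identical(b1, b2)

  worse <- 0
  for (seed in 1:10) {
    se_hi <- se_on_record(generate_beats(
      sim_config(duration = 20, noise_snr_db = 20, seed = seed)))
    se_lo <- se_on_record(generate_beats(
      sim_config(duration = 20, noise_snr_db = 5, seed = seed)))
    if (se_hi < se_lo) worse <- worse + 1
  }
  # allow ties; high-SNR sensitivity must not be systematically below
  expect_lte(worse, 2)
})

test_that("baseline drift does not break detection", {
  rec <- generate_beats(sim_config(duration = 20, baseline_drift_amp = 0.4,
                                   baseline_drift_freq = 0.3, seed = 9))
  expect_gte(se_on_record(rec), 0.95)
})
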