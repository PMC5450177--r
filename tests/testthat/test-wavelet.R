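# Wavelet filters, one-level transform, subband scheduling and band
# extraction.

test_that("Daubechies taps match published values and satisfy orthogonality", {
  # reference taps (minimum-phase scaling filters, standard tables)
  db4 <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
           -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
           0.0328830116668852, -0.010597401785069032)
  expect_equal(ecgwave:::daubechies_taps(4)$lowpass, db4, tolerance = 1e-12)
  db2 <- c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
           -0.12940952255126037)
  expect_equal(ecgwave:::daubechies_taps(2)$lowpass, db2, tolerance = 1e-12)
  for (N in c(1, 2, 4, 6, 8)) {
    h <- ecgwave:::daubechies_taps(N)$lowpass
    expect_equal(sum(h^2), 1, tolerance = 1e-10)       # |H|^2 + |H(-)|^2 = 1
    expect_equal(sum(h), sqrt(2), tolerance = 1e-10)
    if (N > 1)
      for (s in seq(2, 2 * N - 2, by = 2))
        expect_lt(abs(sum(h * c(h[-seq_len(s)], rep(0, s)))), 1e-10)
  }
})

test_that("one decomposition step conserves energy and kills constants", {
  ws <- wavelet_spec()
  set.seed(101)
  for (n in c(64, 512, 1024)) {
    x <- rnorm(n)
    s <- dwt_step(x, ws)
    expect_equal(sum(s$approx^2) + sum(s$detail^2), sum(x^2),
                 tolerance = 1e-6)
    expect_equal(idwt_step(s$approx, s$detail, ws), x, tolerance = 1e-10)
  }
  s <- dwt_step(rep(3.7, 128), ws)
  expect_lt(max(abs(s$detail)), 1e-10)
  expect_error(dwt_step(c(1, 2, 3), ws), "shorter")
})

test_that("a high-band sinusoid lands in the detail branch", {
  # oracle: a 0.375*fs tone lies mid-way through the high-pass band
  ws <- wavelet_spec()
  x <- sin(2 * pi * 0.375 * (0:1023))
  s <- dwt_step(x, ws)
  frac <- sum(s$detail^2) / (sum(s$detail^2) + sum(s$approx^2))
  expect_gte(frac, 0.9)
})

test_that("normalized frequency follows the band-relative definition", {
  expect_equal(normalize_frequency(15, 0, 200), 0.075)
  expect_equal(normalize_frequency(3, 3, 8), 0)
  expect_equal(normalize_frequency(8, 3, 8), 1)
  expect_error(normalize_frequency(5, 5, 5), "invalid band")
  expect_error(normalize_frequency(10, 3, 8), "outside")
})

test_that("subband scheduler reproduces the worked band plans", {
  p_t <- plan_subband(ecg_band(3, 8, 200))
  expect_identical(p_t$level, 4L)
  expect_equal(p_t$mapped_center, 0.44)
  expect_identical(p_t$path, c("approx", "approx", "approx", "detail"))

  p_q <- plan_subband(ecg_band(10, 20, 200))
  expect_identical(p_q$level, 3L)
  expect_equal(p_q$mapped_center, 0.6)

  p_c <- plan_subband(ecg_band(40, 60, 200))   # center 0.25
  expect_identical(p_c$level, 1L)
  expect_equal(p_c$mapped_center, 0.5)

  expect_error(plan_subband(ecg_band(90, 100, 200)), "Nyquist|splitting")
})

test_that("scheduler is scale-consistent: doubling fs adds one level", {
  for (band in list(c(3, 8), c(10, 20), c(5, 12))) {
    p1 <- plan_subband(ecg_band(band[1], band[2], 250))
    p2 <- plan_subband(ecg_band(band[1], band[2], 500))
    expect_identical(p2$level, p1$level + 1L)
    expect_equal(p2$mapped_center, p1$mapped_center)
  }
})

test_that("band extraction concentrates in-band tones and rejects others", {
  ws <- wavelet_spec()
  fs <- 200
  t <- (0:2047) / fs
  tone15 <- sin(2 * pi * 15 * t)
  sb <- extract_band(tone15, fs, ecg_band(10, 20, fs), ws)
  expect_identical(sb$level, 3L)
  expect_gte(sum(sb$coefficients^2) / sum(tone15^2), 0.7)

  tone50 <- sin(2 * pi * 50 * t)
  sb50 <- extract_band(tone50, fs, ecg_band(10, 20, fs), ws)
  expect_lt(sum(sb50$coefficients^2) / sum(tone50^2), 0.1)

  zero <- extract_band(numeric(2048), fs, ecg_band(10, 20, fs), ws)
  expect_true(all(zero$coefficients == 0))

  expect_error(extract_band(numeric(10), fs, ecg_band(10, 20, fs), ws),
               "at least")
})

test_that("band reconstruction raises the in-band energy fraction", {
  ws <- wavelet_spec()
  fs <- 200
  t <- (0:2047) / fs
  set.seed(7)
  band <- ecg_band(10, 20, fs)
  for (rep in 1:3) {
    x <- sin(2 * pi * 15 * t) + rnorm(length(t))
    sb <- extract_band(x, fs, band, ws)
    rec <- reconstruct_band(sb, ws, length(x))
    expect_gt(band_energy_fraction(rec, fs, band),
              band_energy_fraction(x, fs, band))
  }
})

test_that("subband index-to-time mapping localizes an impulse", {
  ws <- wavelet_spec()
  fs <- 200
  x <- numeric(2048); x[1001] <- 1       # impulse at t = 5 s
  sb <- extract_band(x, fs, ecg_band(10, 20, fs), ws)
  i <- which.max(abs(sb$coefficients)) - 1
  expect_lt(abs(subband_time(sb, i) - 5), 2.5 * sb$decimation / fs)
})

test_that("stopband gain bound decreases strictly in the vanishing moments", {
  expect_equal(stopband_gain(4), 2 / factorial(4) * sin(pi / 8)^4,
               tolerance = 1e-12)
  expect_equal(stopband_gain(4), 1.7872e-3, tolerance = 1e-4)
  expect_equal(stopband_gain(6), 8.7249e-6, tolerance = 1e-4)
  g <- vapply(1:20, stopband_gain, numeric(1))
  expect_true(all(diff(g) < 0))
  expect_lt(stopband_gain(30), 1e-20)
})

test_that("spectral band-energy fraction isolates tones", {
  fs <- 200
  t <- (0:1999) / fs
  tone <- sin(2 * pi * 15 * t)
  expect_gte(band_energy_fraction(tone, fs, ecg_band(10, 20, fs)), 0.99)
  expect_lte(band_energy_fraction(tone, fs, ecg_band(30, 40, fs)), 0.01)
  expect_error(band_energy_fraction(numeric(0), fs, ecg_band(10, 20, fs)),
               "empty")
  # synthetic QRS train concentrates below 40 Hz
  rec <- generate_beats(sim_config(duration = 10, t_amplitude = 0,
                                   seed = 2))
  expect_gte(band_energy_fraction(rec$signal, rec$fs, ecg_band(0, 40, rec$fs)),
             0.9)
})
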