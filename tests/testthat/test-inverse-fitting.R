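# Regressors, the two least-squares solvers, the alternating fit, and
# the k-threshold classifier.

test_that("regressors evaluate the unit templates at compressed latencies", {
  lat <- tpl$right$grid[c(50, 120, 200)]
  Y <- regressors(tpl, lat, k = 1)
  expect_equal(Y$Y1, tpl$right$values[c(50, 120, 200)])
  expect_equal(Y$Y2, tpl$left$values[c(50, 120, 200)])
  expect_equal(regressors(tpl, 0, 1)$Y1, 0)     # templates start at rest
  # k = 2 halves the support
  expect_warning(Y2 <- regressors(tpl, c(0.1, 0.2), k = 2), "support")
  expect_equal(Y2$Y1[2], 0)
  expect_error(regressors(tpl, 0.1, k = -1), "positive")
})

test_that("solve_h matches the generic least-squares oracle", {
  set.seed(21)
  # exact recovery on consistent data
  Y1 <- runif(50); Y2 <- runif(50)
  T0 <- 0.9 * Y1 - 0.8 * Y2
  h <- solve_h(T0, Y1, Y2)
  expect_equal(h$h_R, 0.9, tolerance = 1e-9)
  expect_equal(h$h_L, 0.8, tolerance = 1e-9)
  # oracle equivalence on noisy overdetermined instances
  for (i in 1:25) {
    n <- sample(5:40, 1)
    Y1 <- rnorm(n); Y2 <- rnorm(n)
    T <- rnorm(1) * Y1 - rnorm(1) * Y2 + rnorm(n, sd = 0.3)
    h <- solve_h(T, Y1, Y2)
    cf <- coef(lm(T ~ Y1 + Y2))
    expect_equal(h$h_R, unname(cf["Y1"]), tolerance = 1e-9)
    expect_equal(h$h_L, -unname(cf["Y2"]), tolerance = 1e-9)
  }
  expect_error(solve_h(T0, Y1 = runif(50), Y2 = rep(0, 50)), "singular")
  expect_error(solve_h(1, 1, 1), "2 beats")
})

test_that("solve_k recovers the least-squares slope of the integral relation", {
  Phi1 <- template_integral(tpl$right, 1)
  Phi2 <- template_integral(tpl$left, 1)
  u <- 0.95 * Phi1 - 0.9 * Phi2
  expect_equal(solve_k(rep(1.3 * u, 20), 0.95, 0.9, Phi1, Phi2), 1.3,
               tolerance = 1e-12)
  set.seed(31)
  dl <- 1.3 * u + rnorm(100, sd = 0.05 * abs(u))
  se <- 0.05 * abs(u) / sqrt(100) / abs(u)
  expect_lt(abs(solve_k(dl, 0.95, 0.9, Phi1, Phi2) - 1.3), 3 * se)
  expect_error(solve_k(dl, 1, Phi1 / Phi2, Phi1, Phi2), "degenerate")
})

test_that("fit recovers generating parameters on the design grid", {
  for (k in c(0.7, 1.0, 1.4)) for (hR in c(0.8, 1.0)) for (hL in c(0.8, 1.0)) {
    f <- generate_ap_features(list(k = k, h_R = hR, h_L = hL), tpl, seed = 7)
    fit <- fit_ap(f, tpl)
    expect_true(fit$converged)
    expect_lt(abs(fit$k / k - 1), 0.02)
    expect_lt(abs(fit$h_R / hR - 1), 0.02)
    expect_lt(abs(fit$h_L / hL - 1), 0.02)
  }
})

test_that("fit stays within 10% under 5% feature noise", {
  for (k in c(0.7, 1.0, 1.4)) for (hR in c(0.8, 1.0)) for (hL in c(0.8, 1.0)) {
    f <- generate_ap_features(list(k = k, h_R = hR, h_L = hL), tpl,
                              feature_noise = 0.05, seed = 11)
    fit <- fit_ap(f, tpl)
    expect_lt(abs(fit$k / k - 1), 0.10)
    expect_lt(abs(fit$h_R / hR - 1), 0.10)
    expect_lt(abs(fit$h_L / hL - 1), 0.10)
  }
})

test_that("an ischemia-grade time scale is recovered in the decision region", {
  f <- generate_ap_features(list(k = 0.7, h_R = 0.9, h_L = 0.93), tpl,
                            feature_noise = 0.05, seed = 13)
  fit <- fit_ap(f, tpl)
  expect_lt(fit$k, 0.9)
  expect_identical(classify(fit), "myocardial_ischemia")
})

test_that("fit requires at least two complete beats", {
  f <- generate_ap_features(list(k = 1, h_R = 1, h_L = 1), tpl, n_beats = 5)
  expect_error(fit_ap(f[1, ], tpl), "2 beats")
  f2 <- f; f2$t_amp[2:5] <- NA
  expect_error(fit_ap(f2, tpl), "2 beats")
})

test_that("classifier applies the k thresholds and reproduces printed cases", {
  expect_identical(classify(list(k = 0.71, h_R = 0.97, h_L = 0.95)),
                   "myocardial_ischemia")
  expect_identical(classify(list(k = 1.79, h_R = 0.81, h_L = 0.83)),
                   "heart_failure")
  expect_identical(classify(list(k = 1.01, h_R = 0.98, h_L = 0.99)),
                   "normal")
  # boundary behaviour: thresholds are strict inequalities
  expect_identical(classify(list(k = 0.9)), "normal")
  expect_identical(classify(list(k = 1.2)), "normal")
  # advisory flags do not change the label
  r <- classify(list(k = 1.0, h_R = 0.5, h_L = 0.5), flags = TRUE)
  expect_identical(r$label, "normal")
  expect_true(r$advisory[["low_h_R"]] && r$advisory[["low_h_L"]])
})

test_that("classification is monotone in k", {
  ks <- seq(0.5, 2, by = 0.01)
  labels <- vapply(ks, function(k) classify(list(k = k)), character(1))
  code <- c(myocardial_ischemia = 1, normal = 2, heart_failure = 3)[labels]
  expect_true(all(diff(code) >= 0))
})

test_that("per-class accuracy on the published parameter table", {
  rows <- load_pathology_params()
  acc <- classify_table(rows)
  acc <- acc[match(c("myocardial_ischemia", "heart_failure", "normal"),
                   acc$clinical), ]
  expect_equal(acc$n, c(15L, 15L, 10L))
  expect_equal(acc$accuracy_pct, c(93.3, 86.7, 100))
})
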