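test_that("autocorrelation matches hand arithmetic and definitional identities", {
  # 4-point oracle, worked by hand: x - mean = (1,-1,1,-1), gamma_0 = 1,
  # gamma_1 = (1/4) * ((1)(-1) + (-1)(1) + (1)(-1)) = -0.75
  g <- autocorrelation(c(1, -1, 1, -1), 1)
  expect_equal(g, c(1, -0.75))
  g_unb <- autocorrelation(c(1, -1, 1, -1), 1, estimator = "unbiased")
  expect_equal(g_unb, c(1, -1))

  set.seed(1)
  x <- rnorm(50)
  g0 <- autocorrelation(x, 0)
  expect_gte(g0, 0)
  expect_equal(g0, mean((x - mean(x))^2))

  expect_error(autocorrelation(rnorm(10), 10), "max_lag")
})

test_that("a long AR(1) realization recovers its lag-1 ratio", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(20500), 0.5, method = "recursive"))[501:20500]
  g <- autocorrelation(x, 1)
  expect_equal(g[2] / g[1], 0.5, tolerance = 0.02)
})

test_that("Yule-Walker on the exact AR(1) autocorrelation is exact", {
  g <- 0.6^(0:3) / (1 - 0.36)
  m <- solve_yule_walker(g, 1)
  expect_equal(m$coefficients, 0.6)
  expect_equal(m$noise_variance, 1)
})

test_that("Levinson-Durbin equals the dense Toeplitz solve", {
  set.seed(3)
  for (k in 1:100) {
    p <- sample(1:21, 1)
    r <- random_pd_acf(p, n = 150 + p)
    m <- solve_yule_walker(r, p)
    o <- dense_yule_walker(r, p)
    expect_equal(m$coefficients, o$phi, tolerance = 1e-10)
    expect_equal(m$noise_variance, o$sigma2, tolerance = 1e-10)
  }
})

test_that("degenerate autocorrelation sequences fail with a step-labelled error", {
  expect_error(solve_yule_walker(c(0, 0), 1), "gamma_0")
  expect_error(solve_yule_walker(c(1, 1.5), 1), "recursion step 1")
  expect_error(solve_yule_walker(c(1, 0.99, 0.5), 2), "recursion step")
})

test_that("order-21 fits of white noise leave all coefficients small", {
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(1000)
    m <- solve_yule_walker(autocorrelation(x, 21), 21)
    if (all(abs(m$coefficients) < 3 / sqrt(1000))) ok <- ok + 1
    expect_equal(m$noise_variance, var(x), tolerance = 0.1)
  }
  expect_gte(ok, 90)
})

test_that("AR(1) and AR(2) coefficients are recovered within 3 standard errors", {
  # asymptotic covariance of the Yule-Walker estimator:
  # Var(phi_hat) ~ sigma^2 * Gamma_p^{-1} / N, Gamma_p from the true ACF
  cases <- list(list(phi = 0.6), list(phi = c(1.2, -0.5)))
  for (case in cases) {
    p <- length(case$phi)
    # true autocovariances from a very long realization
    set.seed(99)
    xl <- as.numeric(stats::filter(rnorm(2e5 + 500), case$phi,
                                   method = "recursive"))[-(1:500)]
    g_true <- autocorrelation(xl, p)
    se <- sqrt(diag(solve(stats::toeplitz(g_true[1:p]))) / 1000)
    ok <- 0
    for (s in 1:100) {
      set.seed(s + 1000)
      x <- as.numeric(stats::filter(rnorm(1500), case$phi,
                                    method = "recursive"))[501:1500]
      m <- solve_yule_walker(autocorrelation(x, p), p)
      if (all(abs(m$coefficients - case$phi) < 3 * se)) ok <- ok + 1
    }
    expect_gte(ok, 95)
  }
})

test_that("our Yule-Walker fit matches stats::ar.yw", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(2500), c(0.9, -0.3),
                                method = "recursive"))[501:2500]
  m <- solve_yule_walker(autocorrelation(x, 8), 8)
  ref <- stats::ar.yw(x, aic = FALSE, order.max = 8, demean = TRUE)
  expect_equal(m$coefficients, unname(ref$ar), tolerance = 1e-8)
})

test_that("scaling the input scales the noise variance but not the coefficients", {
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(1500), 0.7, method = "recursive"))[501:1500]
  m1 <- solve_yule_walker(autocorrelation(x, 5), 5)
  m2 <- solve_yule_walker(autocorrelation(3 * x, 5), 5)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
  expect_equal(m2$noise_variance, 9 * m1$noise_variance, tolerance = 1e-12)
})

test_that("the PSD of a white-noise model is flat and AR peaks land where designed", {
  flat <- yule_walker_psd(eegcsa:::new_ar_model(numeric(0), 1), n_freqs = 22)
  expect_equal(flat$psd[2:21], rep(2 / 200, 20))
  expect_true(all(flat$psd >= 0))

  # oracle: a conjugate pole pair at angle 2*pi*10/200 peaks near 10 Hz
  m10 <- ar_template(10, radii = 0.95)
  dense <- yule_walker_psd(m10, fs = 200, freqs = seq(0, 100, by = 0.25))
  expect_lt(abs(dense$freq[which.max(dense$psd)] - 10), 0.5)

  expect_error(yule_walker_psd(eegcsa:::new_ar_model(1.2, 1)), "non-stationary")
})

test_that("the trapezoid integral of the PSD recovers the process variance", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(50500), c(1.0, -0.6),
                                method = "recursive"))[501:50500]
  g <- autocorrelation(x, 2)
  m <- solve_yule_walker(g, 2)
  dense <- yule_walker_psd(m, fs = 200, freqs = seq(0, 100, by = 0.05))
  integral <- sum(diff(dense$freq) * (head(dense$psd, -1) + tail(dense$psd, -1)) / 2)
  expect_equal(integral, g[1], tolerance = 0.02)
})

test_that("feature vectors have length 22 and collapse identical channels", {
  cfg <- synth_config(seed = 6)
  tr <- notch_filter(generate_trial("LEFT", cfg, "S1", 1))
  f <- extract_features(tr)
  expect_length(f, 22)
  expect_true(all(is.finite(f)))

  two_same <- cbind(tr$samples[, 1], tr$samples[, 1])
  expect_equal(extract_features(two_same, fs = 200),
               extract_features(matrix(tr$samples[, 1]), fs = 200))

  f_ar <- extract_features(tr, mode = "ar")
  expect_length(f_ar, 22)  # 21 coefficients + log noise variance
  m <- solve_yule_walker(rowMeans(apply(tr$samples, 2, autocorrelation,
                                        max_lag = 21)), 21)
  expect_equal(f_ar, c(m$coefficients, log(m$noise_variance)))

  expect_error(extract_features(matrix(1, 1000, 2), fs = 200), "constant")
  expect_error(extract_features(tr, order = 1000), "order")
})

test_that("a nearest-centroid rule on default features separates the four tasks", {
  dat <- make_subject_features(trials_per_task = 40, seed = 31)
  n <- nrow(dat$x)
  train <- unlist(lapply(split(seq_len(n), dat$task), function(idx) idx[1:28]))
  test <- setdiff(seq_len(n), train)
  mu <- colMeans(dat$x[train, ])
  sdv <- apply(dat$x[train, ], 2, sd)
  sdv[sdv < 1e-12] <- 1
  z <- sweep(sweep(dat$x, 2, mu), 2, sdv, "/")
  cent <- t(sapply(sort(unique(dat$task)), function(k) {
    colMeans(z[train, ][dat$task[train] == k, ])
  }))
  pred <- rownames(cent)[apply(z[test, ], 1, function(v) {
    which.min(colSums((t(cent) - v)^2))
  })]
  expect_gt(mean(pred == dat$task[test]), 0.9)
})
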