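make_rank1_surface <- function(n_years = 15, seed = 81) {
  set.seed(seed)
  x <- age_grid()
  bx <- exp(-x / 35); bx <- bx / sum(bx)
  kt <- cumsum(rnorm(n_years, -0.8, 0.6)); kt <- kt - mean(kt)
  ax <- standard_schedule("male")
  surf <- matrix(ax, n_years, 100, byrow = TRUE) + outer(kt, bx)
  rownames(surf) <- 1996:(1995 + n_years)
  list(surface = surf, ax = ax, bx = bx, kt = kt)
}

test_that("a noiseless rank-one surface is recovered exactly", {
  tr <- make_rank1_surface()
  fit <- fit_lc(tr$surface)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(sum(fit$bx), 1, tolerance = 1e-10)
  expect_equal(sum(fit$kt), 0, tolerance = 1e-10)
  expect_equal(fit$bx, tr$bx, tolerance = 1e-8)
  expect_equal(fit$kt, tr$kt, tolerance = 1e-6)
  expect_equal(fit$ax, tr$ax, tolerance = 1e-8)
  # reconstruction identity
  rec <- matrix(fit$ax, nrow(tr$surface), 100, byrow = TRUE) +
    outer(fit$kt, fit$bx) + fit$residuals
  expect_equal(rec, tr$surface, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("permuting years permutes the index and leaves the age response", {
  tr <- make_rank1_surface(n_years = 8, seed = 82)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  f1 <- fit_lc(tr$surface)
  f2 <- fit_lc(tr$surface[perm, ])
  expect_equal(f2$bx, f1$bx, tolerance = 1e-10)
  expect_equal(f2$kt, f1$kt[perm], tolerance = 1e-10)
})

test_that("a 3x3 toy surface matches an explicit eigen-decomposition", {
  M <- matrix(c(-4.0, -3.1, -2.2,
                -4.4, -3.0, -2.0,
                -4.8, -3.2, -1.8), 3, 3, byrow = TRUE)
  fit <- fit_lc(M)
  ax <- colMeans(M)
  C <- sweep(M, 2, ax)
  # leading eigenvector of C'C is b up to scale; k = C b / (b'b)
  eg <- eigen(crossprod(C))
  b_raw <- eg$vectors[, 1]
  if (sum(b_raw) < 0) b_raw <- -b_raw
  b_want <- b_raw / sum(b_raw)
  k_want <- drop(C %*% b_raw) * sum(b_raw) / sum(b_raw^2)
  expect_equal(fit$bx, b_want, tolerance = 1e-9)
  expect_equal(fit$kt, k_want - mean(k_want), tolerance = 1e-9)
})

test_that("constant-in-time surfaces fall back to a uniform age response", {
  surf <- matrix(standard_schedule("female"), 5, 100, byrow = TRUE)
  expect_warning(fit <- fit_lc(surf), "degenerate")
  expect_equal(fit$bx, rep(0.01, 100))
  expect_equal(fit$kt, rep(0, 5))
  expect_error(fit_lc(surf[1:2, ]), "3 years")
})

test_that("drift estimator matches its defining arithmetic", {
  # perfectly linear index: slope recovered, zero innovation
  kt <- seq(10, -10, length.out = 21)
  dm <- fit_drift(kt)
  expect_equal(dm$drift, -1, tolerance = 1e-12)
  expect_equal(dm$innovation_sd, 0, tolerance = 1e-12)
  # k = (0, 1, 0): drift 0, differences (1, -1), sd sqrt(2)
  dm2 <- fit_drift(c(0, 1, 0))
  expect_equal(dm2$drift, 0)
  expect_equal(dm2$innovation_sd, sqrt(2), tolerance = 1e-12)
  # level shifts do not matter
  dm3 <- fit_drift(c(0, 1, 0) + 100)
  expect_equal(dm3$drift, dm2$drift)
  expect_equal(dm3$innovation_sd, dm2$innovation_sd)
  expect_error(fit_drift(c(1, 2)), "3 time points")
})

test_that("zero-innovation forecasts are exactly linear in the horizon", {
  tr <- make_rank1_surface(seed = 83)
  fit <- fit_lc(tr$surface)
  paths <- forecast_k(fit, horizon = 12, n_sims = 5, seed = 84,
                      drift_model = list(drift = -0.7, innovation_sd = 0))
  k_last <- fit$kt[length(fit$kt)]
  want <- k_last + (1:12) * -0.7
  for (s in 1:5) expect_equal(unname(paths[s, ]), want, tolerance = 1e-12)
})

test_that("simulated index paths match random-walk-with-drift moments", {
  kt <- cumsum(rnorm(30, -0.5, 0.4))
  dm <- fit_drift(kt)
  paths <- forecast_k(kt, horizon = 10, n_sims = 10000, seed = 85)
  k_last <- kt[30]
  # mean at horizon 10
  mu_want <- k_last + 10 * dm$drift
  se_mean <- dm$innovation_sd * sqrt(10) / sqrt(10000)
  expect_lt(abs(mean(paths[, 10]) - mu_want), 3 * se_mean)
  # variance grows linearly: var at horizon h is h * sd^2
  v_want <- 10 * dm$innovation_sd^2
  se_var <- v_want * sqrt(2 / 9999)
  expect_lt(abs(var(paths[, 10]) - v_want), 3 * se_var)
  v5 <- var(paths[, 5])
  expect_lt(abs(v5 - 5 * dm$innovation_sd^2), 3 * 5 * dm$innovation_sd^2 * sqrt(2 / 9999))
})

test_that("municipal forecasts anchor at the jump-off schedule", {
  tr <- make_rank1_surface(seed = 86)
  fit <- fit_lc(tr$surface)
  muni <- standard_schedule("male") + 0.2
  fc <- municipal_forecast(muni, fit, horizon = 5, n_sims = 50, seed = 87)
  expect_equal(unname(fc$rate_q["q50", 1, ]), exp(muni), tolerance = 1e-12)
  expect_equal(unname(fc$rate_q["q2.5", 1, ]), exp(muni), tolerance = 1e-12)
  expect_equal(unname(fc$rate_q["q97.5", 1, ]), exp(muni), tolerance = 1e-12)
  expect_error(municipal_forecast(muni, fit, horizon = 5, n_sims = 10,
                                  k_paths = forecast_k(fit, 3, 10, 1)),
               "beyond simulated paths")
})

test_that("uniform age response propagates the index decline equally", {
  tr <- make_rank1_surface(seed = 88)
  fit <- fit_lc(tr$surface)
  fit$bx <- rep(1 / 100, 100)
  paths <- forecast_k(fit, horizon = 10, n_sims = 3, seed = 89,
                      drift_model = list(drift = -2, innovation_sd = 0))
  muni <- standard_schedule("female")
  fc <- municipal_forecast(muni, fit, horizon = 10, k_paths = paths)
  # every age declines by drift/100 per year
  lr10 <- log(fc$rate_q["q50", 11, ])
  expect_equal(unname(lr10), muni + 10 * (-2) / 100, tolerance = 1e-10)
})

test_that("municipalities sharing a region keep their log-rate gap", {
  tr <- make_rank1_surface(seed = 90)
  fit <- fit_lc(tr$surface)
  paths <- forecast_k(fit, horizon = 8, n_sims = 40, seed = 91)
  m1 <- standard_schedule("male")
  m2 <- m1 + 0.3
  f1 <- municipal_forecast(m1, fit, horizon = 8, k_paths = paths)
  f2 <- municipal_forecast(m2, fit, horizon = 8, k_paths = paths)
  for (q in c("q2.5", "q50", "q97.5")) {
    expect_equal(log(f2$rate_q[q, 9, ]) - log(f1$rate_q[q, 9, ]),
                 rep(0.3, 100), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("noisy surfaces still recover the age response and drift", {
  set.seed(92)
  x <- age_grid()
  bx <- exp(-x / 35); bx <- bx / sum(bx)
  n_years <- 40
  kt <- cumsum(c(0, rnorm(n_years - 1, -1.0, 0.3))); kt <- kt - mean(kt)
  ax <- standard_schedule("male")
  surf <- matrix(ax, n_years, 100, byrow = TRUE) + outer(kt, bx) +
    matrix(rnorm(n_years * 100, 0, 0.05), n_years, 100)
  fit <- fit_lc(surf)
  expect_gt(cor(fit$bx, bx), 0.99)
  dm <- fit_drift(fit)
  dm_true <- fit_drift(kt)
  se <- dm$innovation_sd / sqrt(n_years - 1)
  expect_lt(abs(dm$drift - dm_true$drift), 2 * se + 0.05)
})

test_that("e0 forecast bands widen with the horizon under innovation noise", {
  tr <- make_rank1_surface(seed = 93)
  fit <- fit_lc(tr$surface)
  paths <- forecast_k(fit, horizon = 15, n_sims = 400, seed = 94,
                      drift_model = list(drift = -0.6, innovation_sd = 0.8))
  fc <- municipal_forecast(standard_schedule("male"), fit, horizon = 15,
                           k_paths = paths)
  width <- fc$e0_q["q97.5", ] - fc$e0_q["q2.5", ]
  expect_equal(unname(width[1]), 0, tolerance = 1e-12)
  expect_gt(width[16], width[2])
  expect_gt(width[8], width[2])
})
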