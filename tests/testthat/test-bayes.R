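test_that("with full coverage the likelihood term reduces to the Poisson one", {
  std <- standard_schedule("male")
  set.seed(41)
  N <- rep(1e3, 100)
  D <- rpois(100, N * exp(std))
  cov1 <- coverage_prior(c(1, 1), c(1, 1))  # uniform: finite density at pi = 1
  ap <- alpha_prior()
  a1 <- rep(0.1, 7); a2 <- rep(-0.2, 7)
  B <- topals_basis()
  pois_ll <- function(a) {
    lam <- std + drop(B %*% a)
    sum(D * lam - N * exp(lam))
  }
  # pi = 1 in both blocks: log-posterior differences in alpha equal Poisson
  # log-likelihood differences (the prior-on-pi constant cancels)
  d_post <- log_posterior(a1, c(1, 1), D, N, std, cov1, ap) -
    log_posterior(a2, c(1, 1), D, N, std, cov1, ap)
  d_pois <- (pois_ll(a1) + log_alpha_prior_for_test(a1, ap)) -
    (pois_ll(a2) + log_alpha_prior_for_test(a2, ap))
  expect_equal(d_post, d_pois, tolerance = 1e-10)
})

test_that("halving coverage is equivalent to halving the rate in the likelihood", {
  # the identifiability structure: only pi * exp(lambda) enters the mean
  std <- standard_schedule("female")
  set.seed(42)
  N <- rep(1e3, 100)
  R <- rpois(100, 0.5 * N * exp(std))
  cov1 <- coverage_prior(2, 2, breaks = 0)       # single block, flat-ish prior
  ap <- alpha_prior()
  lik_part <- function(alpha, pi) {
    log_posterior(alpha, pi, R, N, std, cov1, ap) -
      log_alpha_prior_for_test(alpha, ap) - dbeta(pi, 2, 2, log = TRUE)
  }
  a <- rep(0.1, 7)
  # (pi, lambda) -> (pi * c, lambda - log c) leaves the likelihood unchanged
  l1 <- lik_part(a, 0.8)
  l2 <- lik_part(a + log(0.8 / 0.5), 0.5)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("log posterior matches a hand-summed toy expression", {
  # 2 ages, scalar offset, one coverage block
  basis2 <- matrix(1, 2, 1)
  std2 <- c(-3, -2)
  R2 <- c(4, 7); N2 <- c(100, 200)
  cov1 <- coverage_prior(3, 2, breaks = 0)
  ap <- alpha_prior(level_sd = 1.5)
  a <- 0.4; p <- 0.7
  lam <- std2 + a
  by_hand <- sum(R2 * (lam + log(p)) - N2 * p * exp(lam)) +
    dnorm(a, 0, 1.5, log = TRUE) + dbeta(p, 3, 2, log = TRUE)
  expect_equal(
    log_posterior(a, p, R2, N2, std2, cov1, ap, basis = basis2),
    by_hand, tolerance = 1e-12)
  # out-of-range coverage is rejected, not an error
  expect_identical(
    log_posterior(a, 1.2, R2, N2, std2, cov1, ap, basis = basis2), -Inf)
  expect_identical(
    log_posterior(a, 0, R2, N2, std2, cov1, ap, basis = basis2), -Inf)
})

test_that("a point-mass coverage prior collapses the model to the TOPALS fit", {
  std <- standard_schedule("male")
  set.seed(43)
  N <- rep(1e5, 100)
  D <- rpois(100, N * exp(std + 0.1))
  post <- sample_posterior(D, N, std, complete_registration_prior(),
                           n_samples = 1500, burnin = 800, seed = 44)
  ft <- fit_topals(D, N, std)
  expect_lt(max(abs(posterior_median_log_rates(post) - ft$log_rates)), 0.05)
  expect_true(all(post$draws[, "pi_block1"] > 1 - 1e-6))
})

test_that("completeness is the unadjusted/adjusted rate ratio, clipped at one", {
  std <- standard_schedule("female")
  N <- rep(1e4, 100)
  unadj <- fit_topals(N * exp(std), N, std)
  # an adjusted posterior whose median log rates we control directly
  fake_post <- structure(list(lambda_q = rbind(
    q2.5 = std - 0.1, q50 = std, q97.5 = std + 0.1)), class = "rate_posterior")
  c_equal <- completeness_from_fits(unadj, fake_post)
  expect_equal(as.numeric(c_equal), rep(1, 100), tolerance = 1e-7)
  # adjusted rate doubled at one age -> completeness one half there
  lam_adj <- std; lam_adj[31] <- std[31] + log(2)
  fake_post$lambda_q["q50", ] <- lam_adj
  c_half <- completeness_from_fits(unadj, fake_post)
  expect_equal(as.numeric(c_half)[31], 0.5, tolerance = 1e-7)
  # adjusted below unadjusted -> clipped to 1 and counted
  lam_lo <- std - 0.2
  fake_post$lambda_q["q50", ] <- lam_lo
  c_clip <- completeness_from_fits(unadj, fake_post)
  expect_true(all(as.numeric(c_clip) <= 1))
  expect_equal(attr(c_clip, "n_clipped"), 100)
})

test_that("municipal adjustment divides rates by completeness", {
  std <- standard_schedule("male")
  N <- rep(1e4, 100)
  f <- fit_topals(N * exp(std), N, std)
  ones <- structure(rep(1, 100), class = "completeness_schedule")
  expect_equal(adjust_municipal(f, ones), f$log_rates)
  halves <- structure(rep(0.5, 100), class = "completeness_schedule")
  expect_equal(exp(adjust_municipal(f, halves)), 2 * exp(f$log_rates))
  cx <- structure(seq(0.5, 1, length.out = 100), class = "completeness_schedule")
  adj <- adjust_municipal(f, cx)
  expect_equal(exp(adj) / exp(f$log_rates), 1 / as.numeric(cx))
  # adjusted rates never fall below unadjusted
  expect_true(all(adj >= f$log_rates - 1e-12))
})

test_that("true adult completeness is recovered with informative priors", {
  std <- standard_schedule("male")
  blk <- age_blocks(c(0, 5))
  pr <- coverage_prior(c(0.8, 0.7) * 50, c(0.2, 0.3) * 50)
  set.seed(45)
  N <- rep(1e5, 100)
  Dc <- rpois(100, N * exp(std))
  R <- rbinom(100, Dc, c(0.8, 0.7)[blk])
  post <- sample_posterior(R, N, std, pr, n_samples = 1500, burnin = 1000,
                           seed = 46)
  expect_lt(abs(post$pi_q["q50", "pi_block2"] - 0.7), 0.1)
})

test_that("doubling exposures contracts the posterior credible intervals", {
  std <- standard_schedule("female")
  blk <- age_blocks(c(0, 5))
  pr <- coverage_prior(c(0.8, 0.75) * 40, c(0.2, 0.25) * 40)
  width <- function(mult, seed) {
    set.seed(seed)
    N <- rep(5e3 * mult, 100)
    Dc <- rpois(100, N * exp(std))
    R <- rbinom(100, Dc, c(0.8, 0.75)[blk])
    post <- sample_posterior(R, N, std, pr, n_samples = 1500, burnin = 800,
                             seed = seed + 1)
    mean(post$lambda_q["q97.5", ] - post$lambda_q["q2.5", ])
  }
  expect_lt(width(2, 47), width(1, 49))
})

test_that("multi-chain runs report split-Rhat near one", {
  std <- standard_schedule("male")
  set.seed(48)
  N <- rep(2e4, 100)
  D <- rpois(100, N * exp(std))
  pr <- coverage_prior(c(0.9, 0.85) * 60, c(0.1, 0.15) * 60)
  post <- sample_posterior(D, N, std, pr, n_samples = 1000, burnin = 800,
                           n_chains = 2, seed = 50)
  expect_false(is.null(post$rhat))
  expect_lt(max(post$rhat), 1.2)
})
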