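#' Beta priors on death-registration coverage by age block
#'
#' Registration coverage (completeness) pi is the fraction of true deaths
#' that enter the vital-registration system. It is modelled as
#' piecewise-constant over age blocks (default: child 0-4 and adult 5+),
#' with an independent Beta prior per block. A block whose Beta shapes sum
#' to `1e7` or more is treated as a point mass at the prior mean: the
#' sampler fixes pi there instead of sampling it, which recovers the
#' complete-registration model exactly.
#'
#' @param shape1,shape2 positive Beta shape vectors, one entry per block.
#' @param breaks lower block endpoints (first must be 0); default `c(0, 5)`.
#' @return a `coverage_prior` object.
#' @export
coverage_prior <- function(shape1, shape2, breaks = c(0, 5)) {
  stopifnot(length(shape1) == length(breaks), length(shape2) == length(breaks),
            all(shape1 > 0), all(shape2 > 0))
  structure(
    list(shape1 = shape1, shape2 = shape2, breaks = breaks,
         fixed = ifelse(shape1 + shape2 >= 1e7, shape1 / (shape1 + shape2), NA_real_)),
    class = "coverage_prior"
  )
}

#' @rdname coverage_prior
#' @details `complete_registration_prior()` is the degenerate prior pinning
#'   pi at 1 in every block.
#' @export
complete_registration_prior <- function(breaks = c(0, 5)) {
  coverage_prior(rep(1e8, length(breaks)), rep(1e-4, length(breaks)), breaks)
}

#' Gaussian smoothness prior on TOPALS offsets
#'
#' `f_alpha` places independent normals on the consecutive differences of
#' the spline offsets (the smoothness component, matching the TOPALS
#' penalty) and a weak normal on the first offset (the level component,
#' which makes the prior proper).
#'
#' @param level_sd standard deviation of the level prior on `alpha_1`.
#' @param diff_sd standard deviation on each difference
#'   `alpha_{j+1} - alpha_j`; the default `1/sqrt(2)` corresponds to a
#'   TOPALS smoothness penalty weight of 1.
#' @return an `alpha_prior` object.
#' @export
alpha_prior <- function(level_sd = 2, diff_sd = 1 / sqrt(2)) {
  stopifnot(level_sd > 0, diff_sd > 0)
  structure(list(level_sd = level_sd, diff_sd = diff_sd), class = "alpha_prior")
}

log_alpha_prior <- function(alpha, prior) {
  lp <- stats::dnorm(alpha[1], 0, prior$level_sd, log = TRUE)
  if (length(alpha) > 1) {
    lp <- lp + sum(stats::dnorm(diff(alpha), 0, prior$diff_sd, log = TRUE))
  }
  lp
}

#' Joint un-normalized log posterior of offsets and coverage
#'
#' Evaluates, up to an additive constant, the log of the integrand whose
#' pi-marginalization gives the posterior for adjusted rates: the thinned
#' Poisson likelihood of registered deaths
#' `sum_x [R_x (lambda_x(alpha) + log pi_b(x)) - N_x pi_b(x) exp(lambda_x(alpha))]`
#' plus the log smoothness prior on `alpha` and the log Beta priors on `pi`.
#' Because registered deaths are a binomial thinning of Poisson deaths, the
#' likelihood depends on `(alpha, pi)` only through `pi * exp(lambda)` in
#' the mean — the identifiability gap that the coverage prior resolves.
#'
#' @param alpha offset vector (length = columns of `basis`).
#' @param pi coverage values, one per prior block; values outside `(0, 1]`
#'   return `-Inf` rather than erroring.
#' @param registered,exposures age vectors of registered deaths and exposure.
#' @param standard log-mortality standard schedule.
#' @param coverage a [coverage_prior()].
#' @param prior_alpha an [alpha_prior()].
#' @param basis offset basis; default [topals_basis()].
#' @return scalar log density (up to a constant).
#' @export
log_posterior <- function(alpha, pi, registered, exposures, standard,
                          coverage, prior_alpha = alpha_prior(),
                          basis = topals_basis()) {
  stopifnot(length(pi) == length(coverage$breaks))
  if (any(pi <= 0) || any(pi > 1)) return(-Inf)
  blk <- age_blocks(coverage$breaks, ages = seq_len(nrow(basis)) - 1L)
  lam <- standard + drop(basis %*% alpha)
  pib <- pi[blk]
  ll <- sum(registered * (lam + log(pib)) - exposures * pib * exp(lam))
  lp_pi <- sum(ifelse(is.na(coverage$fixed),
                      stats::dbeta(pi, coverage$shape1, coverage$shape2, log = TRUE),
                      0))
  ll + log_alpha_prior(alpha, prior_alpha) + lp_pi
}

#' Sample the joint posterior of mortality offsets and coverage
#'
#' Adaptive random-walk Metropolis over `(alpha, log pi)` for one area and
#' sex. Because registered deaths only identify the product of coverage and
#' rate, the posterior concentrates on a ridge trading mortality level
#' against coverage; a Laplace step therefore shapes the proposal: the
#' chain starts at the posterior mode (found by quasi-Newton optimization)
#' with the mode's inverse Hessian as initial proposal covariance; during
#' burn-in the covariance is re-estimated from the chain's own history and
#' a global scale is tuned toward a 25% acceptance rate. After burn-in the
#' sampler alternates random-walk steps with independence draws from a
#' heavy-tailed multivariate-t fitted to the adapted covariance, which
#' decorrelate the chain along the weakly identified ridge direction.
#' Blocks with
#' a point-mass coverage prior are held fixed, so with all-pi-fixed priors
#' the model collapses to the penalized TOPALS fit of the registered
#' deaths.
#'
#' @param registered,exposures age vectors for the area/sex being fit.
#' @param standard log-mortality standard schedule.
#' @param coverage a [coverage_prior()].
#' @param prior_alpha an [alpha_prior()].
#' @param n_samples post-burn-in draws to keep (>= 1000 recommended for
#'   production use).
#' @param burnin adaptation iterations discarded; default `n_samples / 2`.
#' @param n_chains independent chains; split-Rhat is reported when > 1.
#' @param thin keep every `thin`-th draw.
#' @param seed RNG seed (NULL = use the current stream).
#' @param basis offset basis.
#' @return a `rate_posterior` object: `draws` (matrix of alpha and pi),
#'   `lambda_q` (2.5/50/97.5% posterior quantiles of log rates per age),
#'   `rate_q`, `pi_q`, `accept_rate`, `rhat`, `diagnostics`, `seed`.
#' @export
sample_posterior <- function(registered, exposures, standard, coverage,
                             prior_alpha = alpha_prior(),
                             n_samples = 2000L, burnin = NULL,
                             n_chains = 1L, thin = 1L, seed = NULL,
                             basis = topals_basis()) {
  stopifnot(n_samples >= 1)
  if (is.null(burnin)) burnin <- max(500L, n_samples %/% 2L)
  k <- ncol(basis)
  nb <- length(coverage$breaks)
  free <- which(is.na(coverage$fixed))
  pi_full <- function(theta_pi) {
    p <- coverage$fixed
    p[free] <- exp(theta_pi)
    p
  }
  lpost <- function(theta) {
    log_posterior(theta[seq_len(k)], pi_full(theta[-seq_len(k)]),
                  registered, exposures, standard, coverage, prior_alpha,
                  basis) +
      # log-transform Jacobian for the sampled blocks; log-pi space keeps
      # the level/coverage likelihood ridge exactly linear
      if (length(free)) sum(theta[-seq_len(k)]) else 0
  }
  init_fit <- fit_topals(registered, exposures, standard, basis = basis)
  prior_mean <- coverage$shape1 / (coverage$shape1 + coverage$shape2)
  pi0 <- pmin(pmax(prior_mean[free], 1e-6), 1 - 1e-6)
  # start alpha so that pi * exp(lambda) matches the registered rates
  peak_ages <- apply(basis, 2, which.max) - 1L  # age where each column peaks
  pi_init_full <- coverage$fixed
  pi_init_full[free] <- pi0
  knot_shift <- -log(pi_init_full[age_blocks(coverage$breaks, ages = peak_ages)])
  init <- c(init_fit$alpha + knot_shift, log(pi0))
  d <- length(init)

  ## Laplace step: posterior mode and curvature shape the proposal
  neg <- function(th) {
    v <- lpost(th)
    if (!is.finite(v)) 1e10 else -v
  }
  opt <- stats::optim(init, neg, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  mode <- opt$par
  H <- tryCatch(stats::optimHess(mode, neg), error = function(e) NULL)
  L <- NULL
  if (!is.null(H)) {
    Sig <- tryCatch(solve(H + diag(1e-8, d)), error = function(e) NULL)
    if (!is.null(Sig)) {
      L <- tryCatch(t(chol((Sig + t(Sig)) / 2)), error = function(e) NULL)
    }
  }
  if (is.null(L)) L <- diag(c(rep(0.05, k), rep(0.25, length(free))), d)

  chol_cov <- function(X) {
    S <- stats::cov(X) + diag(1e-10 + 1e-6 * mean(diag(stats::cov(X))), d)
    tryCatch(t(chol(S)), error = function(e) NULL)
  }

  run_chain <- function(chain_init) {
    Lc <- L
    log_g <- log(2.4 / sqrt(d))
    theta <- chain_init
    f <- lpost(theta)
    if (!is.finite(f)) { theta <- mode; f <- lpost(theta) }
    n_iter <- burnin + n_samples * thin
    keep <- matrix(NA_real_, n_samples, d)
    hist_burn <- matrix(NA_real_, burnin, d)
    acc <- 0L; acc_batch <- 0L; batch <- 0L; n_rw <- 0L
    refresh <- unique(pmax(round(burnin * c(0.33, 0.66)), 2L))
    ## burn-in: adaptive random walk, covariance learned from the chain
    for (i in seq_len(burnin)) {
      n_rw <- n_rw + 1L
      prop <- theta + drop(Lc %*% stats::rnorm(d)) * exp(log_g)
      fp <- lpost(prop)
      if (is.finite(fp) && log(stats::runif(1)) < fp - f) {
        theta <- prop; f <- fp
        acc_batch <- acc_batch + 1L
      }
      hist_burn[i, ] <- theta
      if (n_rw %% 25L == 0L) {
        batch <- batch + 1L
        log_g <- log_g + (acc_batch / 25 - 0.25) / sqrt(batch)
        acc_batch <- 0L
      }
      if (i %in% refresh && i > 10L) {
        Lnew <- chol_cov(hist_burn[seq_len(i), , drop = FALSE])
        if (!is.null(Lnew)) { Lc <- Lnew; log_g <- log(2.4 / sqrt(d)); batch <- 0L }
      }
    }
    ## independence proposal: heavy-tailed t at the adapted moments
    tail_rows <- hist_burn[seq.int(max(1L, burnin %/% 2L), burnin), , drop = FALSE]
    centre <- colMeans(tail_rows)
    Lt <- chol_cov(tail_rows)
    if (is.null(Lt)) Lt <- Lc
    Lt <- 1.2 * Lt
    t_df <- 4
    ldet_Lt <- sum(log(diag(Lt)))
    ldt <- function(th) {
      z <- forwardsolve(Lt, th - centre)
      -ldet_Lt - (t_df + d) / 2 * log1p(sum(z^2) / t_df)
    }
    q_theta <- ldt(theta)
    for (i in seq_len(n_samples * thin)) {
      if (stats::runif(1) < 0.5) {      # independence move
        z <- stats::rnorm(d) / sqrt(stats::rchisq(1, t_df) / t_df)
        prop <- centre + drop(Lt %*% z)
        fp <- lpost(prop)
        q_prop <- ldt(prop)
        if (is.finite(fp) &&
            log(stats::runif(1)) < (fp - f) + (q_theta - q_prop)) {
          theta <- prop; f <- fp; q_theta <- q_prop
        }
      } else {                          # random-walk move
        n_rw <- n_rw + 1L
        prop <- theta + drop(Lc %*% stats::rnorm(d)) * exp(log_g)
        fp <- lpost(prop)
        if (is.finite(fp) && log(stats::runif(1)) < fp - f) {
          theta <- prop; f <- fp; q_theta <- ldt(theta)
          acc <- acc + 1L
        }
      }
      if (i %% thin == 0L) keep[i %/% thin, ] <- theta
    }
    list(draws = keep, accept = acc / max(n_rw - burnin, 1L))
  }

  chains <- with_seed(seed, lapply(seq_len(n_chains), function(cc) {
    jitter <- if (cc == 1L) 0 else drop(L %*% stats::rnorm(d))
    run_chain(mode + jitter)
  }))

  draws_theta <- do.call(rbind, lapply(chains, `[[`, "draws"))
  accept <- mean(vapply(chains, `[[`, numeric(1), "accept"))
  rhat <- if (n_chains > 1L) {
    sapply(seq_len(d), function(j) {
      m <- sapply(chains, function(ch) mean(ch$draws[, j]))
      v <- sapply(chains, function(ch) stats::var(ch$draws[, j]))
      n <- nrow(chains[[1]]$draws)
      W <- mean(v); B <- n * stats::var(m)
      if (W <= 0) return(1)
      sqrt(((n - 1) / n * W + B / n) / W)
    })
  } else NULL

  alpha_draws <- draws_theta[, seq_len(k), drop = FALSE]
  pi_draws <- matrix(rep(coverage$fixed, each = nrow(draws_theta)),
                     nrow(draws_theta), nb)
  if (length(free)) {
    pi_draws[, free] <- exp(draws_theta[, k + seq_along(free), drop = FALSE])
  }
  colnames(alpha_draws) <- paste0("alpha", seq_len(k))
  colnames(pi_draws) <- paste0("pi_block", seq_len(nb))

  lam_draws <- alpha_draws %*% t(basis) +
    matrix(standard, nrow(alpha_draws), nrow(basis), byrow = TRUE)
  qs <- c(0.025, 0.5, 0.975)
  lambda_q <- apply(lam_draws, 2, stats::quantile, probs = qs)
  rownames(lambda_q) <- c("q2.5", "q50", "q97.5")
  pi_q <- apply(pi_draws, 2, stats::quantile, probs = qs)
  rownames(pi_q) <- c("q2.5", "q50", "q97.5")

  diagnostics <- character(0)
  if (accept < 0.1 || accept > 0.6) {
    msg <- sprintf("acceptance rate %.2f outside [0.1, 0.6]", accept)
    warning(msg)
    diagnostics <- c(diagnostics, msg)
  }

  structure(
    list(draws = cbind(alpha_draws, pi_draws), lambda_q = lambda_q,
         rate_q = exp(lambda_q), pi_q = pi_q, accept_rate = accept,
         rhat = rhat, diagnostics = diagnostics, seed = seed,
         coverage = coverage, basis = basis, standard = standard,
         n_chains = n_chains),
    class = "rate_posterior"
  )
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat(sprintf("<rate_posterior> %d draws, acceptance %.2f\n",
              nrow(x$draws), x$accept_rate))
  cat("  posterior median coverage:",
      paste(sprintf("%.3f", x$pi_q["q50", ]), collapse = " "), "\n")
  if (!is.null(x$rhat)) {
    cat(sprintf("  max split-Rhat %.3f over %d chains\n", max(x$rhat), x$n_chains))
  }
  invisible(x)
}

#' @export
summary.rate_posterior <- function(object, ...) {
  list(lambda_quantiles = object$lambda_q,
       rate_quantiles = object$rate_q,
       pi_quantiles = object$pi_q,
       accept_rate = object$accept_rate,
       rhat = object$rhat)
}

#' Posterior median log rates of a rate_posterior
#' @param x a `rate_posterior`.
#' @return age vector of posterior median log rates.
#' @export
posterior_median_log_rates <- function(x) unname(x$lambda_q["q50", ])

#' Registration completeness schedule from unadjusted and adjusted fits
#'
#' Completeness at each age is the ratio of the unadjusted rate (TOPALS fit
#' of registered deaths) to the adjusted rate (posterior median of the
#' coverage-corrected model): `c_x = exp(lambda_unadj - lambda_adj)`,
#' clipped into `(1e-6, 1]`. Values above 1 arise from stochastic noise and
#' are clipped; the number of clipped ages is recorded in attribute
#' `"n_clipped"`.
#'
#' @param unadjusted a `topals_fit` on registered deaths.
#' @param adjusted a `rate_posterior` for the same area/sex.
#' @return a `completeness_schedule`: numeric vector over the age grid in
#'   `(0, 1]`.
#' @export
completeness_from_fits <- function(unadjusted, adjusted) {
  lam_u <- unadjusted$log_rates
  lam_a <- posterior_median_log_rates(adjusted)
  stopifnot(length(lam_u) == length(lam_a))
  cx <- exp(lam_u - lam_a)
  n_clip <- sum(cx > 1) + sum(cx < 1e-6)
  cx <- pmin(pmax(cx, 1e-6), 1)
  structure(cx, class = "completeness_schedule", n_clipped = n_clip)
}

#' Adjust a municipal schedule with its microregion's completeness
#'
#' Under the assumption that under-registration is homogeneous across the
#' municipalities of a microregion, the municipal log rate is corrected by
#' the microregion completeness: `lambda_adj = lambda_muni - log(c_x)`.
#' Since `c_x <= 1`, adjusted rates never fall below the unadjusted ones.
#'
#' @param municipal_fit a `topals_fit` (or a numeric log-rate vector).
#' @param completeness the enveloping microregion's
#'   [completeness_from_fits()] schedule (same sex).
#' @return numeric age vector of adjusted log rates.
#' @export
adjust_municipal <- function(municipal_fit, completeness) {
  lam <- if (inherits(municipal_fit, "topals_fit")) municipal_fit$log_rates
         else as.numeric(municipal_fit)
  stopifnot(length(lam) == length(completeness))
  lam - log(as.numeric(completeness))
}
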