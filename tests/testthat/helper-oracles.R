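# Independent one-off implementations used as oracles. These are written as
# direct transcriptions of the defining formulas, deliberately sharing no
# code with the package internals they check.

# Marshall local EB estimator, straight from the moment formulas.
marshall_oracle <- function(r, n, nb_list) {
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    idx <- nb_list[[i]]
    m_i <- sum(r[idx] * n[idx]) / sum(n[idx])
    s2_i <- sum(n[idx] * (r[idx] - m_i)^2) / sum(n[idx])
    nbar_i <- mean(n[idx])
    A_i <- s2_i - m_i / nbar_i
    C_i <- if (A_i > 0) A_i / (A_i + m_i / n[i]) else 0
    out[i] <- m_i + C_i * (r[i] - m_i)
  }
  out
}

# Brute-force life-expectancy recursion for a flat hazard, summing
# person-years age by age with mid-interval deaths and a constant-hazard
# open tail.
e0_bruteforce_constant_hazard <- function(mu, n_ages = 100) {
  q <- mu / (1 + 0.5 * mu)
  l <- 1
  total <- 0
  for (x in seq_len(n_ages)) {
    d <- l * q
    total <- total + (l - d) + 0.5 * d
    l <- l - d
  }
  total + l / mu
}

# Log of the offset smoothness prior, re-transcribed.
log_alpha_prior_for_test <- function(alpha, ap) {
  dnorm(alpha[1], 0, ap$level_sd, log = TRUE) +
    sum(dnorm(diff(alpha), 0, ap$diff_sd, log = TRUE))
}

# Penalized TOPALS objective, re-transcribed for grid searches.
topals_objective <- function(alpha, deaths, exposures, standard, basis,
                             penalty_weight, ridge) {
  lam <- standard + as.vector(basis %*% alpha)
  loglik <- sum(deaths * lam - exposures * exp(lam))
  pen <- penalty_weight * sum(diff(alpha)^2) + ridge * sum(alpha^2)
  loglik - pen
}

# A small world shared by several pipeline tests (built once per test run).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_world(n_macro = 2, n_micro_per_macro = 2,
                                n_muni_per_micro = 4, exposure_scale = 3e4,
                                seed = 42)
    }
    cache
  }
})
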