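#' Fit the Lee-Carter model to a historical log-mortality surface
#'
#' Decomposes `log m_{x,t} = a_x + b_x k_t + eps_{x,t}` by singular value
#' decomposition: `a_x` is the per-age mean over years, the leading
#' singular pair of the centered surface gives `b_x` and `k_t`. The sign is
#' fixed so `sum(b_x) > 0`, then `b` is rescaled to `sum(b_x) = 1` with
#' `k_t` absorbing the scale, and `k_t` is recentered to `sum(k_t) = 0` with
#' the removed mean folded back into `a_x`. Residuals are retained for
#' diagnostics and never forecast, so `a + b k' + eps` reconstructs the
#' input surface exactly.
#'
#' @param surface `T x 100` matrix of log mortality rates, rows = years in
#'   increasing order (rownames taken as years when present).
#' @param years optional numeric year labels (default rownames or `1:T`).
#' @return an `lc_fit`: `ax`, `bx`, `kt`, `residuals`, `years`,
#'   `explained` (share of centered variance carried by the first pair).
#' @export
fit_lc <- function(surface, years = NULL) {
  surface <- as.matrix(surface)
  if (nrow(surface) < 3) stop("need at least 3 years")
  if (any(!is.finite(surface))) stop("surface must be finite")
  if (is.null(years)) {
    years <- if (!is.null(rownames(surface))) as.numeric(rownames(surface))
             else seq_len(nrow(surface))
  }
  ax <- colMeans(surface)
  M <- sweep(surface, 2, ax)
  sv <- svd(M)
  if (sv$d[1] < 1e-12) {
    warning("degenerate (constant-in-time) surface; bx set uniform")
    bx <- rep(1 / ncol(surface), ncol(surface))
    kt <- rep(0, nrow(surface))
  } else {
    bx <- sv$v[, 1]
    kt <- sv$u[, 1] * sv$d[1]
    if (sum(bx) < 0) { bx <- -bx; kt <- -kt }
    s <- sum(bx)
    bx <- bx / s
    kt <- kt * s
    kbar <- mean(kt)
    ax <- ax + bx * kbar
    kt <- kt - kbar
  }
  fitted <- matrix(ax, nrow(surface), ncol(surface), byrow = TRUE) +
    outer(kt, bx)
  structure(
    list(ax = ax, bx = bx, kt = kt, residuals = surface - fitted,
         years = years,
         explained = if (sv$d[1] > 0) sv$d[1]^2 / sum(sv$d^2) else NA_real_),
    class = "lc_fit"
  )
}

#' Random-walk-with-drift model for the mortality index
#'
#' Estimates the drift as `(k_T - k_1) / (T - 1)` and the innovation
#' standard deviation as the standard deviation of the first differences
#' about the drift, with divisor `T - 2` (one degree of freedom spent on
#' the drift).
#'
#' @param kfit an `lc_fit` (or a numeric `k_t` vector of length >= 3).
#' @return list `(drift, innovation_sd)`.
#' @export
fit_drift <- function(kfit) {
  kt <- if (inherits(kfit, "lc_fit")) kfit$kt else as.numeric(kfit)
  T_ <- length(kt)
  if (T_ < 3) stop("need at least 3 time points")
  drift <- (kt[T_] - kt[1]) / (T_ - 1)
  d <- diff(kt)
  innovation_sd <- sqrt(sum((d - drift)^2) / (T_ - 2))
  list(drift = drift, innovation_sd = innovation_sd)
}

#' Simulate future paths of the mortality index
#'
#' `k_{T+h} = k_T + h * drift + sum of h Gaussian innovations`.
#'
#' @param kfit an `lc_fit` or numeric `k_t` vector.
#' @param horizon number of years ahead (>= 1).
#' @param n_sims number of simulated paths.
#' @param seed RNG seed (NULL = current stream).
#' @param drift_model optional list `(drift, innovation_sd)` overriding
#'   [fit_drift()].
#' @return `n_sims x horizon` matrix of simulated `k` values
#'   (columns = horizons 1..horizon), with attribute `"k_last"`.
#' @export
forecast_k <- function(kfit, horizon, n_sims = 1000L, seed = NULL,
                       drift_model = NULL) {
  stopifnot(horizon >= 1, n_sims >= 1)
  kt <- if (inherits(kfit, "lc_fit")) kfit$kt else as.numeric(kfit)
  dm <- if (is.null(drift_model)) fit_drift(kt) else drift_model
  k_last <- kt[length(kt)]
  paths <- with_seed(seed, {
    innov <- matrix(stats::rnorm(n_sims * horizon, 0, dm$innovation_sd),
                    n_sims, horizon)
    k_last + matrix(seq_len(horizon) * dm$drift, n_sims, horizon, byrow = TRUE) +
      t(apply(innov, 1, cumsum))
  })
  if (horizon == 1L) paths <- matrix(paths, n_sims, 1L)
  attr(paths, "k_last") <- k_last
  attr(paths, "drift_model") <- dm
  paths
}

#' Probabilistic municipal mortality forecast from a regional Lee-Carter fit
#'
#' Adapts Lee-Carter to small areas with a single estimation year: the
#' municipality's adjusted log rates at the jump-off year play the role of
#' `a_x`, while the age response `b_x` and the index paths `k_t` come from
#' the enveloping region's fit. Propagation is anchored at the jump-off:
#' `log m_{x,T+h} = log m_x(muni, T) + b_x (k_{T+h} - k_T)`, so at horizon 0
#' every path reproduces the municipal schedule exactly and all forecast
#' uncertainty is inherited from the regional index.
#'
#' @param muni_log_rates municipal jump-off log rates on the full age grid.
#' @param regional_fit the region's `lc_fit`.
#' @param horizon years ahead to forecast.
#' @param n_sims simulated index paths.
#' @param seed RNG seed.
#' @param k_paths optional pre-simulated paths from [forecast_k()] (shared
#'   across the municipalities of one region so that their uncertainty is
#'   common); must have at least `horizon` columns.
#' @param jump_year calendar year of the jump-off (labelling only).
#' @param a0_rule infant separation rule for derived life tables.
#' @return a `municipal_forecast`: `rate_q` (3 x horizon+1 x 100 array of
#'   rate quantiles), `e0_q` (3 x horizon+1 e0 quantiles), per-path final
#'   summaries `final` (`e0`, `e65`, `median`, `iqr` vectors), `years`.
#' @export
municipal_forecast <- function(muni_log_rates, regional_fit, horizon,
                               n_sims = 1000L, seed = NULL, k_paths = NULL,
                               jump_year = 2010, a0_rule = "cd") {
  stopifnot(length(muni_log_rates) == length(regional_fit$bx))
  if (is.null(k_paths)) {
    k_paths <- forecast_k(regional_fit, horizon, n_sims, seed)
  }
  if (ncol(k_paths) < horizon) stop("horizon beyond simulated paths")
  n_sims <- nrow(k_paths)
  k_last <- attr(k_paths, "k_last")
  if (is.null(k_last)) k_last <- regional_fit$kt[length(regional_fit$kt)]
  bx <- regional_fit$bx
  n_age <- length(bx)
  qs <- c(0.025, 0.5, 0.975)
  years <- jump_year + 0:horizon
  rate_q <- array(NA_real_, c(3, horizon + 1, n_age),
                  dimnames = list(c("q2.5", "q50", "q97.5"), years,
                                  seq_len(n_age) - 1L))
  e0_q <- matrix(NA_real_, 3, horizon + 1,
                 dimnames = list(c("q2.5", "q50", "q97.5"), years))
  e0_paths <- matrix(NA_real_, n_sims, horizon + 1)
  final <- NULL
  for (h in 0:horizon) {
    log_m <- if (h == 0) {
      matrix(muni_log_rates, n_age, n_sims)
    } else {
      muni_log_rates + outer(bx, k_paths[, h] - k_last)
    }
    mx <- exp(log_m)                    # 100 x n_sims
    rate_q[, h + 1, ] <- apply(mx, 1, stats::quantile, probs = qs)
    s <- lt_summaries_from_mx_matrix(mx, a0_rule = a0_rule)
    e0_paths[, h + 1] <- s$e0
    e0_q[, h + 1] <- stats::quantile(s$e0, qs)
    if (h == horizon) final <- s
  }
  structure(
    list(rate_q = rate_q, e0_q = e0_q, e0_paths = e0_paths, final = final,
         years = years, bx = bx, jump_log_rates = muni_log_rates,
         n_sims = n_sims, seed = seed),
    class = "municipal_forecast"
  )
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> %d years x %d ages; first pair explains %.1f%% of centered variance\n",
              length(x$kt), length(x$bx), 100 * x$explained))
  dm <- fit_drift(x)
  cat(sprintf("  drift %.4f / year, innovation sd %.4f\n",
              dm$drift, dm$innovation_sd))
  invisible(x)
}

#' @export
coef.lc_fit <- function(object, ...) {
  list(ax = object$ax, bx = object$bx, kt = object$kt)
}

#' @export
plot.lc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  graphics::plot(age_grid(), x$ax, type = "l", xlab = "age", ylab = "ax")
  graphics::plot(age_grid(), x$bx, type = "l", xlab = "age", ylab = "bx")
  graphics::plot(x$years, x$kt, type = "l", xlab = "year", ylab = "kt")
  invisible(x)
}

#' @export
print.municipal_forecast <- function(x, ...) {
  h <- length(x$years) - 1
  cat(sprintf("<municipal_forecast> %d paths to %d (horizon %d)\n",
              x$n_sims, max(x$years), h))
  cat(sprintf("  e0: %.2f at jump-off -> median %.2f [%.2f, %.2f] at horizon\n",
              x$e0_q["q50", 1], x$e0_q["q50", h + 1],
              x$e0_q["q2.5", h + 1], x$e0_q["q97.5", h + 1]))
  invisible(x)
}

#' @export
plot.municipal_forecast <- function(x, ...) {
  graphics::matplot(x$years, t(x$e0_q), type = "l", lty = c(2, 1, 2),
                    col = "navy", xlab = "year",
                    ylab = "life expectancy at birth", ...)
  invisible(x)
}
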