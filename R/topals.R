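#' Linear B-spline offset basis for the TOPALS relational model
#'
#' TOPALS expresses an area's log-mortality schedule as a standard schedule
#' plus a piecewise-linear offset function, `lambda = lambda* + B alpha`.
#' Each column of `B` is the linear hat function of one knot; at any age the
#' row holds the interpolation weights of the two bracketing knots, so rows
#' sum to one and have at most two nonzero entries.
#'
#' @param knots strictly increasing exact ages; the default
#'   `c(0, 1, 10, 20, 40, 70, 100)` gives the 7-parameter basis.
#' @param ages evaluation ages (default the full single-year grid 0-99).
#' @return a `length(ages) x length(knots)` matrix with attribute `"knots"`.
#' @export
topals_basis <- function(knots = c(0, 1, 10, 20, 40, 70, 100),
                         ages = age_grid()) {
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (min(ages) < knots[1] || max(ages) > knots[length(knots)]) {
    stop("ages outside the knot span")
  }
  B <- matrix(0, length(ages), length(knots))
  j <- pmin(findInterval(ages, knots), length(knots) - 1L)
  left <- knots[j]; right <- knots[j + 1L]
  w <- (ages - left) / (right - left)
  B[cbind(seq_along(ages), j)] <- 1 - w
  B[cbind(seq_along(ages), j + 1L)] <- B[cbind(seq_along(ages), j + 1L)] + w
  attr(B, "knots") <- knots
  B
}

#' Fit a TOPALS mortality schedule by penalized Poisson likelihood
#'
#' Maximizes the Poisson log-likelihood of observed death counts
#' `sum_x [D_x lambda_x(alpha) - N_x exp(lambda_x(alpha))]` minus a
#' smoothness penalty `penalty_weight * sum_j (alpha_j - alpha_{j-1})^2` on
#' consecutive spline offsets and a small ridge `ridge * sum alpha_j^2` that
#' bounds the maximizer for degenerate inputs (e.g. zero deaths everywhere).
#' The penalized objective is concave, so a damped Newton iteration with
#' analytic gradient and Hessian converges monotonically.
#'
#' @param deaths,exposures numeric age vectors on the grid of `basis` rows;
#'   `deaths >= 0`, `exposures > 0`.
#' @param standard log-mortality standard schedule `lambda*` (same length).
#' @param penalty_weight non-negative smoothness penalty weight; default 1.
#' @param ridge non-negative ridge on the offset level; default 1e-4.
#' @param basis offset basis from [topals_basis()].
#' @param max_iter,tol Newton iteration cap and gradient max-norm tolerance.
#' @return a `topals_fit` object with elements `alpha`, `log_rates`,
#'   `standard`, `basis`, `penalty_weight`, `ridge`, `converged`,
#'   `objective_value`, `iterations`, `gradient_norm`.
#' @export
fit_topals <- function(deaths, exposures, standard, penalty_weight = 1,
                       ridge = 1e-4, basis = topals_basis(),
                       max_iter = 50L, tol = 1e-8) {
  stopifnot(length(deaths) == nrow(basis), length(exposures) == nrow(basis),
            length(standard) == nrow(basis))
  if (any(exposures <= 0)) stop("exposures must be positive")
  if (any(deaths < 0)) stop("deaths must be non-negative")
  if (penalty_weight < 0 || ridge < 0) stop("penalty weights must be >= 0")
  k <- ncol(basis)
  K <- if (k > 1) diff(diag(k)) else matrix(0, 0, 1)  # offset first differences
  P <- 2 * penalty_weight * crossprod(K) + 2 * ridge * diag(k)
  obj <- function(a) {
    lam <- standard + drop(basis %*% a)
    sum(deaths * lam - exposures * exp(lam)) -
      penalty_weight * sum((K %*% a)^2) - ridge * sum(a^2)
  }
  alpha <- rep(0, k)
  f <- obj(alpha)
  converged <- FALSE
  gnorm <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lam <- standard + drop(basis %*% alpha)
    mu <- exposures * exp(lam)
    g <- drop(crossprod(basis, deaths - mu)) - drop(P %*% alpha)
    gnorm <- max(abs(g))
    if (gnorm < tol) { converged <- TRUE; break }
    H <- -crossprod(basis, basis * mu) - P
    step <- tryCatch(solve(-H, g), error = function(e) g / max(1, sum(mu)))
    # damping: halve until the concave objective increases
    t <- 1
    repeat {
      cand <- alpha + t * step
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      t <- t / 2
      if (t < 1e-12) { cand <- alpha; fc <- f; break }
    }
    alpha <- cand
    f <- fc
  }
  if (!converged) {
    lam <- standard + drop(basis %*% alpha)
    mu <- exposures * exp(lam)
    g <- drop(crossprod(basis, deaths - mu)) - drop(P %*% alpha)
    gnorm <- max(abs(g))
    converged <- gnorm < tol
  }
  structure(
    list(alpha = alpha, log_rates = standard + drop(basis %*% alpha),
         standard = standard, basis = basis, penalty_weight = penalty_weight,
         ridge = ridge, converged = converged, objective_value = f,
         iterations = it, gradient_norm = gnorm,
         deaths = deaths, exposures = exposures),
    class = "topals_fit"
  )
}

#' Fitted mortality rates of a TOPALS fit
#'
#' @param object a `topals_fit`.
#' @param ... unused.
#' @return strictly positive age vector of death rates `exp(lambda)`.
#' @export
fitted.topals_fit <- function(object, ...) exp(object$log_rates)

#' @rdname fitted.topals_fit
#' @param fit a `topals_fit`.
#' @export
fitted_rates <- function(fit) {
  if (!fit$converged) warning("TOPALS fit did not converge")
  exp(fit$log_rates)
}

#' @export
coef.topals_fit <- function(object, ...) object$alpha

#' @export
print.topals_fit <- function(x, ...) {
  cat("<topals_fit>", length(x$alpha), "spline offsets,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("in %d iterations\n", x$iterations))
  cat("  alpha:", paste(sprintf("% .4f", x$alpha), collapse = " "), "\n")
  cat(sprintf("  penalized log-likelihood: %.4f\n", x$objective_value))
  invisible(x)
}

#' @export
residuals.topals_fit <- function(object, ...) {
  # Pearson residuals of the Poisson counts
  mu <- object$exposures * exp(object$log_rates)
  (object$deaths - mu) / sqrt(pmax(mu, .Machine$double.eps))
}

#' @export
plot.topals_fit <- function(x, ...) {
  ages <- seq_len(nrow(x$basis)) - 1
  obs <- log(pmax(x$deaths, 0.5) / x$exposures)
  graphics::plot(ages, obs, pch = 16, cex = 0.5, col = "grey50",
                 xlab = "age", ylab = "log mortality rate", ...)
  graphics::lines(ages, x$standard, lty = 2)
  graphics::lines(ages, x$log_rates, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", c("observed", "standard", "fitted"),
                   lty = c(NA, 2, 1), pch = c(16, NA, NA),
                   col = c("grey50", "black", "firebrick"), bty = "n")
  invisible(x)
}
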