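#' Single-year life table from age-specific mortality rates
#'
#' Builds the standard period life-table columns on ages 0-99 with radix 1.
#' Death probabilities are `q_x = m_x / (1 + (1 - a_x) m_x)` with
#' `a_x = 0.5` (deaths mid-interval) at ages 1+ and an infant separation
#' factor `a_0` chosen by `a0_rule`: `"cd"` (default) uses the
#' Coale-Demeny-style rule `a_0 = 0.07 + 1.7 m_0` capped into
#' `[0.05, 0.35]`; `"midpoint"` uses `a_0 = 0.5`. The open interval beyond
#' age 99 is closed with a constant hazard equal to `m_99`:
#' `T_100 = l_100 / m_99`.
#'
#' @param mx positive, finite rate vector on the full age grid.
#' @param a0_rule infant separation convention, `"cd"` or `"midpoint"`.
#' @param a0 optional explicit override of `a_0`.
#' @return a `lifetable` data frame with columns
#'   `age, mx, ax, qx, lx, dx, Lx, Tx, ex` and attributes `l_tail`
#'   (`l_100`) and `T_tail` (`T_100`).
#' @export
lifetable_from_mx <- function(mx, a0_rule = c("cd", "midpoint"), a0 = NULL) {
  a0_rule <- match.arg(a0_rule)
  mx <- unname(as.numeric(mx))
  n <- length(mx)
  if (any(!is.finite(mx)) || any(mx <= 0)) stop("mx must be positive and finite")
  ax <- rep(0.5, n)
  if (is.null(a0)) {
    ax[1] <- if (a0_rule == "cd") min(max(0.07 + 1.7 * mx[1], 0.05), 0.35) else 0.5
  } else {
    ax[1] <- a0
  }
  qx <- pmin(mx / (1 + (1 - ax) * mx), 1)
  lx <- c(1, cumprod(1 - qx))          # length n + 1; lx[n+1] = survivors to 100
  dx <- lx[seq_len(n)] * qx
  Lx <- lx[-1] + ax * dx
  T_tail <- lx[n + 1] / mx[n]          # constant-hazard closure of the open tail
  Tx <- rev(cumsum(rev(Lx))) + T_tail
  ex <- ifelse(lx[seq_len(n)] > 0, Tx / lx[seq_len(n)], NA_real_)
  out <- data.frame(age = seq_len(n) - 1L, mx = mx, ax = ax, qx = qx,
                    lx = lx[seq_len(n)], dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  attr(out, "l_tail") <- lx[n + 1]
  attr(out, "T_tail") <- T_tail
  class(out) <- c("lifetable", "data.frame")
  out
}

#' Remaining life expectancy at an exact age
#'
#' @param lt a [lifetable_from_mx()] table.
#' @param age integer age in 0-99.
#' @return `T_age / l_age` in years.
#' @export
life_expectancy <- function(lt, age = 0L) {
  stopifnot(age >= 0, age <= 99)
  row <- which(lt$age == age)
  if (lt$lx[row] <= 0) stop("no survivors at age ", age)
  lt$Tx[row] / lt$lx[row]
}

#' Age at which the survivor function crosses a given fraction
#'
#' Returns the smallest real age where the linearly interpolated `l(x)`
#' equals `p * l_0`. If survival never falls to `p` by age 100 the function
#' returns 100 with attribute `"censored" = TRUE`.
#'
#' @param lt a life table.
#' @param p fraction of the radix, in (0, 1).
#' @return real-valued age (possibly with attribute `censored`).
#' @export
survivor_quantile <- function(lt, p) {
  stopifnot(p > 0, p < 1)
  lx <- c(lt$lx, attr(lt, "l_tail"))
  target <- p * lx[1]
  if (target >= lx[1]) return(0)
  below <- which(lx <= target)
  if (length(below) == 0L) {
    return(structure(100, censored = TRUE))
  }
  i <- below[1]                         # first index with lx <= target
  x_hi <- i - 1                         # age at that index
  x_lo <- x_hi - 1
  l_lo <- lx[i - 1]; l_hi <- lx[i]
  if (l_lo == l_hi) return(x_lo)
  x_lo + (l_lo - target) / (l_lo - l_hi)
}

#' Interquartile range of the life-table age at death
#'
#' Lifespan variability measured as the distance between the ages where the
#' survivor function crosses three quarters and one quarter of the radix:
#' `IQR = age(lx = 0.25 l_0) - age(lx = 0.75 l_0)`. Lower values mean
#' deaths more concentrated in age.
#'
#' @param lt a life table.
#' @return non-negative years.
#' @export
death_iqr <- function(lt) {
  as.numeric(survivor_quantile(lt, 0.25)) - as.numeric(survivor_quantile(lt, 0.75))
}

#' Median age at death
#'
#' @param lt a life table.
#' @return the age where `lx` crosses half the radix.
#' @export
median_age_at_death <- function(lt) as.numeric(survivor_quantile(lt, 0.5))

#' Coefficient of variation of life expectancy across areas
#'
#' Between-area convergence measure: population standard deviation divided
#' by the mean of the areas' life expectancies.
#'
#' @param values numeric vector of e0 values (>= 2 areas, positive mean).
#' @return CV as a fraction (multiply by 100 for percent).
#' @export
cv_across_areas <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m <= 0) stop("mean life expectancy must be positive")
  sqrt(mean((values - m)^2)) / m
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> ages 0-%d, e0 = %.2f years\n",
              max(x$age), x$ex[1]))
  print.data.frame(utils::head(x, 5), row.names = FALSE, digits = 4)
  cat("  ...\n")
  invisible(x)
}

#' @export
summary.lifetable <- function(object, ...) {
  c(e0 = life_expectancy(object, 0L),
    e65 = life_expectancy(object, 65L),
    median_age_at_death = median_age_at_death(object),
    death_iqr = death_iqr(object))
}

# Vectorized life-table summaries for a 100 x S matrix of rate schedules;
# used by the forecaster where per-path tables are needed in bulk.
lt_summaries_from_mx_matrix <- function(mx, a0_rule = "cd") {
  n <- nrow(mx); S <- ncol(mx)
  ax <- matrix(0.5, n, S)
  ax[1, ] <- if (a0_rule == "cd") pmin(pmax(0.07 + 1.7 * mx[1, ], 0.05), 0.35) else 0.5
  qx <- pmin(mx / (1 + (1 - ax) * mx), 1)
  log_sx <- apply(log1p(-pmin(qx, 1 - 1e-15)), 2, cumsum)
  lx <- rbind(1, exp(log_sx))           # (n+1) x S
  dx <- lx[seq_len(n), , drop = FALSE] * qx
  Lx <- lx[-1, , drop = FALSE] + ax * dx
  T_tail <- lx[n + 1, ] / mx[n, ]
  Tx <- apply(Lx[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE] +
    matrix(T_tail, n, S, byrow = TRUE)
  e0 <- Tx[1, ]
  e65 <- Tx[66, ] / lx[66, ]
  quant <- function(col_lx, p) {
    target <- p
    below <- which(col_lx <= target)
    if (length(below) == 0L) return(100)
    i <- below[1]
    if (i == 1L) return(0)
    l_lo <- col_lx[i - 1]; l_hi <- col_lx[i]
    (i - 2) + if (l_lo == l_hi) 0 else (l_lo - target) / (l_lo - l_hi)
  }
  med <- apply(lx, 2, quant, p = 0.5)
  iqr <- apply(lx, 2, quant, p = 0.25) - apply(lx, 2, quant, p = 0.75)
  list(e0 = e0, e65 = e65, median = med, iqr = iqr)
}
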