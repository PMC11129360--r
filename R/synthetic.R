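#' Default standard log-mortality schedule of the synthetic world
#'
#' A three-component hazard on ages 0-99: exponentially declining infant
#' and child mortality, a Gaussian young-adult hump (smaller for females),
#' and Gompertz senescent increase. Any positive 100-point schedule can be
#' used in its place.
#'
#' @param sex `"female"` or `"male"`.
#' @return log mortality rate vector over the age grid.
#' @export
standard_schedule <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  x <- age_grid()
  infant <- 0.015 * exp(-1.1 * x)
  hump <- if (sex == "male") 9e-4 * exp(-(x - 22)^2 / (2 * 8^2))
          else 2.5e-4 * exp(-(x - 22)^2 / (2 * 8^2))
  level <- if (sex == "male") 5e-5 else 3.2e-5
  senescent <- level * exp(0.095 * x)
  log(infant + hump + senescent)
}

#' Generate a balanced synthetic geographic hierarchy
#'
#' @param n_macro,n_micro_per_macro,n_muni_per_micro positive counts.
#' @param seed RNG seed (the default hierarchy is deterministic; the seed is
#'   accepted for interface uniformity).
#' @return a [geo_hierarchy()] with
#'   `n_macro * n_micro_per_macro * n_muni_per_micro` municipalities.
#' @export
generate_geography <- function(n_macro, n_micro_per_macro, n_muni_per_micro,
                               seed = NULL) {
  stopifnot(n_macro >= 1, n_micro_per_macro >= 1, n_muni_per_micro >= 1)
  macro <- sprintf("MA%02d", seq_len(n_macro))
  micro <- as.vector(t(outer(macro, seq_len(n_micro_per_macro),
                             function(a, b) sprintf("%s.MI%02d", a, b))))
  micro_macro <- rep(macro, each = n_micro_per_macro)
  muni <- as.vector(t(outer(micro, seq_len(n_muni_per_micro),
                            function(a, b) sprintf("%s.MU%02d", a, b))))
  geo_hierarchy(
    municipality_id = muni,
    microregion_id = rep(micro, each = n_muni_per_micro),
    macroregion_id = rep(micro_macro, each = n_muni_per_micro)
  )
}

#' Generate true municipal log-mortality schedules
#'
#' Each municipality's true schedule is the sex-specific standard plus a
#' linear-spline offset: a macroregion-level 7-vector drawn from
#' `N(0, macro_sd^2)` plus a smaller municipal 7-vector from
#' `N(0, muni_sd^2)`, mapped through the TOPALS basis.
#'
#' @param hierarchy a [geo_hierarchy()].
#' @param seed RNG seed.
#' @param macro_sd,muni_sd offset standard deviations (defaults 0.3, 0.1).
#' @param basis offset basis.
#' @return list with `log_rates` (`municipality x sex x age` array),
#'   `macro_alpha`, `muni_alpha` (the drawn offsets).
#' @export
generate_true_schedules <- function(hierarchy, seed = NULL, macro_sd = 0.3,
                                    muni_sd = 0.1, basis = topals_basis()) {
  k <- ncol(basis)
  munis <- hierarchy$municipality_id
  macros <- sort(unique(hierarchy$macroregion_id))
  with_seed(seed, {
    out <- array(NA_real_, c(length(munis), 2L, nrow(basis)),
                 dimnames = list(munis, sexes(), seq_len(nrow(basis)) - 1L))
    macro_alpha <- array(stats::rnorm(length(macros) * 2 * k, 0, macro_sd),
                         c(length(macros), 2L, k),
                         dimnames = list(macros, sexes(), NULL))
    muni_alpha <- array(stats::rnorm(length(munis) * 2 * k, 0, muni_sd),
                        c(length(munis), 2L, k),
                        dimnames = list(munis, sexes(), NULL))
    for (s in sexes()) {
      std <- standard_schedule(s)
      for (i in seq_along(munis)) {
        ma <- hierarchy$macroregion_id[i]
        a <- macro_alpha[ma, s, ] + muni_alpha[i, s, ]
        out[i, s, ] <- std + drop(basis %*% a)
      }
    }
    list(log_rates = out, macro_alpha = macro_alpha, muni_alpha = muni_alpha)
  })
}

#' Generate true registration-completeness schedules
#'
#' Completeness is piecewise-constant over the child (0-4) / adult (5+) age
#' blocks, constant within each microregion (matching the homogeneity
#' assumption of the municipal adjustment), with logit-normal variation
#' across microregions. `by_municipality = TRUE` adds municipal-level
#' variation on top, violating the homogeneity assumption for robustness
#' experiments.
#'
#' @param hierarchy a [geo_hierarchy()].
#' @param child,adult base completeness of each block, in (0, 1].
#' @param sd_logit between-microregion spread on the logit scale.
#' @param breaks age-block lower endpoints.
#' @param by_municipality add municipal-level logit noise (sd `sd_logit/2`).
#' @param seed RNG seed.
#' @return array `area x sex x age` of completeness fractions in (0, 1]
#'   (area = microregion, or municipality when `by_municipality`), plus
#'   attribute `"blocks"` with the per-block values.
#' @export
generate_completeness <- function(hierarchy, child = 0.75, adult = 0.85,
                                  sd_logit = 0.3, breaks = c(0, 5),
                                  by_municipality = FALSE, seed = NULL) {
  stopifnot(child > 0, child <= 1, adult > 0, adult <= 1)
  micros <- sort(unique(hierarchy$microregion_id))
  areas <- if (by_municipality) hierarchy$municipality_id else micros
  base <- c(child, adult)
  blk <- age_blocks(breaks)
  with_seed(seed, {
    arr <- array(NA_real_, c(length(areas), 2L, 100L),
                 dimnames = list(areas, sexes(), age_grid()))
    blocks <- array(NA_real_, c(length(areas), 2L, length(breaks)),
                    dimnames = list(areas, sexes(), NULL))
    for (i in seq_along(areas)) {
      for (s in seq_along(sexes())) {
        shift <- stats::rnorm(1, 0, sd_logit)
        extra <- if (by_municipality) stats::rnorm(1, 0, sd_logit / 2) else 0
        v <- stats::plogis(stats::qlogis(base) + shift + extra)
        v <- pmin(pmax(v, 1e-6), 1)
        blocks[i, s, ] <- v
        arr[i, s, ] <- v[blk]
      }
    }
    attr(arr, "blocks") <- blocks
    arr
  })
}

#' Generate complete and registered death panels
#'
#' Municipal total exposures are drawn log-normal (median `exposure_scale`)
#' and spread over ages by a fixed stable age pyramid (`w_x` proportional to
#' `exp(-0.03 x)`, split evenly between the sexes). Complete deaths are
#' Poisson with mean `exposure * exp(true log rate)`; registered deaths are
#' a binomial thinning of the complete deaths with the enveloping
#' microregion's completeness at that sex and age.
#'
#' @param truth output of [generate_true_schedules()].
#' @param hierarchy a [geo_hierarchy()].
#' @param exposure_scale median total municipal exposure (> 0).
#' @param completeness completeness array from [generate_completeness()]
#'   (microregion- or municipality-indexed); default complete registration.
#' @param dispersion log-scale sd of municipal totals (default 1).
#' @param seed RNG seed.
#' @return list of two [demographic_panel()]s, `complete` and `registered`.
#' @export
generate_observations <- function(truth, hierarchy, exposure_scale,
                                  completeness = NULL, dispersion = 1,
                                  seed = NULL) {
  stopifnot(exposure_scale > 0)
  munis <- hierarchy$municipality_id
  pyramid <- exp(-0.03 * age_grid())
  pyramid <- pyramid / sum(pyramid) / 2   # per sex
  with_seed(seed, {
    totals <- stats::rlnorm(length(munis), log(exposure_scale), dispersion)
    expo <- array(NA_real_, c(length(munis), 2L, 100L),
                  dimnames = list(munis, sexes(), age_grid()))
    dth <- expo
    reg <- expo
    for (i in seq_along(munis)) {
      cov_area <- if (is.null(completeness)) NULL
        else if (munis[i] %in% dimnames(completeness)[[1]]) munis[i]
        else hierarchy$microregion_id[i]
      for (s in sexes()) {
        n <- totals[i] * pyramid
        m <- exp(truth$log_rates[i, s, ])
        d <- stats::rpois(100L, n * m)
        pi_x <- if (is.null(completeness)) rep(1, 100L)
                else completeness[cov_area, s, ]
        r <- stats::rbinom(100L, d, pi_x)
        expo[i, s, ] <- n
        dth[i, s, ] <- d
        reg[i, s, ] <- r
      }
    }
    list(complete = demographic_panel(dth, expo, "municipality"),
         registered = demographic_panel(reg, expo, "municipality"))
  })
}

#' Generate regional historical log-mortality surfaces
#'
#' For each macroregion and sex, builds a `years x 100` surface with exact
#' Lee-Carter structure `a_x + b_x k_t` (optionally plus Gaussian noise):
#' `b_x` proportional to `exp(-x / 40)` normalized to sum 1 (mortality
#' declines faster at young ages), `k_t` a random walk with the requested
#' drift, recentered to `sum(k_t) = 0`, and `a_x` anchored so that the
#' final-year surface equals the macroregion's mean true schedule.
#'
#' @param truth output of [generate_true_schedules()].
#' @param hierarchy a [geo_hierarchy()].
#' @param n_years length of the history (default 61, e.g. 1950-2010).
#' @param drift per-year drift of `k_t`; a scalar, a named per-macroregion
#'   vector, or a `macroregion x sex` matrix (dimnames required) for
#'   sex-specific histories. Negative drift means declining mortality.
#' @param noise_sd sd of additive Gaussian disturbances (default 0 = exact
#'   rank-one structure).
#' @param walk_sd sd of the random-walk innovations of `k_t` (default 0 =
#'   deterministic linear index).
#' @param end_year calendar year of the last column (default 2010).
#' @param seed RNG seed.
#' @return named list per macroregion of named lists per sex, each with
#'   `surface` (years x ages, rownames = years), `ax`, `bx`, `kt`, `drift`.
#' @export
generate_regional_history <- function(truth, hierarchy, n_years = 61,
                                      drift = -1.5, noise_sd = 0,
                                      walk_sd = 0, end_year = 2010,
                                      seed = NULL) {
  stopifnot(n_years >= 3)
  macros <- sort(unique(hierarchy$macroregion_id))
  drift_for <- if (is.matrix(drift)) {
    if (!all(macros %in% rownames(drift)) || !all(sexes() %in% colnames(drift))) {
      stop("drift matrix must be named macroregion x sex")
    }
    function(ma, s) drift[ma, s]
  } else {
    drifts <- if (length(drift) == 1L) {
      stats::setNames(rep(drift, length(macros)), macros)
    } else {
      drift[macros]
    }
    if (anyNA(drifts)) stop("drift vector must name every macroregion")
    function(ma, s) drifts[[ma]]
  }
  x <- age_grid()
  bx <- exp(-x / 40); bx <- bx / sum(bx)
  years <- (end_year - n_years + 1):end_year
  with_seed(seed, {
    out <- lapply(macros, function(ma) {
      members <- hierarchy$macroregion_id == ma
      per_sex <- lapply(sexes(), function(s) {
        steps <- drift_for(ma, s) + stats::rnorm(n_years - 1, 0, walk_sd)
        kt_raw <- c(0, cumsum(steps))
        kt <- kt_raw - mean(kt_raw)
        # anchor: final-year surface equals the region's mean true schedule
        regional_2010 <- apply(truth$log_rates[members, s, , drop = FALSE],
                               3, mean)
        ax <- regional_2010 - bx * kt[n_years]
        surf <- matrix(ax, n_years, 100L, byrow = TRUE) + outer(kt, bx)
        if (noise_sd > 0) {
          surf <- surf + matrix(stats::rnorm(length(surf), 0, noise_sd),
                                n_years, 100L)
        }
        rownames(surf) <- years
        colnames(surf) <- x
        list(surface = surf, ax = ax, bx = bx, kt = kt, drift = drift_for(ma, s))
      })
      stats::setNames(per_sex, sexes())
    })
    stats::setNames(out, macros)
  })
}

#' Beta coverage priors from (or near) the synthetic truth
#'
#' Emits the per-microregion, per-sex, per-block Beta priors the Bayesian
#' stage consumes. `bias` shifts the prior mean on the logit scale
#' (misspecification scenario); `degenerate = TRUE` emits point-mass priors
#' at 1 regardless of the truth (complete-registration scenario).
#'
#' @param completeness array from [generate_completeness()] (microregion
#'   level).
#' @param concentration Beta prior sample size `shape1 + shape2`.
#' @param bias logit-scale shift of the prior mean (0 = well-specified).
#' @param degenerate emit point masses at 1.
#' @param breaks age-block lower endpoints.
#' @return data frame `microregion_id, sex, age_block, shape1, shape2`.
#' @export
generate_priors <- function(completeness, concentration = 100, bias = 0,
                            degenerate = FALSE, breaks = c(0, 5)) {
  blocks <- attr(completeness, "blocks")
  areas <- dimnames(completeness)[[1]]
  g <- expand.grid(microregion_id = areas, sex = sexes(),
                   age_block = seq_along(breaks),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (degenerate) {
    g$shape1 <- 1e8
    g$shape2 <- 1e-4
  } else {
    mu <- mapply(function(a, s, b) blocks[a, s, b],
                 g$microregion_id, g$sex, g$age_block)
    mu <- stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6)) + bias)
    g$shape1 <- mu * concentration
    g$shape2 <- (1 - mu) * concentration
  }
  g
}

#' Generate a complete synthetic study world
#'
#' Convenience wrapper tying the generators together with deterministic
#' child seeds: geography, true schedules, completeness, complete and
#' registered panels, regional history, and coverage priors.
#'
#' @param n_macro,n_micro_per_macro,n_muni_per_micro hierarchy shape.
#' @param exposure_scale median municipal exposure.
#' @param completeness_child,completeness_adult base completeness (set both
#'   to 1 with `prior_degenerate = TRUE` for the complete-registration
#'   world).
#' @param completeness_sd_logit between-microregion completeness spread.
#' @param macro_sd,muni_sd schedule offset sds.
#' @param n_years,drift,noise_sd,walk_sd history settings (see
#'   [generate_regional_history()]).
#' @param prior_concentration,prior_bias,prior_degenerate prior settings.
#' @param dispersion log-sd of municipal exposure totals.
#' @param seed master seed; all components derive child seeds from it.
#' @return list `hierarchy, truth, completeness, panels, history, priors,
#'   seed`.
#' @export
synthetic_world <- function(n_macro = 2, n_micro_per_macro = 5,
                            n_muni_per_micro = 8, exposure_scale = 5e4,
                            completeness_child = 0.75,
                            completeness_adult = 0.85,
                            completeness_sd_logit = 0.3,
                            macro_sd = 0.3, muni_sd = 0.1,
                            n_years = 61, drift = -1.5, noise_sd = 0,
                            walk_sd = 0, prior_concentration = 100,
                            prior_bias = 0, prior_degenerate = FALSE,
                            dispersion = 1, seed = 1) {
  hierarchy <- generate_geography(n_macro, n_micro_per_macro,
                                  n_muni_per_micro, seed = child_seed(seed, 1))
  truth <- generate_true_schedules(hierarchy, seed = child_seed(seed, 2),
                                   macro_sd = macro_sd, muni_sd = muni_sd)
  completeness <- generate_completeness(
    hierarchy, child = completeness_child, adult = completeness_adult,
    sd_logit = completeness_sd_logit, seed = child_seed(seed, 3))
  panels <- generate_observations(truth, hierarchy, exposure_scale,
                                  completeness = completeness,
                                  dispersion = dispersion,
                                  seed = child_seed(seed, 4))
  history <- generate_regional_history(truth, hierarchy, n_years = n_years,
                                       drift = drift, noise_sd = noise_sd,
                                       walk_sd = walk_sd,
                                       seed = child_seed(seed, 5))
  priors <- generate_priors(completeness,
                            concentration = prior_concentration,
                            bias = prior_bias,
                            degenerate = prior_degenerate)
  list(hierarchy = hierarchy, truth = truth, completeness = completeness,
       panels = panels, history = history, priors = priors, seed = seed)
}
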