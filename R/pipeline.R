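#' Flag areas with implausibly high life expectancy
#'
#' The boxplot upper-fence rule: an area is flagged when its e0 exceeds
#' `Q3 + multiplier * (Q3 - Q1)`, quartiles computed by linear interpolation
#' between order statistics (R's default type-7 convention). Applied per sex
#' independently by the pipeline.
#'
#' @param e0 named numeric vector of life expectancies (>= 4 values).
#' @param multiplier fence multiplier, default 1.5.
#' @return character vector of flagged area ids.
#' @export
flag_outliers <- function(e0, multiplier = 1.5) {
  if (length(e0) < 4) stop("need at least 4 values")
  q <- stats::quantile(e0, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + multiplier * (q[2] - q[1])
  names(e0)[e0 > fence]
}

#' Substitute flagged municipalities' schedules with their microregion's
#'
#' @param municipal_rates named list (or matrix with rownames) of municipal
#'   rate schedules.
#' @param flagged ids to substitute.
#' @param microregion_rates named list/matrix of microregion schedules.
#' @param hierarchy a [geo_hierarchy()].
#' @return `municipal_rates` with flagged entries replaced; attribute
#'   `"substitutions"` holds counts per macroregion.
#' @export
substitute_outliers <- function(municipal_rates, flagged, microregion_rates,
                                hierarchy) {
  get_sched <- function(obj, id) {
    s <- if (is.matrix(obj)) obj[id, ] else obj[[id]]
    if (is.null(s) || (is.matrix(obj) && !id %in% rownames(obj))) NULL else s
  }
  macro_of <- stats::setNames(hierarchy$macroregion_id, hierarchy$municipality_id)
  micro_of <- stats::setNames(hierarchy$microregion_id, hierarchy$municipality_id)
  counts <- table(factor(macro_of[flagged],
                         levels = sort(unique(hierarchy$macroregion_id))))
  for (id in flagged) {
    mic <- if (id %in% names(micro_of)) micro_of[[id]] else NA_character_
    if (is.na(mic)) stop("municipality ", id, " missing from hierarchy")
    repl <- get_sched(microregion_rates, mic)
    if (is.null(repl)) stop("no microregion schedule for ", mic)
    if (is.matrix(municipal_rates)) municipal_rates[id, ] <- repl
    else municipal_rates[[id]] <- repl
  }
  attr(municipal_rates, "substitutions") <- counts
  municipal_rates
}

#' Pipeline configuration
#'
#' Collects the tunables of [run_pipeline()]. Either `world` (a
#' [synthetic_world()] list) or the CSV paths (`deaths_path`,
#' `exposures_path`, `geo_path`, `priors_path`, `history`) must provide the
#' inputs.
#'
#' @param world a [synthetic_world()] output (preferred input form).
#' @param deaths_path,exposures_path,geo_path,priors_path CSV inputs used
#'   when `world` is NULL; `history` must then be supplied as the nested
#'   list of regional surfaces.
#' @param history regional history (overrides `world$history`).
#' @param standard optional per-sex list of standard log schedules; by
#'   default the pooled national registered rates.
#' @param knots TOPALS knots.
#' @param penalty_weight,ridge TOPALS penalty settings.
#' @param prior_alpha an [alpha_prior()].
#' @param n_samples,burnin,n_chains sampler settings per microregion fit.
#' @param smoothing apply Marshall smoothing (step 6).
#' @param outlier_multiplier fence multiplier of the substitution rule.
#' @param horizon forecast years beyond the jump-off (default 20, i.e.
#'   2010 -> 2030).
#' @param n_sims simulated index paths per region.
#' @param jump_year jump-off calendar year.
#' @param a0_rule infant separation rule for life tables.
#' @param seed master seed for the whole run.
#' @param out_dir optional directory where summary CSVs are written.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(world = NULL, deaths_path = NULL,
                            exposures_path = NULL, geo_path = NULL,
                            priors_path = NULL, history = NULL,
                            standard = NULL,
                            knots = c(0, 1, 10, 20, 40, 70, 100),
                            penalty_weight = 1, ridge = 1e-4,
                            prior_alpha = alpha_prior(),
                            n_samples = 1500L, burnin = 750L, n_chains = 1L,
                            smoothing = TRUE, outlier_multiplier = 1.5,
                            horizon = 20L, n_sims = 500L, jump_year = 2010,
                            a0_rule = "cd", seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(horizon >= 0, !is.null(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full small-area mortality pipeline
#'
#' Executes the nine stages end to end: (1) assemble municipal and
#' microregion panels; (2) Bayesian coverage-adjusted microregion fits;
#' (3) unadjusted TOPALS fits for microregions and municipalities;
#' (4) completeness schedules (unadjusted/adjusted rate ratio);
#' (5) municipal adjustment under within-microregion homogeneity;
#' (6) Marshall empirical-Bayes smoothing across microregion neighbours;
#' (7) upper-fence outlier substitution by microregion schedules;
#' (8) regional Lee-Carter fits on the historical surfaces; and
#' (9) municipal probabilistic forecasts sharing each region's simulated
#' index paths. Life tables and summary measures (e0, e65, median age at
#' death, death IQR; CV of e0 per macroregion; sex gaps) are computed for
#' the jump-off and horizon years.
#'
#' The run is fully reproducible from the config: a master seed initializes
#' the RNG and all stages consume one stream in a fixed order.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `municipal` (per municipality x sex
#'   summary table), `cv` (per group/sex/year CV of e0), `sex_gaps`,
#'   `substitutions`, `completeness`, `e0_trajectories`, `flagged`,
#'   `schedules` (final municipal rate matrices per sex), `lc_fits`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(as.integer(config$seed))
  basis <- topals_basis(config$knots)

  ## stage 1: panels
  if (!is.null(config$world)) {
    w <- config$world
    muni_panel <- w$panels$registered
    hierarchy <- w$hierarchy
    priors <- w$priors
    history <- if (is.null(config$history)) w$history else config$history
  } else {
    muni_panel <- read_panel(config$deaths_path, config$exposures_path,
                             config$geo_path)
    hierarchy <- attr(muni_panel, "hierarchy")
    priors <- utils::read.csv(config$priors_path, stringsAsFactors = FALSE)
    history <- config$history
    if (is.null(hierarchy) || is.null(history)) {
      stop("file-based runs need geo_path and history")
    }
  }
  micro_panel <- aggregate_panel(muni_panel, hierarchy, "microregion")
  micros <- micro_panel$areas
  munis <- muni_panel$areas
  macros <- sort(unique(hierarchy$macroregion_id))
  micro_of <- stats::setNames(hierarchy$microregion_id, hierarchy$municipality_id)
  macro_of <- stats::setNames(hierarchy$macroregion_id, hierarchy$municipality_id)

  ## national standard per sex: pooled registered rates
  standard <- config$standard
  if (is.null(standard)) {
    standard <- lapply(stats::setNames(sexes(), sexes()), function(s) {
      D <- colSums(muni_panel$deaths[, s, ])
      N <- colSums(muni_panel$exposures[, s, ])
      log((D + 0.5) / N)
    })
  }

  prior_for <- function(mic, s) {
    p <- priors[priors$microregion_id == mic & priors$sex == s, ]
    p <- p[order(p$age_block), ]
    if (nrow(p) == 0) stop("no priors for ", mic, "/", s)
    coverage_prior(p$shape1, p$shape2)
  }

  ## stages 2-4 per microregion x sex
  completeness <- list()
  micro_adj_rates <- list()   # posterior-median adjusted microregion rates
  for (s in sexes()) {
    comp_s <- matrix(NA_real_, length(micros), 100,
                     dimnames = list(micros, age_grid()))
    adj_s <- comp_s
    for (mic in micros) {
      cell <- panel_cell(micro_panel, mic, s)
      post <- sample_posterior(cell$deaths, cell$exposures, standard[[s]],
                               prior_for(mic, s),
                               prior_alpha = config$prior_alpha,
                               n_samples = config$n_samples,
                               burnin = config$burnin,
                               n_chains = config$n_chains,
                               basis = basis)
      unadj <- fit_topals(cell$deaths, cell$exposures, standard[[s]],
                          penalty_weight = config$penalty_weight,
                          ridge = config$ridge, basis = basis)
      comp_s[mic, ] <- completeness_from_fits(unadj, post)
      adj_s[mic, ] <- exp(posterior_median_log_rates(post))
    }
    completeness[[s]] <- comp_s
    micro_adj_rates[[s]] <- adj_s
  }

  ## stages 3 + 5: municipal TOPALS fits and completeness adjustment
  unadj_log <- list(); adj_log <- list()
  for (s in sexes()) {
    u <- matrix(NA_real_, length(munis), 100, dimnames = list(munis, age_grid()))
    a <- u
    for (mu in munis) {
      cell <- panel_cell(muni_panel, mu, s)
      f <- fit_topals(cell$deaths, cell$exposures, standard[[s]],
                      penalty_weight = config$penalty_weight,
                      ridge = config$ridge, basis = basis)
      u[mu, ] <- f$log_rates
      a[mu, ] <- adjust_municipal(f, completeness[[s]][micro_of[[mu]], ])
    }
    unadj_log[[s]] <- u
    adj_log[[s]] <- a
  }

  ## stage 6: Marshall smoothing per sex and age on the rate scale
  neighborhoods <- neighborhoods_from_hierarchy(hierarchy)
  smooth_rates <- list()
  for (s in sexes()) {
    r <- exp(adj_log[[s]])
    if (isTRUE(config$smoothing)) {
      ex <- muni_panel$exposures[, s, ]
      for (x in seq_len(100)) {
        r[, x] <- marshall_smooth(stats::setNames(r[, x], munis),
                                  stats::setNames(ex[, x], munis),
                                  neighborhoods)
      }
    }
    smooth_rates[[s]] <- r
  }

  ## stage 7: life tables, outlier flags, microregion substitution
  e0_of <- function(rates_mat, a0_rule) {
    apply(rates_mat, 1, function(m) life_expectancy(
      lifetable_from_mx(m, a0_rule = a0_rule), 0L))
  }
  final_rates <- list(); flagged <- list(); substitutions <- list()
  for (s in sexes()) {
    e0 <- e0_of(smooth_rates[[s]], config$a0_rule)
    fl <- flag_outliers(e0, config$outlier_multiplier)
    subbed <- substitute_outliers(smooth_rates[[s]], fl,
                                  micro_adj_rates[[s]], hierarchy)
    final_rates[[s]] <- subbed
    flagged[[s]] <- fl
    substitutions[[s]] <- attr(subbed, "substitutions")
  }

  ## stage 8: regional Lee-Carter fits
  lc_fits <- lapply(stats::setNames(macros, macros), function(ma) {
    lapply(stats::setNames(sexes(), sexes()), function(s) {
      fit_lc(history[[ma]][[s]]$surface)
    })
  })

  ## stage 9: municipal forecasts with shared regional index paths
  k_paths <- lapply(stats::setNames(macros, macros), function(ma) {
    lapply(stats::setNames(sexes(), sexes()), function(s) {
      forecast_k(lc_fits[[ma]][[s]], horizon = max(config$horizon, 1L),
                 n_sims = config$n_sims)
    })
  })
  forecasts <- list()
  for (s in sexes()) {
    forecasts[[s]] <- lapply(stats::setNames(munis, munis), function(mu) {
      municipal_forecast(log(final_rates[[s]][mu, ]),
                         lc_fits[[macro_of[[mu]]]][[s]],
                         horizon = config$horizon,
                         k_paths = k_paths[[macro_of[[mu]]]][[s]],
                         jump_year = config$jump_year,
                         a0_rule = config$a0_rule)
    })
  }

  ## summaries
  horizon_year <- config$jump_year + config$horizon
  municipal <- do.call(rbind, lapply(sexes(), function(s) {
    do.call(rbind, lapply(munis, function(mu) {
      lt <- lifetable_from_mx(final_rates[[s]][mu, ], a0_rule = config$a0_rule)
      fc <- forecasts[[s]][[mu]]
      h1 <- config$horizon + 1
      data.frame(
        municipality_id = mu, microregion_id = micro_of[[mu]],
        macroregion_id = macro_of[[mu]], sex = s,
        e0_unadjusted = life_expectancy(
          lifetable_from_mx(exp(unadj_log[[s]][mu, ]),
                            a0_rule = config$a0_rule), 0L),
        e0_adjusted = life_expectancy(
          lifetable_from_mx(exp(adj_log[[s]][mu, ]),
                            a0_rule = config$a0_rule), 0L),
        e0 = life_expectancy(lt, 0L),
        e65 = life_expectancy(lt, 65L),
        median_age_at_death = median_age_at_death(lt),
        death_iqr = death_iqr(lt),
        flagged = mu %in% flagged[[s]],
        e0_horizon_q2.5 = fc$e0_q["q2.5", h1],
        e0_horizon = fc$e0_q["q50", h1],
        e0_horizon_q97.5 = fc$e0_q["q97.5", h1],
        e65_horizon = stats::median(fc$final$e65),
        median_age_horizon = stats::median(fc$final$median),
        death_iqr_horizon = stats::median(fc$final$iqr),
        stringsAsFactors = FALSE
      )
    }))
  }))

  cv_tab <- do.call(rbind, lapply(sexes(), function(s) {
    sub <- municipal[municipal$sex == s, ]
    groups <- c(stats::setNames(macros, macros), all = "all")
    do.call(rbind, lapply(names(groups), function(g) {
      rows <- if (g == "all") sub else sub[sub$macroregion_id == g, ]
      data.frame(group = g, sex = s,
                 year = c(config$jump_year, horizon_year),
                 cv = c(cv_across_areas(rows$e0),
                        cv_across_areas(rows$e0_horizon)),
                 mean_death_iqr = c(mean(rows$death_iqr),
                                    mean(rows$death_iqr_horizon)),
                 stringsAsFactors = FALSE)
    }))
  }))

  sex_gaps <- do.call(rbind, lapply(c(macros, "all"), function(g) {
    rows <- if (g == "all") municipal else municipal[municipal$macroregion_id == g, ]
    fe <- rows[rows$sex == "female", ]
    ma <- rows[rows$sex == "male", ]
    data.frame(group = g, year = c(config$jump_year, horizon_year),
               gap = c(mean(fe$e0) - mean(ma$e0),
                       mean(fe$e0_horizon) - mean(ma$e0_horizon)),
               stringsAsFactors = FALSE)
  }))

  e0_traj <- do.call(rbind, lapply(sexes(), function(s) {
    do.call(rbind, lapply(munis, function(mu) {
      fc <- forecasts[[s]][[mu]]
      data.frame(municipality_id = mu, sex = s, year = fc$years,
                 e0_q2.5 = fc$e0_q["q2.5", ], e0 = fc$e0_q["q50", ],
                 e0_q97.5 = fc$e0_q["q97.5", ], stringsAsFactors = FALSE)
    }))
  }))

  subs_tab <- do.call(rbind, lapply(sexes(), function(s) {
    data.frame(sex = s, macroregion_id = names(substitutions[[s]]),
               n_substituted = as.integer(substitutions[[s]]),
               stringsAsFactors = FALSE)
  }))

  result <- structure(
    list(municipal = municipal, cv = cv_tab, sex_gaps = sex_gaps,
         substitutions = subs_tab, completeness = completeness,
         e0_trajectories = e0_traj, flagged = flagged,
         schedules = final_rates, lc_fits = lc_fits,
         manifest = list(seed = config$seed, jump_year = config$jump_year,
                         horizon = config$horizon, n_sims = config$n_sims,
                         n_municipalities = length(munis),
                         n_microregions = length(micros))),
    class = "pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(
      df, file.path(config$out_dir, f), row.names = FALSE)
    wr(round_df(municipal), "municipal.csv")
    wr(round_df(cv_tab), "cv.csv")
    wr(round_df(sex_gaps), "sex_gaps.csv")
    wr(subs_tab, "substitutions.csv")
    wr(round_df(e0_traj), "e0_trajectories.csv")
  }
  result
}

# fixed-precision numeric formatting so identical runs write identical bytes
round_df <- function(df, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pipeline_result> %d municipalities, %d microregions, seed %s\n",
              m$n_municipalities, m$n_microregions, m$seed))
  cat(sprintf("  jump-off %d, horizon %d years, %d index paths\n",
              m$jump_year, m$horizon, m$n_sims))
  for (s in sexes()) {
    rows <- x$municipal[x$municipal$sex == s, ]
    cat(sprintf("  %s: mean e0 %.2f (%d) -> %.2f (%d); %d substituted\n",
                s, mean(rows$e0), m$jump_year, mean(rows$e0_horizon),
                m$jump_year + m$horizon, sum(rows$flagged)))
  }
  invisible(x)
}
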