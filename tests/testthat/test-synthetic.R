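test_that("generated geography has the requested balanced shape", {
  h <- generate_geography(2, 3, 4, seed = 1)
  expect_equal(nrow(h), 24)
  expect_equal(length(unique(h$microregion_id)), 6)
  expect_equal(length(unique(h$macroregion_id)), 2)
  h1 <- generate_geography(1, 1, 1, seed = 1)
  expect_equal(nrow(h1), 1)
  expect_error(generate_geography(0, 1, 1), "not TRUE")
})

test_that("all generators are deterministic under a fixed seed", {
  w1 <- synthetic_world(n_macro = 1, n_micro_per_macro = 2,
                        n_muni_per_micro = 2, exposure_scale = 1e4, seed = 7)
  w2 <- synthetic_world(n_macro = 1, n_micro_per_macro = 2,
                        n_muni_per_micro = 2, exposure_scale = 1e4, seed = 7)
  expect_identical(w1$truth$log_rates, w2$truth$log_rates)
  expect_identical(w1$panels$registered$deaths, w2$panels$registered$deaths)
  expect_identical(w1$history, w2$history)
  expect_identical(w1$priors, w2$priors)
})

test_that("zero offset sds reproduce the standard schedule exactly", {
  h <- generate_geography(2, 2, 2, seed = 1)
  tr <- generate_true_schedules(h, seed = 2, macro_sd = 0, muni_sd = 0)
  for (s in sexes()) {
    expect_equal(unname(tr$log_rates[1, s, ]), standard_schedule(s))
    expect_equal(unname(tr$log_rates[8, s, ]), standard_schedule(s))
  }
})

test_that("true hazards are positive, finite and senescent-dominated", {
  h <- generate_geography(2, 2, 3, seed = 3)
  tr <- generate_true_schedules(h, seed = 4)
  expect_true(all(is.finite(tr$log_rates)))
  expect_true(all(exp(tr$log_rates) > 0))
  # default standard: old-age mortality far exceeds late-childhood mortality
  for (s in sexes()) {
    std <- exp(standard_schedule(s))
    expect_gt(std[100], std[11])
  }
})

test_that("complete registration makes registered deaths equal complete deaths", {
  h <- generate_geography(1, 2, 2, seed = 5)
  tr <- generate_true_schedules(h, seed = 6)
  obs <- generate_observations(tr, h, exposure_scale = 1e4, seed = 7)
  expect_identical(obs$registered$deaths, obs$complete$deaths)
})

test_that("empirical rates at high exposure match truth within Poisson error", {
  h <- generate_geography(1, 1, 1, seed = 8)
  tr <- generate_true_schedules(h, seed = 9, macro_sd = 0, muni_sd = 0)
  obs <- generate_observations(tr, h, exposure_scale = 1e8, dispersion = 0,
                               seed = 10)
  d40 <- obs$complete$deaths[1, "male", "40"]
  n40 <- obs$complete$exposures[1, "male", "40"]
  lam_hat <- log(d40 / n40)
  se <- 1 / sqrt(d40)                   # Poisson log-rate standard error
  expect_lt(abs(lam_hat - tr$log_rates[1, "male", "40"]), 3 * se)
})

test_that("binomial thinning has the expected registered mean", {
  # thinned Poisson mean = N * m * pi; check at a high-count cell
  h <- generate_geography(1, 1, 1, seed = 11)
  tr <- generate_true_schedules(h, seed = 12, macro_sd = 0, muni_sd = 0)
  comp <- generate_completeness(h, child = 0.6, adult = 0.6, sd_logit = 0,
                                seed = 13)
  obs <- generate_observations(tr, h, exposure_scale = 1e8, dispersion = 0,
                               completeness = comp, seed = 14)
  r80 <- obs$registered$deaths[1, "female", "80"]
  mu <- obs$registered$exposures[1, "female", "80"] *
    exp(tr$log_rates[1, "female", "80"]) * 0.6
  expect_lt(abs(r80 - mu) / sqrt(mu), 4)
})

test_that("regional history has exact rank-one Lee-Carter structure", {
  h <- generate_geography(2, 2, 2, seed = 15)
  tr <- generate_true_schedules(h, seed = 16)
  hist <- generate_regional_history(tr, h, n_years = 20, drift = -1.0,
                                    seed = 17)
  surf <- hist[["MA01"]][["male"]]$surface
  centered <- sweep(surf, 2, colMeans(surf))
  sv <- svd(centered)$d
  expect_lt(sv[2] / sv[1], 1e-10)       # rank 1 after column centering
  expect_equal(sum(hist[["MA01"]][["male"]]$bx), 1, tolerance = 1e-12)
  expect_equal(sum(hist[["MA01"]][["male"]]$kt), 0, tolerance = 1e-12)
  # negative drift: age-averaged log rate decreases across years
  trend <- rowMeans(surf)
  expect_true(all(diff(trend) < 0))
  # anchoring: final year equals the regional mean true schedule
  members <- h$macroregion_id == "MA01"
  expect_equal(unname(surf[20, ]),
               unname(colMeans(tr$log_rates[members, "male", ])),
               tolerance = 1e-12)
})

test_that("priors are centered on truth when unbiased and pinned when degenerate", {
  h <- generate_geography(1, 3, 2, seed = 18)
  comp <- generate_completeness(h, child = 0.7, adult = 0.9, sd_logit = 0.2,
                                seed = 19)
  pr <- generate_priors(comp, concentration = 80)
  blocks <- attr(comp, "blocks")
  row <- pr[pr$microregion_id == pr$microregion_id[1] & pr$sex == "female" &
            pr$age_block == 2, ]
  expect_equal(row$shape1 / (row$shape1 + row$shape2),
               blocks[pr$microregion_id[1], "female", 2], tolerance = 1e-6)
  prd <- generate_priors(comp, degenerate = TRUE)
  expect_true(all(prd$shape1 + prd$shape2 >= 1e7))
  expect_true(all(prd$shape1 / (prd$shape1 + prd$shape2) > 1 - 1e-9))
})
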