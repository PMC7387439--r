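setup_default <- incubation_setup("S", "Glucose", t = 21)

test_that("background threshold is mean + 3 sample SD, with fixed override", {
  expect_equal(background_threshold(c(0.011, 0.011, 0.011)), 0.011)
  expect_equal(background_threshold(c(0.010, 0.011, 0.012)), 0.011 + 3 * 0.001)
  expect_equal(background_threshold(c(0.5, 0.9), fixed = 0.0124), 0.0124)
  expect_error(background_threshold(c(0.01, 0.02)), "3 background")
})

test_that("activity calls use strict exceedance of the thresholds", {
  meas <- tibble::tibble(
    F_C = c(0.0150, 0.0124, 0.0111, NA),
    F_N = c(0.00300, 0.00446, 0.00447, 0.5),
    defined_C = c(TRUE, TRUE, TRUE, FALSE),
    defined_N = TRUE
  )
  cls <- classify_active(meas, setup_default)
  expect_equal(cls$active_C, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cls$active_N, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cls$active, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("biomass growth rate inverts exponential growth and keeps sign", {
  ts <- tibble::tibble(day = c(0, 21), cells_per_cm3 = c(1e3, 1e3))
  expect_equal(biomass_growth_rate(ts, 21), 0)
  ts$cells_per_cm3[2] <- 1e3 * exp(0.284 * 21)
  expect_equal(biomass_growth_rate(ts, 21), 0.284)
  ts$cells_per_cm3[2] <- 500
  expect_lt(biomass_growth_rate(ts, 21), 0)
  expect_error(biomass_growth_rate(ts, 30), "no observation")
  expect_error(biomass_growth_rate(ts[2, ], 21), "day-0")
})

test_that("doubling time is ln2 / mu_B and undefined for non-growth", {
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(round(doubling_time(0.284), 1), 2.4)
  expect_equal(round(doubling_time(0.487), 1), 1.4)
  expect_true(is.na(doubling_time(0)))
  expect_true(is.na(doubling_time(-0.1)))
  mu <- c(0.05, 0.2, 1, 3)
  expect_equal(doubling_time(mu) * mu, rep(log(2), 4))
})

test_that("substrate rate clamps below natural abundance and flags saturation", {
  expect_equal(substrate_rate(0.0111, 0.0111, 0.99, 21), 0)
  expect_equal(substrate_rate(0.005, 0.0111, 0.99, 21), 0)  # noise clamp
  expect_equal(substrate_rate(0.4896, 0.011, 0.99, 21), 0.032,
               tolerance = 2e-3)
  expect_true(is.na(substrate_rate(0.99, 0.0111, 0.99, 21)))
  expect_true(is.na(substrate_rate(0.995, 0.0111, 0.99, 21)))
  expect_error(substrate_rate(0.5, 0.99, 0.0111, 21), "exceed")
  expect_error(substrate_rate(0.5, 0.0111, 0.99, 0), "positive")
})

test_that("originally active fraction follows f0 = 1 - A(1 - ft)", {
  expect_equal(original_active_fraction(10, 0.95, 100)$f_0, 0.5)
  expect_equal(original_active_fraction(1, 1, 100)$f_0, 1)
  r <- original_active_fraction(2, 0.4, 100)
  expect_true(is.na(r$f_0))
  expect_equal(r$reason, "inactive_exceeds_original")
  r2 <- original_active_fraction(10, 0.95, 5, min_rois = 10)
  expect_true(is.na(r2$f_0))
  expect_equal(r2$reason, "insufficient_rois")
})

test_that("determinable f0 stays in [0,1] and is monotone in ft", {
  grid <- tidyr::expand_grid(A = c(0.5, 1, 2, 5, 20, 100),
                             f_t = seq(0, 0.999, length.out = 40))
  res <- purrr::pmap_dfr(grid, function(A, f_t) {
    original_active_fraction(A, f_t, n_rois = 100)
  })
  det <- dplyr::filter(res, !is.na(f_0))
  expect_true(all(det$f_0 >= 0 & det$f_0 <= 1))
  expect_true(all(is.na(dplyr::filter(res, A * (1 - f_t) > 1)$f_0)))
  for (a in unique(det$A)) {
    f0s <- dplyr::filter(det, A == a)$f_0
    expect_true(all(diff(f0s) > 0))
  }
})

test_that("a fully active population with mu_S = mu_B closes the loop", {
  mu <- 0.15
  scen <- incubation_scenario(n_cells = 60, active_fraction = 1, mu_B = mu,
                              mu_S_C = mu, mu_S_N = mu,
                              timepoints = c(0, 21), seed = 10)
  sim <- sim_incubation(scen)
  day21 <- dplyr::filter(sim$cells, day == 21)
  meas <- tibble::tibble(roi_id = day21$cell_id,
                         F_C = day21$F_t_C, F_N = day21$F_t_N)
  setup <- incubation_setup("S", "Acetate", 21,
                            F_nat_C = scen$F_nat_C, F_nat_N = scen$F_nat_N)
  res <- analyze_incubation(meas, sim$counts, setup)
  expect_equal(res$mu_B, mu)
  g <- glance(res)
  expect_equal(g$mu_S_C, mu)
  expect_equal(g$mu_S_N, mu)
  expect_equal(res$f_t, 1)
  # all active and grown: inactive pool is zero, but ft = 1 leaves f0
  # undetermined unless A = 1
  expect_true(is.na(res$f_0))
  expect_equal(res$T_d * res$mu_B, log(2))
})

test_that("incubation summaries aggregate with nm/N.A. exclusion", {
  one <- tibble::tibble(sample_id = "X", substrate = "Glucose", t_days = 21,
                        mu_B = 0.2, T_d = log(2) / 0.2,
                        mu_S_C = 0.01, mu_S_N = 0.03, f_0 = 0.5)
  s <- summarize_incubations(one)
  expect_equal(s$aggregates$mean_T_d, log(2) / 0.2)
  expect_equal(s$aggregates$min_T_d, s$aggregates$max_T_d)
  expect_equal(s$aggregates$mean_f0, 0.5)
  expect_equal(s$aggregates$ratio_N_to_C, 3)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, mu_S_C = NA, f_0 = NA,
                                             mu_S_N = 0.05))
  s2 <- summarize_incubations(two)
  expect_equal(s2$aggregates$n_f0, 1)
  expect_equal(s2$aggregates$mean_f0, 0.5)
  # nm carbon rate excluded from the grand mean; nitrogen still counted
  expect_equal(s2$aggregates$ratio_N_to_C, mean(c(0.03, 0.05)) / 0.01)
  expect_error(summarize_incubations(list()), "no incubation")
})

test_that("published growth table is internally consistent under rounding", {
  cc <- check_doubling_consistency(table1_growth())
  expect_equal(nrow(cc), 24)
  expect_equal(sum(cc$exact), 20)       # exact round-equality
  expect_equal(sum(cc$consistent), 24)  # rounding-interval overlap
  # targeted rows are exact
  expect_true(all(cc$exact[round(cc$mu_B, 3) %in% c(0.284, 0.487)]))
})
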