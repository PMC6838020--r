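# Flux estimators: linear rates, steady-state fractions, the two closed-form
# flux formulas, the bootstrap, and the assembled flux_fit object.

test_that("linear rate fits recover exact slopes and flag bad input", {
  s <- data.frame(time_min = c(0, 10, 20), conc_mM = 50 - 1.47 * c(0, 10, 20))
  fit <- fit_linear_rate(s)
  expect_equal(fit$rate, 1.47, tolerance = 1e-12)
  expect_lt(fit$sd, 1e-10)
  expect_equal(fit_linear_rate(data.frame(time_min = 0:3,
                                          conc_mM = rep(4, 4)))$rate, 0)
  expect_error(fit_linear_rate(s[1:2, ]), "at least 3 points")
  expect_error(fit_linear_rate(data.frame(time_min = rep(1, 3),
                                          conc_mM = 1:3)), "time variance")
  # window subsetting: only pre-exhaustion points enter
  glc <- species_total(tc_fix_c1, "glucose")
  expect_equal(fit_linear_rate(glc, c(0, 34))$rate, 1.47, tolerance = 1e-9)
})

test_that("steady-state fractions average composition over the window", {
  m <- steady_state_fractions(tc_fix_c1, "fructose", 30)
  # with PPP active a little C1 label is lost as CO2, so m1 + m6 sits just
  # below 1; without PPP the C1 tracer is fully conserved on C1/C6
  expect_gt(m[["m1"]] + m[["m6"]], 0.9)
  expect_lt(m[["m1"]] + m[["m6"]], 1)
  expect_gt(m[["m6"]], 0)
  cfg0 <- flux_config(1.47, 0.68, f_PPP = 0, f_R = fx$c1$f_R, tracer = 1)
  m0 <- steady_state_fractions(run_resting_cell(cfg0, fx$times), "fructose")
  expect_equal(m0[["m1"]] + m0[["m6"]], 1, tolerance = 1e-9)
  m2 <- steady_state_fractions(tc_fix_c2, "fructose", 30)
  for (k in c("m1", "m2", "m3", "m5")) expect_gt(m2[[k]], 0)
  # time-constant composition is returned exactly
  expect_equal(unname(m2[2]),
               unname(steady_state_fractions(tc_fix_c2, "fructose", 60)[2]),
               tolerance = 1e-9)
  expect_error(steady_state_fractions(tc_fix_c1, "fructose", 119), ">= 2 time")
  expect_error(steady_state_fractions(tc_fix_c1, "mannitol"), "no points")
})

test_that("back-flux inversion matches the label-ratio formula", {
  expect_equal(estimate_backflux(0.9, 0, 1.47), 0)
  f_R <- estimate_backflux(0.9, 0.1, 1.47)
  expect_equal(f_R, 2 * 1.47 / (9 - 1))
  # oracle: substituting back must reproduce the ratio
  expect_equal((2 * 1.47 + f_R) / f_R, 0.9 / 0.1, tolerance = 1e-12)
  expect_error(estimate_backflux(0.5, 0.5, 1.47), "model violation")
  expect_error(estimate_backflux(0.1, 0.5, 1.47), "model violation")
  expect_error(estimate_backflux(0, 0.1, 1.47), "model violation|positive")
})

test_that("PPP formula evaluates its closed form and limits", {
  expect_equal(estimate_ppp(0, 0.9, 0.1, 1.47), 0)
  expect_equal(estimate_ppp(0.3, 0, 0, 1.47), 1.47)  # all-PPP limit
  expect_equal(estimate_ppp(0.02, 0.85, 0.10, 1.47),
               1.5 * 0.02 * 1.47 / (1.5 * 0.02 + 0.85 + 0.10))
  # scale-free in the mole fractions
  for (s in c(0.2, 1, 3.7))
    expect_equal(estimate_ppp(0.02 * s, 0.85 * s, 0.10 * s, 1.47),
                 estimate_ppp(0.02, 0.85, 0.10, 1.47), tolerance = 1e-12)
  expect_error(estimate_ppp(0, 0, 0, 1.47), "all of")
})

test_that("bootstrap SD is zero for degenerate data and grows with spread", {
  expect_equal(bootstrap_sd(mean, rep(3, 20), B = 100, seed = 1), 0)
  sds <- vapply(c(0.1, 1, 5), function(s) {
    set.seed(99)
    bootstrap_sd(mean, rnorm(30, sd = s), B = 200, seed = 4)
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("the assembled fit recovers the generating fluxes noiselessly", {
  fit <- fit_fluxes(tc_fix_c1, tc_fix_c2, B = 50)
  expect_s3_class(fit, "flux_fit")
  est <- coef(fit)
  expect_equal(est[["f_IN"]], 1.47, tolerance = 1e-9)
  expect_equal(est[["f_fru"]], 0.68, tolerance = 1e-9)
  expect_equal(est[["f_R"]], fx$c1$f_R, tolerance = 0.15)
  # slope SDs vanish on exact linear data
  expect_lt(fit$sd[["f_IN"]], 1e-9)
  # ratios as printed in the flux map
  expect_equal(fit$estimates[["r_back"]], 0.48, tolerance = 0.02)
  expect_equal(fit$estimates[["r_divert"]], 0.86, tolerance = 0.02)
  # the turnover-corrected PPP diagnostic undoes the formula's known bias
  expect_equal(fit$f_PPP_corrected, 0.08, tolerance = 0.015)
  # m2/m5 cross-check from the C2 tracer agrees with the primary estimate
  expect_equal(fit$f_R_crosscheck_c2, est[["f_R"]], tolerance = 0.05)
})

test_that("zero back-flux is inferred as exactly zero", {
  cfg <- function(tr) flux_config(1.47, 0.68, f_PPP = 0.08, f_R = 0, tracer = tr)
  fit <- fit_fluxes(run_resting_cell(cfg(1), fx$times),
                    run_resting_cell(cfg(2), fx$times), B = 50)
  expect_equal(coef(fit)[["f_R"]], 0)
  expect_equal(fit$estimates[["r_back"]], 0)
})

test_that("tracer mismatch and degenerate inputs are rejected", {
  expect_error(fit_fluxes(tc_fix_c2, tc_fix_c1, B = 50), "inconsistent tracers")
})

test_that("flux_fit methods expose the model consistently", {
  fit <- fit_fluxes(tc_fix_c1, tc_fix_c2, B = 50)
  expect_named(coef(fit), c("f_IN", "f_fru", "f_R", "f_PPP"))
  expect_output(print(fit), "f_IN")
  expect_output(print(summary(fit)), "cross-check")
  res <- residuals(fit)
  expect_length(res, 4)
  expect_true(all(vapply(res, function(r) all(abs(r) < 1e-9), TRUE)))
  # simulate() at the fitted fluxes reproduces the observed totals
  sim <- simulate(fit, nsim = 1, times = fx$times)[[1]]
  expect_equal(species_total(sim$c1, "fructose")$conc_mM,
               species_total(tc_fix_c1, "fructose")$conc_mM,
               tolerance = 0.02)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
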