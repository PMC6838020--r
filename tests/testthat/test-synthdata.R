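# Synthetic-data generation: noise model semantics, determinism, the shipped
# flux fixture, and TSV round-tripping.

test_that("zero noise reproduces the noiseless simulation exactly", {
  nm0 <- noise_model(relative_sd = 0, absolute_sd = 0, detection_limit = 0,
                     seed = 5)
  tc <- generate_experiment(fx$c1, nm0, fx$times)
  expect_equal(tc$conc_mM, tc_fix_c1$conc_mM, tolerance = 1e-15)
  tc2 <- generate_experiment(fx$c1, NULL, fx$times)
  expect_identical(tc2$conc_mM, tc_fix_c1$conc_mM)
})

test_that("noisy generation is seed-deterministic and censored", {
  a <- generate_experiment(fx$c2, noise_model(seed = 7), fx$times)
  b <- generate_experiment(fx$c2, noise_model(seed = 7), fx$times)
  expect_identical(a$conc_mM, b$conc_mM)
  c <- generate_experiment(fx$c2, noise_model(seed = 8), fx$times)
  expect_false(identical(a$conc_mM, c$conc_mM))
  # everything below the detection limit is reported as 0
  expect_true(all(a$conc_mM == 0 | a$conc_mM >= 0.1))
  hi <- generate_experiment(fx$c2, noise_model(detection_limit = 5, seed = 7),
                            fx$times)
  expect_true(all(hi$conc_mM == 0 | hi$conc_mM >= 5))
})

test_that("the reference fixture encodes the headline flux relations", {
  expect_equal(fx$c1$f_IN, 1.47)
  expect_equal(fx$c1$f_fru, 0.68)
  expect_equal(fx$c1$f_PPP, 0.08)
  expect_equal(fx$c1$glucose_0, 50)
  expect_equal(fx$times, c(0, 15, 30, 45, 60, 120))
  # back-flux is 48% of the forward glycolytic flux by construction
  expect_equal(fx$c1$f_R / ((fx$c1$f_IN - fx$c1$f_fru) + fx$c1$f_R), 0.48)
  # fructose diverts 86% of the net F6P->glycolysis flux
  expect_equal(round(fx$c1$f_fru / (fx$c1$f_IN - fx$c1$f_fru), 2), 0.86)
  # round trip: the simulated label ratio returns the configured f_R
  m <- steady_state_fractions(tc_fix_c1, "fructose")
  f_R_hat <- estimate_backflux(m[["m1"]], m[["m6"]], fx$c1$f_IN)
  expect_equal(f_R_hat, fx$c1$f_R, tolerance = 0.15)
})

test_that("main tracer products stay detectable under default noise", {
  tc <- generate_experiment(fx$c2, noise_model(seed = 2), fx$times)
  at60 <- tc[tc$time_min == 60 & tc$conc_mM >= 0.1, ]
  expect_true(any(at60$species == "fructose" & at60$pattern == "[2]"))
  expect_true(any(at60$species == "fructose" & at60$pattern == "[5]"))
  expect_true(any(at60$species == "ethanol"))
  pre <- tc[tc$time_min %in% c(15, 30), ]
  expect_true(all(pre$conc_mM[pre$species == "glucose"] >= 0.1))
})

test_that("time courses round-trip through TSV with metadata", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tc <- generate_experiment(fx$c2, noise_model(seed = 3), fx$times)
  write_timecourse(tc, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_timecourse(path)
  expect_equal(back$conc_mM, tc$conc_mM, tolerance = 1e-12)
  expect_identical(back$pattern, tc$pattern)
  expect_equal(attr(back, "tracer"), 2L)
  expect_equal(attr(back, "config")$f_R, fx$c2$f_R, tolerance = 1e-12)
  # malformed tables are rejected with the offending line
  bad <- tc[1:4, ]; bad$conc_mM[3] <- -1
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(bad, path2, sidecar = FALSE)
  expect_error(read_timecourse(path2), "line 4")
})
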