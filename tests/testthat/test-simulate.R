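# Forward simulator: flux configuration invariants, label routing,
# conservation, steady composition, and the Monte-Carlo cross-check.

test_that("flux_config enforces the model's flux constraints", {
  expect_error(flux_config(-1, 0), "f_IN")
  expect_error(flux_config(1, 0.5, sink_split = c(ethanol = 1)), "sink_split")
  ss <- default_sink_split(); ss["ethanol"] <- 0.9
  expect_error(flux_config(1, 0.5, sink_split = ss), "sum to 1")
  # f_fru + net PPP loss cannot exceed uptake
  expect_error(flux_config(1, 0.99, f_PPP = 0.2), "negative")
  expect_error(flux_config(1, 0.5, tracer = 3), "tracer")
  cfg <- flux_config(1.47, 0.68, 0.08, 0.5)
  expect_equal(cfg$f_glyc_net, 1.47 - 0.68 - 0.08 / 3)
})

test_that("label routing matches the flux topology", {
  times <- c(0, 15, 30)
  # identity route only: all fructose keeps the tracer position
  tc <- run_resting_cell(flux_config(1.0, 0.5, tracer = 1), times)
  fru <- tc[tc$species == "fructose" & tc$conc_mM > 0, ]
  expect_setequal(unique(fru$pattern), "[1]")
  # back-flux creates the reversed [6] label from a C1 tracer
  tc <- run_resting_cell(flux_config(1.0, 0.5, f_R = 0.4, tracer = 1), times)
  pats <- unique(tc$pattern[tc$species == "fructose" & tc$conc_mM > 0])
  expect_true(all(c("[1]", "[6]") %in% pats))
  # PPP creates [1] and [1,3] from a C2 tracer
  tc <- run_resting_cell(flux_config(1.0, 0.5, f_PPP = 0.1, tracer = 2), times)
  pats <- unique(tc$pattern[tc$species == "fructose" & tc$conc_mM > 1e-9])
  expect_true(all(c("[1]", "[1,3]", "[2]") %in% pats))
})

test_that("glucose depletes linearly until exhaustion", {
  glc <- species_total(tc_fix_c1, "glucose")
  expect_equal(glc$conc_mM[glc$time_min == 15], 50 - 1.47 * 15,
               tolerance = 1e-9)
  expect_equal(glc$conc_mM[glc$time_min == 30], 50 - 1.47 * 30,
               tolerance = 1e-9)
  # exhausted before 45 min; concentrations never negative
  expect_equal(glc$conc_mM[glc$time_min == 45], 0)
  expect_true(all(tc_fix_c1$conc_mM >= 0))
  expect_error(species_total(tc_fix_c1, "mannitol"), "not present")
})

test_that("labeled carbon and total carbon are conserved at every time", {
  n_carbons <- c(glucose = 6, fructose = 6, ethanol = 2, acetate = 2,
                 glycerol = 3, pyruvate = 3, dha = 3, tca = 3, co2 = 1)
  for (tc in list(tc_fix_c1, tc_fix_c2,
                  run_resting_cell(flux_config(1.2, 0.3, 0.15, 0.6, tracer = 2),
                                   c(0, 10, 40, 90)))) {
    lt <- label_totals(tc)
    expect_true(all(abs(lt$labeled_mM - 50) / 50 < 1e-6))
    tot <- tapply(tc$conc_mM * n_carbons[tc$species], tc$time_min, sum)
    expect_true(all(abs(tot - 300) / 300 < 1e-6))
  }
})

test_that("fructose composition is steady from 30 min on", {
  comp_at <- function(tc, t) {
    sub <- tc[tc$species == "fructose" & tc$time_min == t, ]
    stats::setNames(sub$conc_mM / sum(sub$conc_mM), sub$pattern)
  }
  for (tc in list(tc_fix_c1, tc_fix_c2)) {
    ref <- comp_at(tc, 30)
    for (t in c(45, 60, 120))
      expect_equal(comp_at(tc, t)[names(ref)], ref, tolerance = 1e-6)
  }
})

test_that("reversed label grows with back-flux and vanishes without it", {
  m6_at <- function(f_R) {
    cfg <- flux_config(1.47, 0.68, f_PPP = 0.08, f_R = f_R, tracer = 1)
    m <- steady_state_fractions(run_resting_cell(cfg, c(0, 15, 30, 45)),
                                "fructose")
    m[["m6"]]
  }
  m6 <- vapply(c(0, 0.2, 0.5, 0.8), m6_at, 0)
  expect_equal(m6[1], 0)
  expect_true(all(diff(m6) > 0))
})

test_that("molecule-tracking Monte-Carlo is seed-deterministic and normalized", {
  a <- mc_steady_fractions(fx$c1, n_molecules = 5000, rounds = 20, seed = 9)
  b <- mc_steady_fractions(fx$c1, n_molecules = 5000, rounds = 20, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  # reversed label present under back-flux
  expect_true("[6]" %in% names(a))
})
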