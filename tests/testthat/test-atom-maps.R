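# Carbon-map construction invariants, the default network's atom routing,
# and the lumped pentose phosphate cycle.

test_that("carbon_map rejects broken atom bookkeeping", {
  # substrate carbon mapped twice / not at all
  expect_error(carbon_map("bad", c(x = 2), c(y = 2),
                          c("(1,1)->(1,1)", "(1,1)->(1,2)")),
               "exactly one mapping entry")
  # product carbon with two preimages
  expect_error(carbon_map("bad", c(x = 2), c(y = 1),
                          c("(1,1)->(1,1)", "(1,2)->(1,1)")),
               "image of exactly one")
  # counts must balance including CO2
  expect_error(carbon_map("bad", c(x = 3), c(y = 3),
                          c("(1,1)->(CO2)", "(1,2)->(1,1)", "(1,3)->(1,2)")),
               "image of exactly one|balance")
  ok <- carbon_map("decarb", c(x = 3), c(y = 2),
                   c("(1,1)->(CO2)", "(1,2)->(1,1)", "(1,3)->(1,2)"))
  expect_s3_class(ok, "carbon_map")
  expect_equal(ok$n_co2, 1L)
})

test_that("map application pushes patterns through and reports CO2 label", {
  idmap <- carbon_map("id", c(hex = 6), c(hex2 = 6),
                      sprintf("(1,%d)->(1,%d)", 1:6, 1:6))
  out <- apply_carbon_map(idmap, list(pool_dist(c("010000" = 1))))
  expect_equal(unname(out$products[[1]]$frac[["010000"]]), 1)
  # condensation of a half-labeled triose pool with itself: independent 50/50
  net <- build_default_network()
  tri <- pool_dist(c("001" = 0.5, "000" = 0.5), species = "triose")
  f6p <- apply_carbon_map(net$reactions$aldolase_condensation,
                          list(tri, tri))$products[[1]]
  expect_equal(f6p$frac[c("100001", "100000", "000001", "000000")],
               c("100001" = 0.25, "100000" = 0.25,
                 "000001" = 0.25, "000000" = 0.25))
  # decarboxylation routes the labeled fraction of C1 to CO2
  pyr <- pool_dist(c("100" = 0.3, "010" = 0.7), species = "pyruvate")
  out <- apply_carbon_map(net$reactions$ethanol_formation, list(pyr))
  expect_equal(out$co2_labeled, 0.3)
  expect_error(apply_carbon_map(idmap, list(pool_dist(c("010" = 1)))),
               "expects 6 carbons")
})

test_that("default network routes tracer carbons as in the pathway", {
  net <- build_default_network()
  rx <- net$reactions
  # direct route keeps glucose C2 at fructose C2
  g2 <- pool_dist(c("[2]" = 1), 6, species = "glucose")
  f6p <- apply_carbon_map(rx$glucose_uptake, list(g2))$products[[1]]
  fru <- apply_carbon_map(rx$f6p_phosphatase, list(f6p))$products[[1]]
  expect_equal(unname(fru$frac[["010000"]]), 1)
  # glucose C1 and C6 both reach the same triose position (GAP C3)
  tri_of <- function(lab) {
    g <- pool_dist(stats::setNames(1, lab), 6, species = "glucose")
    x <- apply_carbon_map(rx$glucose_uptake, list(g))$products[[1]]
    cl <- apply_carbon_map(rx$fba_cleavage, list(x))
    mix_pools(cl$products, c(0.5, 0.5))
  }
  t1 <- tri_of("[1]"); t6 <- tri_of("[6]")
  expect_equal(t1$frac[["001"]], t6$frac[["001"]])
  expect_equal(unname(t1$frac[["001"]]), 0.5)
  # glycolytic route: glucose C2 -> pyruvate C2 -> ethanol C2
  tri2 <- tri_of("[2]")
  pyr <- apply_carbon_map(rx$pyruvate_formation, list(tri2))$products[[1]]
  expect_equal(unname(positional_fractions(pyr)[2]), 0.5)
  eth <- apply_carbon_map(rx$ethanol_formation, list(pyr))$products[[1]]
  expect_equal(unname(positional_fractions(eth)), c(0, 0.5))
  # and glucose C2 -> acetate C1 (carboxyl)
  ace <- apply_carbon_map(rx$acetate_formation, list(pyr))$products[[1]]
  expect_equal(unname(positional_fractions(ace)), c(0.5, 0))
})

test_that("label is conserved through every reaction map", {
  net <- build_default_network()
  set.seed(17)
  for (rx in net$reactions) {
    for (rep in 1:3) {
      ins <- lapply(seq_len(nrow(rx$substrates)), function(s)
        random_pool(rx$substrates$n_carbons[s],
                    species = rx$substrates$species[s]))
      out <- apply_carbon_map(rx, ins)
      lin <- sum(vapply(ins, labeled_carbons, 0))
      lout <- sum(vapply(out$products, labeled_carbons, 0)) + out$co2_labeled
      expect_lt(abs(lin - lout), 1e-12)
    }
  }
})

test_that("the PPP cycle reproduces the transketolase/transaldolase algebra", {
  # first cycle on [2-13C]hexose: 50/50 [1] and [1,3], CO2 unlabeled
  out <- ppp_cycle(pool_dist(c("[2]" = 1), 6))
  expect_setequal(names(out$f6p$frac), c("100000", "101000"))
  expect_equal(unname(out$f6p$frac[c("100000", "101000")]), c(0.5, 0.5))
  expect_equal(out$co2_labeled_fraction, 0)
  expect_equal(labeled_carbons(out$triose), 0)
  # [1-13C]hexose loses all label oxidatively (all three C1 carbons labeled)
  out1 <- ppp_cycle(pool_dist(c("[1]" = 1), 6))
  expect_equal(out1$co2_labeled_fraction, 1)
  expect_equal(labeled_carbons(out1$f6p), 0)
  # second cycle on [1,3-13C] makes the [2,3-13C] trace species
  out2 <- ppp_cycle(pool_dist(c("[1,3]" = 1), 6))
  expect_setequal(names(out2$f6p$frac), c("010000", "011000"))
  expect_equal(unname(out2$f6p$frac[["011000"]]), 0.5)
  expect_error(ppp_cycle(pool_dist(c("[1]" = 1), 3)), "6-carbon")
})

test_that("cleavage + equilibration + condensation reverses C1 to C6 symmetrically", {
  net <- build_default_network()
  rx <- net$reactions
  g <- pool_dist(c("[1]" = 1), 6, species = "glucose")
  x <- apply_carbon_map(rx$glucose_uptake, list(g))$products[[1]]
  tri <- mix_pools(apply_carbon_map(rx$fba_cleavage, list(x))$products,
                   c(0.5, 0.5))
  back <- apply_carbon_map(rx$aldolase_condensation,
                           list(tri, tri))$products[[1]]
  expect_equal(back$frac[["100000"]], back$frac[["000001"]])
  expect_equal(unname(back$frac[["100000"]]), 0.25)
})

test_that("networks serialize to text and back without loss", {
  net <- build_default_network()
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  net2 <- read_network(path)
  expect_setequal(names(net2$reactions), names(net$reactions))
  expect_equal(net2$species, net$species)
  for (nm in names(net$reactions))
    expect_equal(net2$reactions[[nm]]$mapping, net$reactions[[nm]]$mapping)
  # behaviour identical after round-trip
  out <- ppp_cycle(pool_dist(c("[2]" = 1), 6))
  h <- pool_dist(c("[2]" = 1), 6, species = "F6P")
  out2 <- apply_carbon_map(net2$reactions$ppp_cycle, list(h, h, h))
  expect_equal(mix_pools(out2$products[1:2], c(0.5, 0.5))$frac, out$f6p$frac)
})
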