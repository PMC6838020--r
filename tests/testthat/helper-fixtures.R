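# Shared fixtures: the reference flux set and its noiseless simulations,
# computed once per test run.

fx <- bombicola_fixture()
tc_fix_c1 <- run_resting_cell(fx$c1, fx$times)
tc_fix_c2 <- run_resting_cell(fx$c2, fx$times)

# uniform random sparse pool over n carbons (for property-style loops)
random_pool <- function(n_carbons, k = 3, species = NA_character_) {
  pats <- unique(replicate(k, paste(sample(c("0", "1"), n_carbons,
                                           replace = TRUE), collapse = "")))
  w <- stats::runif(length(pats))
  pool_dist(stats::setNames(w / sum(w), pats), n_carbons = n_carbons,
            species = species)
}
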