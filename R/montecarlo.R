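# Molecule-tracking Monte-Carlo oracle for the quasi-steady pool labeling.
#
# Independent stochastic check of the deterministic fixed point: N individual
# molecules, encoded as integer bitmasks (bit i-1 = C_i labeled), are routed
# through the same carbon maps with the same flux weights, drawing reaction
# partners at random from the pools.  Used in tests to validate the exact
# product-measure algebra against sampling.

bit_rev3 <- function(m)        # reverse the three low bits (DHAP <-> GAP)
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 2L), bitwAnd(m, 2L)),
         bitwShiftR(bitwAnd(m, 4L), 2L))

mc_upper_triose <- function(f6p) bit_rev3(bitwAnd(f6p, 7L))       # C1-C3 via DHAP
mc_lower_triose <- function(f6p) bitwAnd(bitwShiftR(f6p, 3L), 7L) # C4-C6
mc_condense <- function(t_dhap, t_gap)
  bitwOr(bit_rev3(t_dhap), bitwShiftL(t_gap, 3L))
# lumped PPP, per contributing hexose (C1 of each is lost as CO2)
mc_ppp_f6p_a <- function(h1, h2)
  bitwOr(bitwOr(bitwShiftR(bitwAnd(h1, 2L), 1L),          # h1 C2 -> C1
                bitwShiftR(bitwAnd(h1, 4L), 1L)),         # h1 C3 -> C2
         bitwOr(bitwAnd(h1, 56L),                         # h1 C4:C6 -> C4:C6
                bitwShiftL(bitwAnd(h2, 2L), 1L)))         # h2 C2 -> C3
mc_ppp_f6p_b <- function(h2, h3)
  bitwOr(bitwOr(bitwShiftR(bitwAnd(h3, 2L), 1L),          # h3 C2 -> C1
                bitwShiftR(bitwAnd(h3, 4L), 1L)),         # h3 C3 -> C2
         bitwAnd(h2, 60L))                                # h2 C3:C6 -> C3:C6
mc_ppp_triose <- function(h3) bitwAnd(bitwShiftR(h3, 3L), 7L)     # h3 C4:C6

#' Monte-Carlo estimate of the steady fructose labeling
#'
#' Tracks `n_molecules` individual molecules through the resting-cell network
#' at the configured fluxes and returns the sampled steady-state fructose
#' (= F6P) pattern fractions.  This sampler shares the atom maps with
#' [run_resting_cell()] but replaces the exact distribution algebra with
#' per-molecule random routing, so it serves as an independent stochastic
#' oracle: deterministic pattern fractions should agree within binomial
#' sampling error (`sqrt(p(1-p)/n)`).
#'
#' @param config a [flux_config].
#' @param n_molecules pool sample size.
#' @param rounds fixed-point iterations; the pool forgets its initial state
#'   geometrically at rate `f_IN / (f_IN + f_R + (2/3) f_PPP)` per round,
#'   so the default is far past convergence.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return named numeric vector of pattern fractions (bracket labels).
#' @export
mc_steady_fractions <- function(config, n_molecules = 1e5, rounds = 60,
                                seed = 1) {
  stopifnot(inherits(config, "flux_config"), n_molecules >= 1000)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- as.integer(n_molecules)
  gmask <- bitwShiftL(1L, config$tracer - 1L)
  x <- rep(gmask, n)
  y <- integer(n)
  f_gross <- config$f_glyc_net + config$f_R
  w_x <- c(glucose = config$f_IN, back = config$f_R, ppp = 2 / 3 * config$f_PPP)
  w_y <- c(split = 2 * f_gross, ppp = config$f_PPP / 3)
  p_x <- w_x / sum(w_x)
  p_y <- if (sum(w_y) > 0) w_y / sum(w_y) else c(split = 1, ppp = 0)
  draw <- function(pool) pool[sample.int(n, n, replace = TRUE)]

  for (r in seq_len(rounds)) {
    # triose pool refilled from the current F6P sample
    src_y <- sample.int(2L, n, replace = TRUE, prob = p_y)
    y_new <- integer(n)
    i <- src_y == 1L
    if (any(i)) {
      h <- draw(x)[i]
      upper <- stats::runif(sum(i)) < 0.5
      y_new[i] <- ifelse(upper, mc_upper_triose(h), mc_lower_triose(h))
    }
    i <- src_y == 2L
    if (any(i)) y_new[i] <- mc_ppp_triose(draw(x)[i])
    # F6P pool from glucose, condensation and PPP return
    src_x <- sample.int(3L, n, replace = TRUE, prob = p_x)
    x_new <- integer(n)
    x_new[src_x == 1L] <- gmask
    i <- src_x == 2L
    if (any(i)) x_new[i] <- mc_condense(draw(y_new)[i], draw(y_new)[i])
    i <- src_x == 3L
    if (any(i)) {
      k <- sum(i)
      a_side <- stats::runif(k) < 0.5
      h1 <- draw(x)[i]; h2 <- draw(x)[i]; h3 <- draw(x)[i]
      x_new[i] <- ifelse(a_side, mc_ppp_f6p_a(h1, h2), mc_ppp_f6p_b(h2, h3))
    }
    x <- x_new; y <- y_new
  }
  counts <- tabulate(x + 1L, nbins = 64L)
  frac <- counts / n
  names(frac) <- vapply(0:63, function(m)
    pattern_label(paste(ifelse(bitwAnd(m, bitwShiftL(1L, 0:5)) > 0, "1", "0"),
                        collapse = "")), "")
  frac[frac > 0]
}
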