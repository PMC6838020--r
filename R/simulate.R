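# Forward simulator of the resting-cell tracer experiment.
#
# Fluxes are zero-order while glucose remains (matching the observed
# approximately linear consumption) and stop at exhaustion.  Intracellular
# hexose-phosphate and triose pools are quasi-steady with zero holdup: their
# label distributions are the flux-weighted fixed point of their inputs, so
# extracellular species accumulate with time-invariant composition.

#' Flux configuration for a resting-cell tracer experiment
#'
#' All fluxes are zero-order rates in mM/min referred to the cell suspension.
#' `f_PPP` is counted in hexose equivalents entering the pentose phosphate
#' pathway; per the 3 hexose \eqn{\to} 2 F6P + 1 triose + 3 CO2 stoichiometry
#' the cycle returns `(2/3) f_PPP` hexoses and `(1/3) f_PPP` trioses.  The
#' net hexose flux from F6P to glycolysis is
#' `f_glyc_net = f_IN - f_fru - f_PPP/3` and must be non-negative.
#'
#' @param f_IN glucose uptake rate (mM/min).
#' @param f_fru fructose-6-phosphate \eqn{\to} fructose excretion rate (mM/min).
#' @param f_PPP hexose flux into the pentose phosphate pathway (mM/min).
#' @param f_R triose-pool \eqn{\to} F6P back-flux via reverse aldolase,
#'   in hexose units (mM/min).
#' @param sink_split named fractions routing the net triose consumption to
#'   `ethanol`, `glycerol`, `pyruvate`, `acetate`, `dha`
#'   (dihydroxyacetone) and `tca`; must sum to 1.
#' @param glucose_0 initial tracer concentration (mM).
#' @param tracer labeled glucose carbon, `1` or `2`.
#' @return an object of class `"flux_config"`.
#' @examples
#' flux_config(f_IN = 1.47, f_fru = 0.68, f_PPP = 0.08, f_R = 0.73, tracer = 2)
#' @export
flux_config <- function(f_IN, f_fru, f_PPP = 0, f_R = 0,
                        sink_split = default_sink_split(),
                        glucose_0 = 50, tracer = 2) {
  stopifnot(f_IN >= 0, f_fru >= 0, f_PPP >= 0, f_R >= 0, glucose_0 > 0)
  if (!tracer %in% c(1, 2)) stop("'tracer' must be 1 or 2")
  need <- c("ethanol", "glycerol", "pyruvate", "acetate", "dha", "tca")
  if (!all(need %in% names(sink_split)))
    stop("sink_split must name: ", paste(need, collapse = ", "))
  sink_split <- sink_split[need]
  if (any(sink_split < 0) || abs(sum(sink_split) - 1) > 1e-9)
    stop("sink_split fractions must be non-negative and sum to 1")
  f_glyc_net <- f_IN - f_fru - f_PPP / 3
  if (f_glyc_net < -1e-12)
    stop(sprintf(paste0("net F6P->glycolysis flux is negative (%.4f): ",
                        "f_IN must cover f_fru plus the net PPP loss"), f_glyc_net))
  structure(list(f_IN = f_IN, f_fru = f_fru, f_PPP = f_PPP, f_R = f_R,
                 sink_split = sink_split, glucose_0 = glucose_0,
                 tracer = as.integer(tracer),
                 f_glyc_net = max(f_glyc_net, 0)),
            class = "flux_config")
}

#' @rdname flux_config
#' @export
default_sink_split <- function()
  c(ethanol = 0.70, glycerol = 0.08, pyruvate = 0.08,
    acetate = 0.05, dha = 0.04, tca = 0.05)

#' @export
print.flux_config <- function(x, digits = 4, ...) {
  cat(sprintf("<flux_config: [%d-13C]glucose, %.5g mM>\n", x$tracer, x$glucose_0))
  print(round(c(f_IN = x$f_IN, f_fru = x$f_fru, f_PPP = x$f_PPP, f_R = x$f_R,
                f_glyc_net = x$f_glyc_net), digits))
  invisible(x)
}

tv_dist <- function(a, b) {
  keys <- union(names(a$frac), names(b$frac))
  fa <- ifelse(keys %in% names(a$frac), a$frac[keys], 0)
  fb <- ifelse(keys %in% names(b$frac), b$frac[keys], 0)
  sum(abs(fa - fb)) / 2
}

# Quasi-steady-state label distributions of the intracellular pools.
# The tracer composition of glucose never changes, so the F6P and triose
# distributions are time-invariant and solved once by fixed-point iteration:
#   F6P    <- mix(glucose f_IN, condensed trioses f_R, PPP return (2/3)f_PPP)
#   triose <- mix(cleaved F6P 2*(f_glyc_net + f_R), PPP return (1/3)f_PPP)
# The gross cleavage weight (net + back-flux) makes the recirculating
# F6P/triose cycle consistent; with f_PPP = 0 it yields the exact
# original:reversed label ratio (2 f_IN + f_R)/f_R.
steady_pools <- function(config, net = build_default_network(),
                         tol = 1e-13, max_iter = 1000L) {
  rx <- net$reactions
  g <- pool_dist(stats::setNames(1, sprintf("[%d]", config$tracer)),
                 n_carbons = 6, species = "glucose")
  x <- apply_carbon_map(rx$glucose_uptake, list(g))$products[[1]]
  split_x <- function(x) {
    cl <- apply_carbon_map(rx$fba_cleavage, list(x))
    mix_pools(cl$products, c(0.5, 0.5))
  }
  y <- split_x(x)
  f_gross <- config$f_glyc_net + config$f_R
  w_f6p <- c(config$f_IN, config$f_R, 2 / 3 * config$f_PPP)
  w_tri <- c(2 * f_gross, config$f_PPP / 3)
  g_f6p <- x  # glucose carried into F6P coordinates (identity map)
  ppp <- NULL
  for (it in seq_len(max_iter)) {
    if (config$f_PPP > 0)
      ppp <- apply_carbon_map(rx$ppp_cycle, list(x, x, x))
    src <- list(g_f6p)
    w <- w_f6p[1]
    if (config$f_R > 0) {
      src <- c(src, list(apply_carbon_map(rx$aldolase_condensation,
                                          list(y, y))$products[[1]]))
      w <- c(w, w_f6p[2])
    }
    if (config$f_PPP > 0) {
      src <- c(src, list(mix_pools(ppp$products[1:2], c(0.5, 0.5))))
      w <- c(w, w_f6p[3])
    }
    x_new <- mix_pools(src, w)
    tri_src <- list(split_x(x_new))
    tw <- w_tri[1]
    if (config$f_PPP > 0) {
      tri_src <- c(tri_src, list(ppp$products[[3]]))
      tw <- c(tw, w_tri[2])
    }
    if (sum(tw) <= 0) tw <- c(1, rep(0, length(tw) - 1))
    y_new <- mix_pools(tri_src, tw)
    delta <- tv_dist(x_new, x) + tv_dist(y_new, y)
    x <- x_new; y <- y_new
    if (delta < tol) break
  }
  # CO2 label release rates (mM labeled carbon / min)
  ppp_co2 <- if (config$f_PPP > 0) {
    out <- apply_carbon_map(rx$ppp_cycle, list(x, x, x))
    (config$f_PPP / 3) * out$co2_labeled
  } else 0
  m_y <- positional_fractions(y)
  list(f6p = x, triose = y, ppp_co2_labeled_rate = ppp_co2,
       pyr_c1_labeled = unname(m_y[1]))
}

sink_distributions <- function(y, net = build_default_network()) {
  rx <- net$reactions
  pyr <- apply_carbon_map(rx$pyruvate_formation, list(y))$products[[1]]
  list(pyruvate = pyr,
       ethanol = apply_carbon_map(rx$ethanol_formation, list(pyr))$products[[1]],
       acetate = apply_carbon_map(rx$acetate_formation, list(pyr))$products[[1]],
       glycerol = apply_carbon_map(rx$glycerol_formation, list(y))$products[[1]],
       dha = apply_carbon_map(rx$dha_formation, list(y))$products[[1]],
       tca = apply_carbon_map(rx$tca_entry, list(pyr))$products[[1]])
}

#' Simulate a resting-cell tracer time course
#'
#' Explicit time stepping (fixed step `dt` \eqn{\le} 0.1 min) of the
#' zero-order flux model.  Glucose depletes linearly at `f_IN` until
#' exhausted, after which all fluxes stop; fructose and the sink species
#' accumulate with the quasi-steady labeling compositions of the
#' intracellular pools; cumulative CO2 is tracked as labeled/unlabeled rows.
#'
#' @param config a [flux_config].
#' @param times sampling grid in minutes, sorted, starting at 0.
#' @param dt integration step (min), at most 0.1.
#' @return a `data.frame` time course with columns `time_min`, `species`,
#'   `pattern` (bracket label such as `"[1,3]"`) and `conc_mM`, one row per
#'   species \eqn{\times} pattern \eqn{\times} time; attributes `tracer` and
#'   `config` carry the generating setup.
#' @examples
#' cfg <- flux_config(f_IN = 1.47, f_fru = 0.68, f_R = 0.5, tracer = 1)
#' tc <- run_resting_cell(cfg, times = c(0, 15, 30, 45, 60, 120))
#' head(tc)
#' @export
run_resting_cell <- function(config, times = c(0, 15, 30, 45, 60, 120),
                             dt = 0.1) {
  stopifnot(inherits(config, "flux_config"))
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("'times' must be non-negative and strictly increasing")
  if (dt <= 0 || dt > 0.1) stop("'dt' must be in (0, 0.1]")
  net <- build_default_network()
  sp <- steady_pools(config, net)
  sinks <- sink_distributions(sp$triose, net)

  # sink production rates, mM of product per min
  s_total <- 2 * (config$f_IN - config$f_fru) - config$f_PPP / 3
  s_total <- max(s_total, 0)
  rate <- config$sink_split * s_total
  decarb <- unname(rate["ethanol"] + rate["acetate"])
  co2_rate <- config$f_PPP + decarb
  co2_lab_rate <- sp$ppp_co2_labeled_rate + decarb * sp$pyr_c1_labeled

  conc <- c(glucose = config$glucose_0, fructose = 0,
            ethanol = 0, glycerol = 0, pyruvate = 0, acetate = 0,
            dha = 0, tca = 0, co2 = 0, co2_labeled = 0)
  grow <- c(fructose = config$f_fru, rate[c("ethanol", "glycerol", "pyruvate",
                                            "acetate", "dha", "tca")],
            co2 = co2_rate, co2_labeled = co2_lab_rate)

  advance <- function(conc, h) {
    if (config$f_IN <= 0 || conc[["glucose"]] <= 0) return(conc)
    used <- min(config$f_IN * h, conc[["glucose"]])
    frac <- used / (config$f_IN * h)
    conc[names(grow)] <- conc[names(grow)] + grow * h * frac
    conc[["glucose"]] <- conc[["glucose"]] - used
    conc
  }

  dists <- c(list(glucose = pool_dist(
                    stats::setNames(1, sprintf("[%d]", config$tracer)),
                    n_carbons = 6, species = "glucose"),
                  fructose = {
                    f <- sp$f6p; f$species <- "fructose"; f
                  }),
             sinks)

  rows <- vector("list", length(times))
  t_cur <- 0
  for (k in seq_along(times)) {
    while (t_cur < times[k] - 1e-9) {
      h <- min(dt, times[k] - t_cur)
      conc <- advance(conc, h)
      t_cur <- t_cur + h
    }
    blocks <- lapply(names(dists), function(s) {
      d <- dists[[s]]
      data.frame(time_min = times[k], species = s,
                 pattern = vapply(names(d$frac), pattern_label, ""),
                 conc_mM = unname(conc[[s]] * d$frac))
    })
    co2 <- data.frame(time_min = times[k], species = "co2",
                      pattern = c("[1]", "[]"),
                      conc_mM = c(conc[["co2_labeled"]],
                                  conc[["co2"]] - conc[["co2_labeled"]]))
    rows[[k]] <- do.call(rbind, c(blocks, list(co2)))
  }
  tc <- do.call(rbind, rows)
  rownames(tc) <- NULL
  attr(tc, "tracer") <- config$tracer
  attr(tc, "config") <- config
  tc
}

#' Total concentration time series of one species
#'
#' Sums a time course over labeling patterns.
#'
#' @param tc a time course as returned by [run_resting_cell()] or
#'   [read_timecourse()].
#' @param species species name.
#' @return `data.frame` with columns `time_min` and `conc_mM`.
#' @export
species_total <- function(tc, species) {
  if (!species %in% tc$species)
    stop(sprintf("species '%s' not present in time course", species))
  sub <- tc[tc$species == species, ]
  agg <- stats::aggregate(conc_mM ~ time_min, data = sub, FUN = sum)
  agg[order(agg$time_min), ]
}
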