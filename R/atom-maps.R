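# Atom-to-atom carbon transition maps and the resting-cell network.
#
# A carbon map records, for one (possibly lumped) reaction, which substrate
# carbon becomes which product carbon; carbons lost by decarboxylation go to
# the reserved CO2 slot.  Mapping entries use the serialization syntax
# "(slot,pos)->(slot,pos)" with "(CO2)" as the reserved product.

#' Define a metabolite species
#'
#' @param name species identifier, unique within a network.
#' @param n_carbons number of carbon atoms (>= 1).
#' @param compartment one of `"extracellular"`, `"intracellular"`, `"sink"`.
#' @return a `species_def` list.
#' @export
species_def <- function(name, n_carbons,
                        compartment = c("intracellular", "extracellular", "sink")) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n_carbons >= 1L)
  structure(list(name = name, n_carbons = as.integer(n_carbons),
                 compartment = compartment),
            class = "species_def")
}

parse_map_entry <- function(entry) {
  # "(1,2)->(1,1)" or "(1,1)->(CO2)"
  m <- regmatches(entry, regexec(
    "^\\((\\d+),(\\d+)\\)->\\((?:(CO2)|(\\d+),(\\d+))\\)$", entry))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed mapping entry: '%s'", entry))
  if (m[4] == "CO2")
    c(s_slot = as.integer(m[2]), s_pos = as.integer(m[3]), p_slot = 0L, p_pos = 0L)
  else
    c(s_slot = as.integer(m[2]), s_pos = as.integer(m[3]),
      p_slot = as.integer(m[5]), p_pos = as.integer(m[6]))
}

#' Construct a carbon transition map for one reaction
#'
#' Validates the atom bookkeeping at construction time: every substrate carbon
#' is mapped exactly once, every product carbon is the image of exactly one
#' substrate carbon, and substrate carbons = product carbons + CO2 carbons.
#'
#' @param name reaction identifier.
#' @param substrates,products named integer vectors: names are species names,
#'   values the carbon counts; order defines the slot numbering (a species may
#'   occupy several slots, e.g. the three hexoses of the lumped pentose
#'   phosphate cycle).
#' @param mapping character vector of entries `"(slot,pos)->(slot,pos)"`;
#'   carbons released as CO2 are written `"(slot,pos)->(CO2)"`.
#' @return an object of class `"carbon_map"`.
#' @examples
#' carbon_map("decarboxylation", c(pyruvate = 3), c(acetate = 2),
#'            c("(1,1)->(CO2)", "(1,2)->(1,1)", "(1,3)->(1,2)"))
#' @export
carbon_map <- function(name, substrates, products, mapping) {
  stopifnot(is.character(name), length(substrates) >= 1L, length(products) >= 1L)
  ent <- t(vapply(mapping, parse_map_entry, integer(4)))
  rownames(ent) <- NULL
  n_sub <- as.integer(substrates); n_pro <- as.integer(products)

  sub_key <- paste(ent[, "s_slot"], ent[, "s_pos"])
  all_sub <- unlist(lapply(seq_along(n_sub),
                           function(s) paste(s, seq_len(n_sub[s]))))
  if (!setequal(sub_key, all_sub) || anyDuplicated(sub_key))
    stop(sprintf("reaction '%s': every substrate carbon must appear in exactly one mapping entry", name))

  pro <- ent[ent[, "p_slot"] > 0L, , drop = FALSE]
  pro_key <- paste(pro[, "p_slot"], pro[, "p_pos"])
  all_pro <- unlist(lapply(seq_along(n_pro),
                           function(s) paste(s, seq_len(n_pro[s]))))
  if (!setequal(pro_key, all_pro) || anyDuplicated(pro_key))
    stop(sprintf("reaction '%s': every product carbon must be the image of exactly one substrate carbon", name))

  n_co2 <- sum(ent[, "p_slot"] == 0L)
  if (sum(n_sub) != sum(n_pro) + n_co2)
    stop(sprintf("reaction '%s': carbon counts do not balance", name))

  structure(list(name = name,
                 substrates = data.frame(species = names(substrates),
                                         n_carbons = n_sub),
                 products = data.frame(species = names(products),
                                       n_carbons = n_pro),
                 mapping = ent, n_co2 = n_co2),
            class = "carbon_map")
}

#' @export
print.carbon_map <- function(x, ...) {
  cat(sprintf("<carbon_map: %s>\n  %s -> %s%s\n", x$name,
              paste(x$substrates$species, collapse = " + "),
              paste(x$products$species, collapse = " + "),
              if (x$n_co2 > 0) sprintf(" + %d CO2", x$n_co2) else ""))
  invisible(x)
}

#' Push pool distributions through a carbon map
#'
#' Applies a reaction's atom map to one pool distribution per substrate slot,
#' assuming independence between slots (a condensation is the product measure
#' of its two partners — the standard well-mixed-pool isotopomer-balance
#' assumption).  Each product slot's distribution is the push-forward marginal
#' of the joint substrate labeling; the CO2 output is the expected number of
#' labeled carbons released per reaction event.
#'
#' @param map a [carbon_map].
#' @param inputs list of [pool_dist], one per substrate slot, in slot order.
#' @return list with `products` (list of [pool_dist] per product slot),
#'   `co2_labeled` (expected labeled CO2 carbons per event) and `n_co2`.
#' @export
apply_carbon_map <- function(map, inputs) {
  stopifnot(inherits(map, "carbon_map"))
  ns <- nrow(map$substrates)
  if (length(inputs) != ns)
    stop(sprintf("reaction '%s' has %d substrate slots, got %d inputs",
                 map$name, ns, length(inputs)))
  for (s in seq_len(ns)) {
    p <- inputs[[s]]
    if (!inherits(p, "pool_dist"))
      stop("inputs must be pool_dist objects")
    if (p$n_carbons != map$substrates$n_carbons[s])
      stop(sprintf("slot %d of '%s' expects %d carbons, got %d",
                   s, map$name, map$substrates$n_carbons[s], p$n_carbons))
    if (!is.na(p$species) && p$species != map$substrates$species[s])
      stop(sprintf("slot %d of '%s' expects species '%s', got '%s'",
                   s, map$name, map$substrates$species[s], p$species))
  }

  ent <- map$mapping
  products <- vector("list", nrow(map$products))
  for (j in seq_len(nrow(map$products))) {
    rows <- ent[ent[, "p_slot"] == j, , drop = FALSE]
    slots <- sort(unique(rows[, "s_slot"]))
    n_j <- map$products$n_carbons[j]
    # enumerate the product measure over the supports of contributing slots
    supports <- lapply(slots, function(s) names(inputs[[s]]$frac))
    probs <- lapply(slots, function(s) unname(inputs[[s]]$frac))
    idx <- expand.grid(lapply(supports, seq_along), KEEP.OUT.ATTRS = FALSE)
    acc <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(idx))) {
      pr <- 1
      bits <- rep("0", n_j)
      for (k in seq_along(slots)) {
        i <- idx[r, k]
        pr <- pr * probs[[k]][i]
        pat <- supports[[k]][i]
        sel <- rows[, "s_slot"] == slots[k]
        from <- rows[sel, "s_pos"]; to <- rows[sel, "p_pos"]
        bits[to] <- substring(pat, from, from)
      }
      key <- paste(bits, collapse = "")
      acc[[key]] <- (if (!is.null(acc[[key]])) acc[[key]] else 0) + pr
    }
    fr <- unlist(as.list(acc))
    products[[j]] <- pool_dist(fr, n_carbons = n_j,
                               species = map$products$species[j])
  }

  co2_rows <- ent[ent[, "p_slot"] == 0L, , drop = FALSE]
  co2_labeled <- 0
  if (nrow(co2_rows) > 0) {
    for (r in seq_len(nrow(co2_rows))) {
      m <- positional_fractions(inputs[[co2_rows[r, "s_slot"]]])
      co2_labeled <- co2_labeled + m[co2_rows[r, "s_pos"]]
    }
  }
  list(products = products, co2_labeled = unname(co2_labeled), n_co2 = map$n_co2)
}

# ---------------------------------------------------------------------------
# Default resting-cell network

identity_map_entries <- function(n, s_slot = 1L, p_slot = 1L)
  sprintf("(%d,%d)->(%d,%d)", s_slot, seq_len(n), p_slot, seq_len(n))

#' The resting-cell carbon transition network
#'
#' Builds the fixed metabolic network used for the resting-cell tracer
#' simulations: glucose uptake to fructose-6-phosphate (hexokinase +
#' phosphoglucose isomerase, identity map on the hexose backbone); the
#' fructose-6-phosphate phosphatase step excreting free fructose (identity
#' map); aldolase cleavage to a single, fully triose-phosphate-isomerase
#' equilibrated triose pool held in glyceraldehyde-3-phosphate coordinates
#' (F6P C1\eqn{\to}C3, C2\eqn{\to}C2, C3\eqn{\to}C1 via DHAP; C4/C5/C6
#' \eqn{\to} C1/C2/C3 directly); the reverse aldolase condensation (the
#' gluconeogenic back-flux responsible for label reversal, e.g.
#' \[6-\eqn{^{13}}C\]fructose from \[1-\eqn{^{13}}C\]glucose); a lumped
#' pentose phosphate cycle (3 hexose-P \eqn{\to} 2 F6P + 1 triose + 3 CO2,
#' oxidative loss of each C1 followed by the standard transketolase /
#' transaldolase recombination); and the triose-derived sinks (pyruvate,
#' ethanol + CO2, acetate + CO2, glycerol, dihydroxyacetone, and a lumped
#' TCA entry).
#'
#' @return an object of class `"flux_network"`: a list with `species`
#'   (data frame), `reactions` (named list of [carbon_map]) and `nodes`
#'   (designated node names).
#' @examples
#' net <- build_default_network()
#' names(net$reactions)
#' @export
build_default_network <- function() {
  sp <- list(
    species_def("glucose",  6, "extracellular"),
    species_def("F6P",      6, "intracellular"),
    species_def("triose",   3, "intracellular"),
    species_def("fructose", 6, "extracellular"),
    species_def("pyruvate", 3, "sink"),
    species_def("ethanol",  2, "sink"),
    species_def("acetate",  2, "sink"),
    species_def("glycerol", 3, "sink"),
    species_def("dha",      3, "sink"),
    species_def("tca",      3, "sink"),
    species_def("co2",      1, "sink"))
  species <- data.frame(
    name = vapply(sp, `[[`, "", "name"),
    n_carbons = vapply(sp, `[[`, 0L, "n_carbons"),
    compartment = vapply(sp, `[[`, "", "compartment"))

  reactions <- list(
    # hexokinase + phosphoglucose isomerase, lumped; backbone unchanged
    glucose_uptake = carbon_map("glucose_uptake",
      c(glucose = 6), c(F6P = 6), identity_map_entries(6)),
    # fructose-6P phosphatase: free fructose keeps the F6P backbone
    f6p_phosphatase = carbon_map("f6p_phosphatase",
      c(F6P = 6), c(fructose = 6), identity_map_entries(6)),
    # aldolase cleavage; both halves enter one TPI-equilibrated pool in
    # GAP coordinates (upper half via DHAP, hence C1<->C3 reversal)
    fba_cleavage = carbon_map("fba_cleavage",
      c(F6P = 6), c(triose = 3, triose = 3),
      c("(1,1)->(1,3)", "(1,2)->(1,2)", "(1,3)->(1,1)",
        "(1,4)->(2,1)", "(1,5)->(2,2)", "(1,6)->(2,3)")),
    # reverse aldolase + fructose-bisphosphatase: slot 1 condenses as the
    # DHAP partner (upper half), slot 2 as the GAP partner (lower half)
    aldolase_condensation = carbon_map("aldolase_condensation",
      c(triose = 3, triose = 3), c(F6P = 6),
      c("(1,1)->(1,3)", "(1,2)->(1,2)", "(1,3)->(1,1)",
        "(2,1)->(1,4)", "(2,2)->(1,5)", "(2,3)->(1,6)")),
    # lumped oxidative PPP cycle: each hexose loses C1 as CO2; the three
    # pentoses recombine via TK1 (X5P + R5P -> S7P + GAP), TA
    # (S7P + GAP -> F6P + E4P) and TK2 (X5P + E4P -> F6P + GAP).
    # Slot 1 = TK1-donor X5P, slot 2 = R5P, slot 3 = TK2-donor X5P.
    ppp_cycle = carbon_map("ppp_cycle",
      c(F6P = 6, F6P = 6, F6P = 6), c(F6P = 6, F6P = 6, triose = 3),
      c("(1,1)->(CO2)", "(1,2)->(1,1)", "(1,3)->(1,2)",
        "(1,4)->(1,4)", "(1,5)->(1,5)", "(1,6)->(1,6)",
        "(2,1)->(CO2)", "(2,2)->(1,3)", "(2,3)->(2,3)",
        "(2,4)->(2,4)", "(2,5)->(2,5)", "(2,6)->(2,6)",
        "(3,1)->(CO2)", "(3,2)->(2,1)", "(3,3)->(2,2)",
        "(3,4)->(3,1)", "(3,5)->(3,2)", "(3,6)->(3,3)")),
    pyruvate_formation = carbon_map("pyruvate_formation",
      c(triose = 3), c(pyruvate = 3), identity_map_entries(3)),
    glycerol_formation = carbon_map("glycerol_formation",
      c(triose = 3), c(glycerol = 3), identity_map_entries(3)),
    dha_formation = carbon_map("dha_formation",
      c(triose = 3), c(dha = 3), identity_map_entries(3)),
    # pyruvate decarboxylase + ADH; numbering follows the NMR naming in
    # which [2-13C]glucose yields [2-13C]ethanol
    ethanol_formation = carbon_map("ethanol_formation",
      c(pyruvate = 3), c(ethanol = 2),
      c("(1,1)->(CO2)", "(1,2)->(1,2)", "(1,3)->(1,1)")),
    # via acetaldehyde oxidation; carboxyl carbon = acetate C1
    acetate_formation = carbon_map("acetate_formation",
      c(pyruvate = 3), c(acetate = 2),
      c("(1,1)->(CO2)", "(1,2)->(1,1)", "(1,3)->(1,2)")),
    # terminal lumped TCA entry (malate/succinate not label-resolved)
    tca_entry = carbon_map("tca_entry",
      c(pyruvate = 3), c(tca = 3), identity_map_entries(3)))

  structure(list(
    species = species,
    reactions = reactions,
    nodes = list(glucose = "glucose", f6p = "F6P", triose = "triose",
                 fructose = "fructose", co2 = "co2",
                 sinks = c("ethanol", "glycerol", "pyruvate", "acetate",
                           "dha", "tca"))),
    class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network: %d species, %d reactions>\n",
              nrow(x$species), length(x$reactions)))
  invisible(x)
}

#' One pass of the lumped pentose phosphate cycle
#'
#' Consumes three hexose-phosphate molecules drawn independently from the
#' supplied distribution, loses each C1 oxidatively as CO2, and recombines
#' the three pentoses through the transketolase/transaldolase maps into two
#' fructose-6-phosphates and one triose.  On pure \[2-\eqn{^{13}}C\]hexose
#' this yields equal parts \[1-\eqn{^{13}}C\]- and
#' \[1,3-\eqn{^{13}}C\]fructose-6-phosphate with unlabeled CO2; a second
#' cycle on \[1,3-\eqn{^{13}}C\]hexose yields \[2-\eqn{^{13}}C\] and
#' \[2,3-\eqn{^{13}}C\] products.
#'
#' @param hexose a 6-carbon [pool_dist] of the hexose-phosphate pool.
#' @return list with `f6p` (the pooled F6P output distribution), `triose`
#'   (3-carbon [pool_dist]) and `co2_labeled_fraction` (labeled fraction of
#'   the three CO2 carbons released).
#' @export
ppp_cycle <- function(hexose) {
  stopifnot(inherits(hexose, "pool_dist"))
  if (hexose$n_carbons != 6L)
    stop("ppp_cycle expects a 6-carbon hexose distribution")
  map <- build_default_network()$reactions$ppp_cycle
  h <- hexose
  h$species <- "F6P"
  out <- apply_carbon_map(map, list(h, h, h))
  list(f6p = mix_pools(out$products[1:2], c(0.5, 0.5)),
       triose = out$products[[3]],
       co2_labeled_fraction = out$co2_labeled / out$n_co2)
}
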