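# Positional-isotopomer distributions.
#
# A pool distribution assigns a mole fraction to every binary 13C labeling
# pattern of one metabolite pool.  Patterns are stored as character keys of
# "0"/"1" with the first character = C1 (standard sugar numbering, keto/aldehyde
# proximal).  Only single-tracer binary labeling is represented; natural
# abundance is ignored.

#' Construct a positional-isotopomer pool distribution
#'
#' A `pool_dist` holds the mole-fraction distribution of one metabolite pool
#' over its binary \eqn{^{13}}C labeling patterns (one bit per carbon,
#' C1 first).  Distributions are stored sparsely: patterns with zero fraction
#' are dropped.  The fractions must sum to 1; drifts up to `1e-6` are silently
#' renormalized, larger deviations are an error.
#'
#' @param fractions named numeric vector of mole fractions.  Names are either
#'   binary strings (`"010000"`) or bracket labels (`"[2]"`, `"[1,3]"`, `"[]"`
#'   for unlabeled).
#' @param n_carbons number of carbon positions; required when all names are
#'   bracket labels, otherwise taken from the binary strings.
#' @param species optional species name carried along for slot matching.
#' @return an object of class `"pool_dist"` with elements `species`,
#'   `n_carbons` and `frac` (named numeric, binary-string keys).
#' @examples
#' pool_dist(c("[2]" = 1), n_carbons = 6, species = "glucose")
#' pool_dist(c("100000" = 0.9, "000001" = 0.1))
#' @export
pool_dist <- function(fractions, n_carbons = NULL, species = NA_character_) {
  if (length(fractions) == 0L || is.null(names(fractions)))
    stop("'fractions' must be a non-empty named numeric vector")
  keys <- names(fractions)
  bracket <- startsWith(keys, "[")
  if (any(bracket)) {
    if (is.null(n_carbons))
      stop("'n_carbons' is required when patterns are given as bracket labels")
    keys[bracket] <- vapply(keys[bracket], parse_pattern, "", n_carbons = n_carbons)
  }
  nc <- unique(nchar(keys))
  if (length(nc) != 1L)
    stop("all patterns must have the same number of carbons")
  if (!is.null(n_carbons) && nc != n_carbons)
    stop(sprintf("patterns have %d carbons, expected %d", nc, n_carbons))
  if (any(grepl("[^01]", keys)))
    stop("binary patterns may contain only '0' and '1'")
  x <- as.numeric(fractions)
  if (any(x < -1e-12)) stop("mole fractions must be non-negative")
  x[x < 0] <- 0
  names(x) <- keys
  x <- tapply(x, names(x), sum)           # merge duplicate keys
  x <- stats::setNames(as.vector(x), names(x))
  x <- x[x > 0]
  s <- sum(x)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("mole fractions sum to %.8f; must sum to 1 (tolerance 1e-6)", s))
  x <- x / s
  structure(
    list(species = species, n_carbons = nc,
         frac = sort(x, decreasing = TRUE)),
    class = "pool_dist")
}

#' @export
print.pool_dist <- function(x, digits = 4, ...) {
  cat(sprintf("<pool_dist%s, %d carbons>\n",
              if (is.na(x$species)) "" else paste0(": ", x$species), x$n_carbons))
  lab <- vapply(names(x$frac), pattern_label, "")
  print(round(stats::setNames(x$frac, lab), digits))
  invisible(x)
}

#' Convert between binary patterns and bracket labels
#'
#' The interchange syntax for labeling patterns lists the labeled carbon
#' positions in brackets, e.g. `"[1,3]"` for C1+C3 and `"[]"` for the
#' unlabeled molecule — the same naming used for isotopomer species such as
#' \[1,3-\eqn{^{13}}C\]fructose.
#'
#' @param pattern binary pattern string such as `"101000"`.
#' @param label bracket label such as `"[1,3]"`.
#' @param n_carbons number of carbon positions of the molecule.
#' @return `pattern_label()` returns the bracket label; `parse_pattern()` the
#'   binary string.
#' @examples
#' pattern_label("101000")        # "[1,3]"
#' parse_pattern("[1,3]", 6)      # "101000"
#' @export
pattern_label <- function(pattern) {
  pos <- which(strsplit(pattern, "")[[1]] == "1")
  paste0("[", paste(pos, collapse = ","), "]")
}

#' @rdname pattern_label
#' @export
parse_pattern <- function(label, n_carbons) {
  if (!grepl("^\\[[0-9, ]*\\]$", label))
    stop(sprintf("malformed pattern label: '%s'", label))
  inner <- gsub("\\[|\\]|\\s", "", label)
  bits <- rep("0", n_carbons)
  if (nzchar(inner)) {
    pos <- as.integer(strsplit(inner, ",")[[1]])
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > n_carbons))
      stop(sprintf("pattern label '%s' has positions outside 1..%d", label, n_carbons))
    bits[pos] <- "1"
  }
  paste(bits, collapse = "")
}

#' Per-position labeled mole fractions
#'
#' Computes the marginal labeled mole fraction at each carbon position,
#' \eqn{m_i = \sum_{\mathrm{patterns\ with\ } C_i \mathrm{\ labeled}} f},
#' the quantities (e.g. \eqn{m_1, m_2, m_5} of fructose) entering the
#' back-flux and pentose-phosphate flux estimators.
#'
#' @param pool a [pool_dist].
#' @return numeric vector `m` of length `n_carbons`, values in \[0, 1\].
#' @examples
#' positional_fractions(pool_dist(c("[1]" = 0.9, "[6]" = 0.1), 6))
#' @export
positional_fractions <- function(pool) {
  stopifnot(inherits(pool, "pool_dist"))
  pat <- names(pool$frac)
  m <- numeric(pool$n_carbons)
  for (i in seq_len(pool$n_carbons))
    m[i] <- sum(pool$frac[substr(pat, i, i) == "1"])
  names(m) <- paste0("m", seq_len(pool$n_carbons))
  m
}

#' Mix pool distributions with flux weights
#'
#' Weighted average of distributions over the same species/carbon count,
#' renormalized.  Used to combine the label sources feeding a metabolite pool
#' in proportion to their fluxes.
#'
#' @param pools list of [pool_dist] objects with equal `n_carbons`.
#' @param weights non-negative weights, not all zero.
#' @return a [pool_dist].
#' @export
mix_pools <- function(pools, weights) {
  stopifnot(length(pools) == length(weights), length(pools) >= 1L)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  nc <- unique(vapply(pools, function(p) p$n_carbons, 0L))
  sp <- unique(vapply(pools, function(p) p$species, ""))
  if (length(nc) != 1L)
    stop("cannot mix pools with different carbon counts")
  if (length(sp) != 1L)
    stop(sprintf("cannot mix pools of different species: %s",
                 paste(sp, collapse = ", ")))
  acc <- numeric(0)
  for (k in seq_along(pools)) {
    if (weights[k] == 0) next
    f <- pools[[k]]$frac * weights[k]
    for (p in names(f)) acc[p] <- (if (p %in% names(acc)) acc[[p]] else 0) + f[[p]]
  }
  pool_dist(acc / sum(acc), n_carbons = nc, species = sp)
}

#' Expected number of labeled carbons per molecule
#'
#' \eqn{\sum_{\mathrm{pattern}} f \times \mathrm{popcount(pattern)}}; the
#' conserved quantity used in label-balance checks.
#'
#' @param pool a [pool_dist].
#' @return a single number in \[0, `n_carbons`\].
#' @export
labeled_carbons <- function(pool) {
  stopifnot(inherits(pool, "pool_dist"))
  counts <- vapply(names(pool$frac),
                   function(p) sum(strsplit(p, "")[[1]] == "1"), 0)
  sum(pool$frac * counts)
}
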