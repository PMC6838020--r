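# Plain-text I/O: tidy TSV time courses with a JSON metadata sidecar, and a
# line-oriented text serialization of carbon-transition networks.

# polynomial rolling hash over the deparsed object; provenance fingerprint
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read and write tidy time-course tables
#'
#' Time courses are stored as tab-separated text with the header
#' `time_min  species  pattern  conc_mM` (patterns in bracket syntax such as
#' `"[1,3]"`); generation metadata (tracer, fluxes, seed, config hash) is
#' written to a JSON sidecar at `<path>.json` and re-attached on reading.
#'
#' @param tc a time-course `data.frame`.
#' @param path TSV file path.
#' @param sidecar write/read the JSON metadata sidecar.
#' @return `write_timecourse()` returns `path` invisibly;
#'   `read_timecourse()` the time-course `data.frame`.
#' @export
write_timecourse <- function(tc, path, sidecar = TRUE) {
  need <- c("time_min", "species", "pattern", "conc_mM")
  stopifnot(all(need %in% names(tc)))
  utils::write.table(tc[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    cfg <- attr(tc, "config")
    meta <- list(
      generator = paste0("fructoflux ",
                         as.character(utils::packageVersion("fructoflux"))),
      tracer = attr(tc, "tracer"),
      seed = attr(tc, "seed"),
      config = if (!is.null(cfg)) {
        cl <- unclass(cfg)
        cl$sink_split <- as.list(cl$sink_split)  # keep names in JSON
        cl
      },
      noise = if (!is.null(attr(tc, "noise"))) unclass(attr(tc, "noise")),
      config_hash = if (!is.null(cfg)) config_hash(unclass(cfg)))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path, sidecar = TRUE) {
  tc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_min", "species", "pattern", "conc_mM")
  if (!all(need %in% names(tc)))
    stop(sprintf("'%s' is not a time-course TSV (expected columns: %s)",
                 path, paste(need, collapse = ", ")))
  bad <- which(!is.finite(tc$conc_mM) | tc$conc_mM < 0)
  if (length(bad) > 0)
    stop(sprintf("invalid concentration in '%s' at line %d (data row %d): %s",
                 path, bad[1] + 1L, bad[1], format(tc$conc_mM[bad[1]])))
  bad <- which(!grepl("^\\[[0-9, ]*\\]$", tc$pattern))
  if (length(bad) > 0)
    stop(sprintf("malformed pattern in '%s' at line %d: '%s'",
                 path, bad[1] + 1L, tc$pattern[bad[1]]))
  sc <- paste0(path, ".json")
  if (sidecar && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    attr(tc, "tracer") <- meta$tracer
    attr(tc, "seed") <- meta$seed
    if (!is.null(meta$config)) {
      cfg <- meta$config
      attr(tc, "config") <- flux_config(
        f_IN = cfg$f_IN, f_fru = cfg$f_fru, f_PPP = cfg$f_PPP, f_R = cfg$f_R,
        sink_split = unlist(cfg$sink_split), glucose_0 = cfg$glucose_0,
        tracer = cfg$tracer)
    }
  }
  tc
}

#' Read and write carbon-transition networks as structured text
#'
#' Line-oriented format: `species <name> <n_carbons> <compartment>` records,
#' `node <role> <name,...>` designations, and per reaction a `reaction`
#' header followed by `substrates`/`products` (as `species:carbons` slot
#' lists) and `map` lines of `"(slot,pos)->(slot,pos)"` entries with `(CO2)`
#' as the reserved product.
#'
#' @param net a `flux_network` (see [build_default_network()]).
#' @param path output file.
#' @return `write_network()` returns `path` invisibly; `read_network()` the
#'   reconstructed `flux_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "flux_network"))
  out <- c("# fructoflux carbon-transition network v1",
           sprintf("species %s %d %s", net$species$name,
                   net$species$n_carbons, net$species$compartment),
           vapply(names(net$nodes), function(k)
             sprintf("node %s %s", k, paste(net$nodes[[k]], collapse = ",")),
             ""))
  for (rx in net$reactions) {
    out <- c(out,
      sprintf("reaction %s", rx$name),
      sprintf("substrates %s", paste(sprintf("%s:%d", rx$substrates$species,
                                             rx$substrates$n_carbons),
                                     collapse = " ")),
      sprintf("products %s", paste(sprintf("%s:%d", rx$products$species,
                                           rx$products$n_carbons),
                                   collapse = " ")),
      sprintf("map %s", paste(apply(rx$mapping, 1, function(e)
        if (e[["p_slot"]] == 0L)
          sprintf("(%d,%d)->(CO2)", e[["s_slot"]], e[["s_pos"]])
        else
          sprintf("(%d,%d)->(%d,%d)", e[["s_slot"]], e[["s_pos"]],
                  e[["p_slot"]], e[["p_pos"]])), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  tok <- strsplit(ln, "\\s+")
  kind <- vapply(tok, `[[`, "", 1)

  spl <- tok[kind == "species"]
  species <- data.frame(name = vapply(spl, `[[`, "", 2),
                        n_carbons = as.integer(vapply(spl, `[[`, "", 3)),
                        compartment = vapply(spl, `[[`, "", 4))
  nodes <- lapply(tok[kind == "node"], function(t) strsplit(t[3], ",")[[1]])
  names(nodes) <- vapply(tok[kind == "node"], `[[`, "", 2)

  slots <- function(t) {
    parts <- strsplit(t[-1], ":")
    stats::setNames(as.integer(vapply(parts, `[[`, "", 2)),
                    vapply(parts, `[[`, "", 1))
  }
  reactions <- list()
  i <- 1L
  while (i <= length(tok)) {
    if (kind[i] == "reaction") {
      name <- tok[[i]][2]
      stopifnot(kind[i + 1L] == "substrates", kind[i + 2L] == "products",
                kind[i + 3L] == "map")
      reactions[[name]] <- carbon_map(name, slots(tok[[i + 1L]]),
                                      slots(tok[[i + 2L]]), tok[[i + 3L]][-1])
      i <- i + 4L
    } else i <- i + 1L
  }
  structure(list(species = species, reactions = reactions,
                 nodes = lapply(nodes, function(x) if (length(x) > 1) x else x)),
            class = "flux_network")
}
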