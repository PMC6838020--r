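# Pipeline commands: file-level generate / infer / validate entry points.
# A thin Rscript wrapper over these functions ships in inst/scripts/.

popcount_label <- function(label) {
  inner <- gsub("\\[|\\]|\\s", "", label)
  if (!nzchar(inner)) 0L else length(strsplit(inner, ",")[[1]])
}

#' Labeled-carbon totals of a time course
#'
#' Sums `concentration x labeled carbons` over all rows at each time —
#' the conserved quantity of the tracer experiment (equal to
#' `glucose_0 x 1` for a singly labeled tracer at all times).
#'
#' @param tc a time course.
#' @return `data.frame` with columns `time_min` and `labeled_mM`.
#' @export
label_totals <- function(tc) {
  lab <- vapply(tc$pattern, popcount_label, 0L)
  agg <- stats::aggregate(list(labeled_mM = tc$conc_mM * lab),
                          by = list(time_min = tc$time_min), FUN = sum)
  agg[order(agg$time_min), ]
}

#' Generate synthetic tracer experiment files
#'
#' Writes the \[1-\eqn{^{13}}C\] and \[2-\eqn{^{13}}C\] tracer time courses
#' of a flux fixture as tidy TSV files with JSON metadata sidecars.
#'
#' @param out_dir output directory (created if missing).
#' @param fixture list with `c1`, `c2` ([flux_config]s) and `times`, as
#'   returned by [bombicola_fixture()].
#' @param noise a [noise_model] template, or `NULL` for noiseless tables.
#' @param seed overrides the noise seed; the C2 experiment uses `seed + 1`.
#' @return named character vector of the two TSV paths, invisibly.
#' @export
cmd_generate <- function(out_dir, fixture = bombicola_fixture(),
                         noise = noise_model(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(noise) && !is.null(seed))
    noise$seed <- as.integer(seed)
  paths <- c(c1 = file.path(out_dir, "c1_tracer.tsv"),
             c2 = file.path(out_dir, "c2_tracer.tsv"))
  nm2 <- if (is.null(noise)) NULL else
    noise_model(noise$relative_sd, noise$absolute_sd, noise$detection_limit,
                seed = noise$seed + 1L)
  write_timecourse(generate_experiment(fixture$c1, noise, fixture$times),
                   paths[["c1"]])
  write_timecourse(generate_experiment(fixture$c2, nm2, fixture$times),
                   paths[["c2"]])
  invisible(paths)
}

#' Infer fluxes from time-course files and write a report
#'
#' Reads the two tracer TSVs, runs [fit_fluxes()], and writes a JSON report
#' (estimates, standard deviations, ratios, windows, provenance) plus a
#' human-readable text report.
#'
#' @param c1_path,c2_path TSV paths of the two tracer experiments.
#' @param out_prefix path prefix for `<prefix>.json` and `<prefix>.txt`.
#' @param ... passed to [fit_fluxes()].
#' @return the `flux_fit`, invisibly.
#' @export
cmd_infer <- function(c1_path, c2_path, out_prefix, ...) {
  tc1 <- read_timecourse(c1_path)
  tc2 <- read_timecourse(c2_path)
  fit <- fit_fluxes(tc1, tc2, ...)
  report <- list(
    estimates = as.list(fit$estimates),
    sd = as.list(fit$sd),
    m_c1 = as.list(fit$m_c1), m_c2 = as.list(fit$m_c2),
    f_R_crosscheck_c2 = fit$f_R_crosscheck_c2,
    rate_window = fit$rate_window, ss_window_start = fit$ss_window[1],
    B = fit$B, seed = fit$seed,
    provenance = list(
      package = paste0("fructoflux ",
                       as.character(utils::packageVersion("fructoflux"))),
      inputs = c(c1_path, c2_path),
      input_hash = config_hash(list(tc1$conc_mM, tc2$conc_mM))))
  jsonlite::write_json(report, paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(summary(fit))),
             paste0(out_prefix, ".txt"))
  invisible(fit)
}

#' Noiseless parameter-recovery study over a flux grid
#'
#' Simulates noiseless tracer pairs on a grid of back-flux and pentose
#' phosphate flux ratios and re-infers the fluxes, reporting relative
#' recovery errors.  The estimators are deliberate steady-state
#' approximations of the full label dynamics, so small but nonzero errors
#' on `f_R` and `f_PPP` are expected and quantified here.
#'
#' @param f_IN,f_fru generating uptake and excretion rates (mM/min).
#' @param r_R grid of `f_R / f_IN` ratios.
#' @param r_P grid of `f_PPP / f_IN` ratios.
#' @param times sampling grid (min).
#' @param B bootstrap replicates per fit (small: only point estimates are
#'   studied here).
#' @return `data.frame` with generating values, estimates and relative
#'   errors (`NA` relative error where the generating value is 0; absolute
#'   error reported instead).
#' @export
recovery_study <- function(f_IN = 1.47, f_fru = 0.68,
                           r_R = c(0, 0.25, 0.5), r_P = c(0, 0.05, 0.15),
                           times = c(0, 15, 30, 45, 60, 120), B = 50) {
  grid <- expand.grid(f_R = r_R * f_IN, f_PPP = r_P * f_IN)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    f_R <- grid$f_R[i]; f_PPP <- grid$f_PPP[i]
    cfg <- function(tr) flux_config(f_IN, f_fru, f_PPP, f_R, tracer = tr)
    fit <- fit_fluxes(run_resting_cell(cfg(1), times),
                      run_resting_cell(cfg(2), times), B = B)
    est <- coef(fit)
    rel <- function(e, t) if (t > 0) abs(e - t) / t else NA_real_
    data.frame(f_IN_true = f_IN, f_fru_true = f_fru,
               f_R_true = f_R, f_PPP_true = f_PPP,
               f_IN_est = est[["f_IN"]], f_fru_est = est[["f_fru"]],
               f_R_est = est[["f_R"]], f_PPP_est = est[["f_PPP"]],
               f_PPP_corr_est = fit$f_PPP_corrected,
               f_IN_relerr = rel(est[["f_IN"]], f_IN),
               f_fru_relerr = rel(est[["f_fru"]], f_fru),
               f_R_relerr = rel(est[["f_R"]], f_R),
               f_PPP_relerr = rel(est[["f_PPP"]], f_PPP),
               f_PPP_corr_relerr = rel(fit$f_PPP_corrected, f_PPP),
               f_R_abserr = abs(est[["f_R"]] - f_R),
               f_PPP_abserr = abs(est[["f_PPP"]] - f_PPP),
               f_PPP_corr_abserr = abs(fit$f_PPP_corrected - f_PPP))
  })
  do.call(rbind, res)
}

#' Run the model's internal validation suite
#'
#' Property checks run on a fresh network and fixture: atom-map label
#' conservation, the pentose-phosphate worked examples, whole-simulation
#' labeled-carbon conservation, absence of reversed label without
#' back-flux, and the noiseless parameter-recovery grid.
#'
#' @param quiet suppress the printed summary.
#' @return `data.frame` with columns `check`, `pass`, `detail`; attribute
#'   `"ok"` is `TRUE` when everything passed.
#' @export
cmd_validate <- function(quiet = FALSE) {
  checks <- list()
  add <- function(name, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)

  # PPP worked examples
  out <- ppp_cycle(pool_dist(c("[2]" = 1), 6))
  ok1 <- isTRUE(all.equal(sort(unname(out$f6p$frac)), c(0.5, 0.5))) &&
    setequal(names(out$f6p$frac), c("100000", "101000")) &&
    out$co2_labeled_fraction < 1e-12
  add("ppp_first_cycle_2C13", ok1, "F6P = {[1]:0.5, [1,3]:0.5}, CO2 unlabeled")
  out2 <- ppp_cycle(pool_dist(c("[1,3]" = 1), 6))
  ok2 <- setequal(names(out2$f6p$frac), c("010000", "011000")) &&
    isTRUE(all.equal(sort(unname(out2$f6p$frac)), c(0.5, 0.5)))
  add("ppp_second_cycle_13C13", ok2, "F6P = {[2]:0.5, [2,3]:0.5}")

  # label conservation through every reaction map (random inputs)
  net <- build_default_network()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(42)
  worst <- 0
  for (rx in net$reactions) {
    ins <- lapply(seq_len(nrow(rx$substrates)), function(s) {
      n <- rx$substrates$n_carbons[s]
      pats <- replicate(3, paste(sample(c("0", "1"), n, TRUE), collapse = ""))
      w <- stats::runif(3)
      pool_dist(stats::setNames(w / sum(w), pats), n_carbons = n,
                species = rx$substrates$species[s])
    })
    out <- apply_carbon_map(rx, ins)
    lin <- sum(vapply(ins, labeled_carbons, 0))
    lout <- sum(vapply(out$products, labeled_carbons, 0)) + out$co2_labeled
    worst <- max(worst, abs(lin - lout))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  add("map_label_conservation", worst < 1e-12,
      sprintf("max |in - out| = %.2e", worst))

  # whole-simulation labeled-carbon conservation at the fixture
  fx <- bombicola_fixture()
  worst <- 0
  for (cfg in list(fx$c1, fx$c2)) {
    tc <- run_resting_cell(cfg, fx$times)
    lt <- label_totals(tc)
    worst <- max(worst, abs(lt$labeled_mM - cfg$glucose_0) / cfg$glucose_0)
  }
  add("simulation_label_conservation", worst < 1e-6,
      sprintf("max relative drift = %.2e", worst))

  # no reversed label without back-flux
  cfg0 <- flux_config(1.47, 0.68, f_PPP = 0.08, f_R = 0, tracer = 1)
  m <- steady_state_fractions(run_resting_cell(cfg0, fx$times), "fructose")
  add("no_reversal_without_backflux", m[["m6"]] == 0,
      sprintf("m6 = %.2e", m[["m6"]]))

  # noiseless recovery grid; f_PPP pass/fail judged on the turnover-corrected
  # estimate (the raw mole-fraction formula is biased low by construction when
  # f_R > 0 — its error is reported alongside)
  rg <- recovery_study(B = 50)
  ok <- all(rg$f_IN_relerr < 0.01, rg$f_fru_relerr < 0.01,
            rg$f_R_relerr < 0.15, rg$f_PPP_corr_relerr < 0.15,
            rg$f_R_abserr[is.na(rg$f_R_relerr)] < 1e-6,
            rg$f_PPP_corr_abserr[is.na(rg$f_PPP_corr_relerr)] < 1e-6,
            na.rm = TRUE)
  add("recovery_grid", ok,
      sprintf(paste0("max rel err: f_IN %.2e, f_fru %.2e, f_R %.2e, ",
                     "f_PPP(corr) %.2e; raw-formula f_PPP err up to %.2f"),
              max(rg$f_IN_relerr, na.rm = TRUE),
              max(rg$f_fru_relerr, na.rm = TRUE),
              max(rg$f_R_relerr, na.rm = TRUE),
              max(rg$f_PPP_corr_relerr, na.rm = TRUE),
              max(rg$f_PPP_relerr, na.rm = TRUE)))

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  if (!quiet) {
    for (i in seq_len(nrow(out)))
      cat(sprintf("%-34s %s  %s\n", out$check[i],
                  if (out$pass[i]) "PASS" else "FAIL", out$detail[i]))
    cat(if (all(out$pass)) "all checks passed\n" else "CHECKS FAILED\n")
  }
  invisible(out)
}
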