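# Methods for the fitted flux model object.

#' @export
print.flux_fit <- function(x, digits = 3, ...) {
  cat("Resting-cell 13C-tracer flux fit\n\n")
  fl <- x$estimates[c("f_IN", "f_fru", "f_R", "f_PPP")]
  tab <- data.frame(estimate = round(fl, digits),
                    sd = round(x$sd[names(fl)], digits))
  print(tab)
  cat(sprintf("\nback-flux / forward glycolytic flux: %.1f%%\n",
              100 * x$estimates[["r_back"]]))
  cat(sprintf("fructose / net F6P->glycolysis flux: %.1f%%\n",
              100 * x$estimates[["r_divert"]]))
  invisible(x)
}

#' Extract fitted fluxes
#'
#' @param object a `flux_fit`.
#' @param ... unused.
#' @return named vector of the four fitted fluxes (mM/min).
#' @export
coef.flux_fit <- function(object, ...)
  object$estimates[c("f_IN", "f_fru", "f_R", "f_PPP")]

#' Summarize a fitted flux model
#'
#' Adds the derived ratios, the steady-state positional fractions of both
#' experiments, and the `m2/m5` cross-check estimate of the back-flux from
#' the \[2-\eqn{^{13}}C\] experiment.
#'
#' @param object a `flux_fit`.
#' @param ... unused.
#' @return an object of class `"summary.flux_fit"`.
#' @export
summary.flux_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.flux_fit")
}

#' @export
print.summary.flux_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print.flux_fit(f, digits = digits)
  cat(sprintf("\nrate window: [%g, %g) min; composition window: t >= %g min\n",
              f$rate_window[1], f$rate_window[2], f$ss_window[1]))
  cat(sprintf("bootstrap: B = %d, seed = %d\n", f$B, f$seed))
  cat("\nsteady-state fructose positional fractions\n")
  m <- rbind(`[1-13C] tracer` = f$m_c1, `[2-13C] tracer` = f$m_c2)
  print(round(m, digits + 1))
  rev_frac <- f$m_c1[["m6"]] / (f$m_c1[["m1"]] + f$m_c1[["m6"]])
  cat(sprintf("\nreversed-label share of fructose (C1 tracer): %.1f%%\n",
              100 * rev_frac))
  if (is.finite(f$f_R_crosscheck_c2))
    cat(sprintf("f_R cross-check from [2-13C] m2/m5: %.3f mM/min (primary: %.3f)\n",
                f$f_R_crosscheck_c2, f$estimates[["f_R"]]))
  cat(sprintf("f_PPP turnover-corrected diagnostic: %.3f mM/min (formula: %.3f)\n",
              f$f_PPP_corrected, f$estimates[["f_PPP"]]))
  invisible(x)
}

#' Simulate tracer experiments at the fitted fluxes
#'
#' Regenerates synthetic \[1-\eqn{^{13}}C\] and \[2-\eqn{^{13}}C\] time
#' courses from the fitted flux set, optionally with measurement noise —
#' the parametric-bootstrap companion of [fit_fluxes()].
#'
#' @param object a `flux_fit`.
#' @param nsim number of replicate experiment pairs.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @param times sampling grid (min).
#' @param noise a [noise_model] template, or `NULL` for noiseless output.
#' @param ... unused.
#' @return list of `nsim` elements, each a list with `c1` and `c2` time
#'   courses.
#' @export
simulate.flux_fit <- function(object, nsim = 1, seed = 1L,
                              times = c(0, 15, 30, 45, 60, 120),
                              noise = NULL, ...) {
  fl <- coef(object)
  cfg <- function(tracer)
    flux_config(f_IN = fl[["f_IN"]], f_fru = fl[["f_fru"]],
                f_PPP = fl[["f_PPP"]], f_R = fl[["f_R"]],
                glucose_0 = object$glucose_0, tracer = tracer)
  lapply(seq_len(nsim), function(i) {
    nm <- if (is.null(noise)) NULL else
      noise_model(noise$relative_sd, noise$absolute_sd,
                  noise$detection_limit, seed = seed + i - 1L)
    list(c1 = generate_experiment(cfg(1), nm, times),
         c2 = generate_experiment(cfg(2), nm, times))
  })
}

#' Residuals of the linear rate fits
#'
#' @param object a `flux_fit`.
#' @param ... unused.
#' @return named list of residual vectors for the glucose and fructose
#'   slope fits of both experiments.
#' @export
residuals.flux_fit <- function(object, ...) {
  pe <- object$per_experiment
  list(glucose_c1 = pe$c1$fit_glc$residuals,
       fructose_c1 = pe$c1$fit_fru$residuals,
       glucose_c2 = pe$c2$fit_glc$residuals,
       fructose_c2 = pe$c2$fit_fru$residuals)
}

#' Plot observed totals and fitted rates
#'
#' Total glucose and fructose time series of both tracer experiments with
#' the fitted linear rates overlaid on the pre-exhaustion window.
#'
#' @param x a `flux_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flux_fit <- function(x, ...) {
  pe <- x$per_experiment
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (lab in c("c1", "c2")) {
    p <- pe[[lab]]
    ylim <- range(0, p$glc$conc_mM, p$fru$conc_mM)
    graphics::plot(p$glc$time_min, p$glc$conc_mM, pch = 19, ylim = ylim,
                   xlab = "time (min)", ylab = "concentration (mM)",
                   main = sprintf("[%s-13C]glucose",
                                  if (lab == "c1") "1" else "2"), ...)
    graphics::points(p$fru$time_min, p$fru$conc_mM, pch = 1)
    tt <- seq(0, min(p$t_ex, max(p$glc$time_min)), length.out = 2)
    g0 <- max(p$glc$conc_mM)
    graphics::lines(tt, g0 - x$estimates[["f_IN"]] * tt, lty = 2)
    graphics::lines(tt, x$estimates[["f_fru"]] * tt, lty = 3)
    graphics::legend("topright", bty = "n", pch = c(19, 1),
                     legend = c("glucose", "fructose"))
  }
  invisible(x)
}
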