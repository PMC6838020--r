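# Synthetic NMR time-course generation: the noiseless simulator output
# perturbed by a measurement-noise and detection-limit model, emulating
# supernatant 13C-NMR quantification of a resting-cell tracer pulse.

#' Measurement noise model for synthetic NMR time courses
#'
#' Each concentration value is perturbed by independent Gaussian noise with
#' `sd = relative_sd * value + absolute_sd`, clamped at zero; values below
#' `detection_limit` are censored to 0.  The defaults give relative errors
#' on the inferred fluxes of the order seen in replicate NMR flux
#' measurements (roughly 15% on the uptake rate).
#'
#' @param relative_sd multiplicative noise component (fraction of the value).
#' @param absolute_sd additive noise component (mM).
#' @param detection_limit censoring threshold (mM).
#' @param seed integer seed making generation deterministic.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(relative_sd = 0.05, absolute_sd = 0.05,
                        detection_limit = 0.1, seed = 1L) {
  stopifnot(relative_sd >= 0, absolute_sd >= 0, detection_limit >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(relative_sd = relative_sd, absolute_sd = absolute_sd,
                 detection_limit = detection_limit, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic tracer experiment
#'
#' Runs the noiseless simulator ([run_resting_cell()]) and applies the
#' measurement [noise_model()].  With zero noise the output equals the
#' noiseless simulation; for a given seed the output is reproducible
#' bit-for-bit.
#'
#' @param config a [flux_config].
#' @param noise a [noise_model]; `NULL` for a noiseless table.
#' @param times sampling grid in minutes.
#' @return a time-course `data.frame` as in [run_resting_cell()], with an
#'   additional `seed` attribute.
#' @examples
#' fx <- bombicola_fixture()
#' tc <- generate_experiment(fx$c2, noise_model(seed = 7), fx$times)
#' @export
generate_experiment <- function(config, noise = noise_model(),
                                times = c(0, 15, 30, 45, 60, 120)) {
  tc <- run_resting_cell(config, times)
  if (is.null(noise)) return(tc)
  stopifnot(inherits(noise, "noise_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  sd <- noise$relative_sd * tc$conc_mM + noise$absolute_sd
  v <- tc$conc_mM + stats::rnorm(nrow(tc), 0, sd)
  v[v < 0] <- 0
  v[v < noise$detection_limit] <- 0
  tc$conc_mM <- v
  attr(tc, "noise") <- noise
  attr(tc, "seed") <- noise$seed
  tc
}

#' Reference flux fixture for *Starmerella bombicola* resting cells
#'
#' The shipped ground-truth flux set for the
#' \emph{mtdh1}\eqn{\Delta}\emph{mtdh2}\eqn{\Delta} resting-cell experiment:
#' glucose uptake `f_IN` = 1.47 mM/min, fructose excretion `f_fru` = 0.68
#' mM/min, pentose-phosphate entry `f_PPP` = 0.08 mM/min, a 50 mM tracer
#' pulse sampled at 0/15/30/45/60/120 min, and the triose \eqn{\to} F6P
#' back-flux `f_R` set so that it equals 48% of the forward glycolytic flux
#' `(f_IN - f_fru) + f_R`, i.e. `f_R = 0.48/0.52 * (f_IN - f_fru)`
#' (computed, not hard-coded).  With these values fructose diverts 86% of
#' the net F6P \eqn{\to} glycolysis flux.
#'
#' @return list with elements `c1` and `c2` (the \[1-\eqn{^{13}}C\] and
#'   \[2-\eqn{^{13}}C\] tracer [flux_config]s) and `times` (sampling grid).
#' @examples
#' fx <- bombicola_fixture()
#' fx$c1$f_R / ((fx$c1$f_IN - fx$c1$f_fru) + fx$c1$f_R)  # 0.48
#' @export
bombicola_fixture <- function() {
  f_IN <- 1.47; f_fru <- 0.68; f_PPP <- 0.08
  r_back <- 0.48
  f_R <- r_back / (1 - r_back) * (f_IN - f_fru)
  cfg <- function(tracer)
    flux_config(f_IN = f_IN, f_fru = f_fru, f_PPP = f_PPP, f_R = f_R,
                glucose_0 = 50, tracer = tracer)
  list(c1 = cfg(1), c2 = cfg(2), times = c(0, 15, 30, 45, 60, 120))
}
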