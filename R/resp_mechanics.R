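#' Simulate a ventilator breath from the single-compartment equation of motion
#'
#' Generates an airway pressure/flow/volume waveform obeying
#' `Paw(t) = V(t)/C + R * V'(t) + P0`: square-wave inspiratory flow for `ti`
#' seconds followed by passive exponential expiration with time constant
#' `R * C`. Used by the cohort generator and by mechanics recovery tests.
#'
#' @param C Compliance, mL/cmH2O.
#' @param R Resistance, cmH2O.s/L.
#' @param P0 End-expiratory pressure, cmH2O.
#' @param vt Tidal volume, mL.
#' @param ti Inspiratory time, s.
#' @param t_total Breath duration, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise SD added to pressure, cmH2O.
#' @return A tibble with columns `time_s`, `flow_lps`, `volume_ml`,
#'   `paw_cmh2o`.
#' @examples
#' w <- simulate_breath(C = 2, R = 50, P0 = 6)
#' fit_single_compartment(w)
#' @export
simulate_breath <- function(C, R, P0, vt = 12.6, ti = 0.3, t_total = 1.5,
                            dt = 0.005, noise_sd = 0) {
  stopifnot(C > 0, R >= 0, vt > 0, ti > 0, t_total > ti, dt > 0)
  time <- seq(0, t_total, by = dt)
  insp_flow <- vt / ti / 1000 # L/s, constant during inspiration
  tau <- R * C / 1000         # s (R in cmH2O.s/L, C in mL/cmH2O)
  flow <- ifelse(time <= ti, insp_flow,
                 if (tau > 0) -vt / 1000 / tau * exp(-(time - ti) / tau) else 0)
  volume <- ifelse(time <= ti, vt * time / ti,
                   if (tau > 0) vt * exp(-(time - ti) / tau) else 0)
  paw <- volume / C + R * flow + P0
  if (noise_sd > 0) paw <- paw + stats::rnorm(length(paw), 0, noise_sd)
  tibble::tibble(time_s = time, flow_lps = flow, volume_ml = volume,
                 paw_cmh2o = paw)
}

#' Fit single-compartment respiratory mechanics to a breath waveform
#'
#' Ordinary least squares on the equation of motion
#' `Paw = V * (1/C) + V' * R + P0` with design matrix `[V, V', 1]`, giving
#' dynamic compliance, resistance and the end-expiratory pressure estimate.
#'
#' @param waveform A data frame with columns `time_s`, `flow_lps` (L/s),
#'   `volume_ml` (mL), `paw_cmh2o` (cmH2O); at least 20 samples.
#' @return An object of class `mechanics_fit` with elements `C` (mL/cmH2O),
#'   `R` (cmH2O.s/L), `P0` (cmH2O), `rss`, `n_samples`. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' fit_single_compartment(simulate_breath(2, 50, 6))
#' @export
fit_single_compartment <- function(waveform) {
  stopifnot(is.data.frame(waveform))
  need <- c("time_s", "flow_lps", "volume_ml", "paw_cmh2o")
  miss <- setdiff(need, names(waveform))
  if (length(miss)) {
    stop("fit_single_compartment: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(waveform) < 20) {
    stop("fit_single_compartment: need at least 20 samples", call. = FALSE)
  }
  v <- waveform$volume_ml
  f <- waveform$flow_lps
  p <- waveform$paw_cmh2o
  if (all(f == 0) || stats::var(v) == 0 || stats::var(f) == 0) {
    stop("fit_single_compartment: rank-deficient design (constant flow or volume)",
         call. = FALSE)
  }
  X <- cbind(v, f)
  fit <- stats::lm(p ~ v + f)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 3) {
    stop("fit_single_compartment: rank-deficient design; C and R not identifiable",
         call. = FALSE)
  }
  b <- stats::coef(fit)
  if (b[["v"]] <= 0) {
    stop("fit_single_compartment: fitted elastance is non-positive; waveform inconsistent",
         call. = FALSE)
  }
  structure(
    list(C = 1 / b[["v"]], R = max(b[["f"]], 0), P0 = b[["(Intercept)"]],
         rss = sum(stats::residuals(fit)^2), n_samples = nrow(waveform)),
    class = "mechanics_fit"
  )
}

#' @export
print.mechanics_fit <- function(x, ...) {
  cat("<mechanics_fit>\n")
  cat(sprintf("  C   %.3f mL/cmH2O\n  R   %.2f cmH2O.s/L\n  P0  %.2f cmH2O\n",
              x$C, x$R, x$P0))
  cat(sprintf("  RSS %.3g over %d samples\n", x$rss, x$n_samples))
  invisible(x)
}

#' @method tidy mechanics_fit
#' @export
tidy.mechanics_fit <- function(x, ...) {
  tibble::tibble(
    term = c("C", "R", "P0"),
    estimate = c(x$C, x$R, x$P0)
  )
}

#' @method glance mechanics_fit
#' @export
glance.mechanics_fit <- function(x, ...) {
  tibble::tibble(C = x$C, R = x$R, P0 = x$P0, rss = x$rss,
                 n_samples = x$n_samples)
}

#' Static (quasi-static) respiratory compliance
#'
#' Tidal volume over the plateau-to-PEEP driving pressure.
#'
#' @param vt Tidal volume, mL.
#' @param pplat Plateau pressure, cmH2O.
#' @param peep Positive end-expiratory pressure, cmH2O.
#' @return Compliance, mL/cmH2O.
#' @examples
#' static_compliance(12.6, 16.3, 6)
#' @export
static_compliance <- function(vt, pplat, peep) {
  if (any(pplat <= peep)) {
    stop("static_compliance: plateau pressure must exceed PEEP", call. = FALSE)
  }
  vt / (pplat - peep)
}

#' Airway resistance from peak-to-plateau pressure drop
#'
#' @param pip Peak inspiratory pressure, cmH2O.
#' @param pplat Plateau pressure, cmH2O.
#' @param peak_flow Peak inspiratory flow, L/s (> 0).
#' @return Resistance, cmH2O.s/L.
#' @examples
#' airway_resistance(20, 15, 0.1)
#' @export
airway_resistance <- function(pip, pplat, peak_flow) {
  if (any(peak_flow <= 0)) {
    stop("airway_resistance: peak flow must be > 0", call. = FALSE)
  }
  (pip - pplat) / peak_flow
}

#' Minute ventilation
#'
#' @param vt_ml Tidal volume, mL (> 0).
#' @param rr Respiratory rate, breaths/min (> 0).
#' @return Minute ventilation, L/min.
#' @examples
#' minute_ventilation(12.6, 40)
#' @export
minute_ventilation <- function(vt_ml, rr) {
  if (any(vt_ml <= 0) || any(rr <= 0)) {
    stop("minute_ventilation: tidal volume and rate must be > 0", call. = FALSE)
  }
  vt_ml * rr / 1000
}
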