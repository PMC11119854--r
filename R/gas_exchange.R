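#' Alveolar oxygen tension from the alveolar gas equation
#'
#' Computes PAO2 = FiO2 * (Pb - PH2O) - PaCO2 / RQ, the simplified clinical
#' form of the alveolar gas equation. Negative results (possible at very low
#' FiO2 with high PaCO2) are clamped to zero with a warning.
#'
#' @param fio2 Inspired oxygen fraction, in (0, 1].
#' @param paco2 Arterial CO2 tension, mmHg (>= 0).
#' @param constants A [physio_constants()] object.
#' @return Alveolar PO2, mmHg. Vectorised over `fio2` and `paco2`.
#' @examples
#' alveolar_po2(0.21, 40) # room air, normocapnia
#' alveolar_po2(1, 0)     # pure oxygen, no CO2: Pb - PH2O
#' @export
alveolar_po2 <- function(fio2, paco2, constants = physio_constants()) {
  if (any(!is.finite(fio2)) || any(fio2 <= 0) || any(fio2 > 1)) {
    stop("alveolar_po2: fio2 must be a fraction in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(paco2)) || any(paco2 < 0)) {
    stop("alveolar_po2: paco2 must be >= 0 mmHg", call. = FALSE)
  }
  pao2 <- fio2 * (constants$Pb - constants$PH2O) - paco2 / constants$RQ
  if (any(pao2 < 0)) {
    warning("alveolar_po2: alveolar PO2 below 0 mmHg clamped to 0", call. = FALSE)
    pao2 <- pmax(pao2, 0)
  }
  pao2
}

#' Alveolar-arterial oxygen difference
#'
#' @param pao2_alveolar Alveolar PO2, mmHg.
#' @param pao2_arterial Arterial PO2, mmHg.
#' @return PAO2 - PaO2, mmHg. A negative difference (arterial above alveolar)
#'   is physically inconsistent and triggers a warning but is returned as-is.
#' @examples
#' aa_difference(99.7, 60)
#' @export
aa_difference <- function(pao2_alveolar, pao2_arterial) {
  stopifnot(all(pao2_alveolar >= 0), all(pao2_arterial >= 0))
  d <- pao2_alveolar - pao2_arterial
  if (any(d < 0)) {
    warning("aa_difference: arterial PO2 exceeds alveolar PO2 (measurement inconsistency?)",
            call. = FALSE)
  }
  d
}

#' PaO2:FiO2 ratio
#'
#' @param pao2 Arterial PO2, mmHg.
#' @param fio2 Inspired oxygen fraction, in (0, 1].
#' @return PaO2 / FiO2, mmHg.
#' @examples
#' pf_ratio(63, 0.21)
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(fio2 <= 0) || any(fio2 > 1)) {
    stop("pf_ratio: fio2 must be a fraction in (0, 1]", call. = FALSE)
  }
  pao2 / fio2
}

#' Oxyhaemoglobin dissociation curve (Severinghaus closed form)
#'
#' `hb_saturation()` maps oxygen tension to haemoglobin saturation using the
#' Severinghaus single-equation fit to the standard human dissociation curve,
#' S = 1 / (1 + 23400 / (P^3 + 150 P)). `hb_po2()` is its exact analytic
#' inverse (the real root of the associated depressed cubic).
#'
#' @param po2 Oxygen tension, mmHg (>= 0).
#' @return Saturation as a fraction in [0, 1).
#' @examples
#' hb_saturation(26.9) # near P50
#' hb_po2(0.5)
#' @export
hb_saturation <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 < 0)) {
    stop("hb_saturation: po2 must be >= 0 mmHg", call. = FALSE)
  }
  x <- po2^3 + 150 * po2
  ifelse(po2 == 0, 0, 1 / (1 + 23400 / x))
}

#' @rdname hb_saturation
#' @param so2 Saturation as a fraction, strictly inside (0, 1).
#' @export
hb_po2 <- function(so2) {
  if (any(!is.finite(so2)) || any(so2 <= 0) || any(so2 >= 1)) {
    stop("hb_po2: so2 must lie strictly inside (0, 1)", call. = FALSE)
  }
  # solve P^3 + 150 P - A = 0, A = 23400 * s / (1 - s); Cardano, single real root
  a <- 23400 * so2 / (1 - so2)
  u <- (a / 2 + sqrt(a^2 / 4 + 125000))^(1 / 3)
  u - 50 / u
}

# derivative of the Severinghaus curve wrt po2; used by the Newton inversion
hb_saturation_deriv <- function(po2) {
  x <- po2^3 + 150 * po2
  dx <- 3 * po2^2 + 150
  23400 * dx / (x + 23400)^2
}

#' Oxygen content of blood
#'
#' Haemoglobin-bound plus dissolved oxygen:
#' `hb_O2_capacity * hb * so2 + dissolved_O2_coeff * po2`.
#'
#' @param hb Haemoglobin, g/dL.
#' @param so2 Saturation, fraction in [0, 1].
#' @param po2 Oxygen tension, mmHg.
#' @param constants A [physio_constants()] object.
#' @return Oxygen content, mL O2/dL.
#' @examples
#' o2_content(12, 1, 100)
#' @export
o2_content <- function(hb, so2, po2, constants = physio_constants()) {
  stopifnot(all(hb >= 0), all(so2 >= 0), all(so2 <= 1), all(po2 >= 0))
  constants$hb_O2_capacity * hb * so2 + constants$dissolved_O2_coeff * po2
}

#' Berggren shunt equation
#'
#' Qs/Qt = (Cc' - Ca) / (Cc' - Cv), the fraction of pulmonary blood flow that
#' bypasses ventilated lung, from end-capillary, arterial and mixed-venous
#' oxygen contents.
#'
#' @param cc_o2 End-capillary O2 content, mL/dL.
#' @param ca_o2 Arterial O2 content, mL/dL.
#' @param cv_o2 Mixed-venous O2 content, mL/dL.
#' @return Shunt fraction in [0, 1] (values outside are clamped with warning).
#' @examples
#' shunt_equation(20, 18, 15)
#' @export
shunt_equation <- function(cc_o2, ca_o2, cv_o2) {
  if (any(cc_o2 <= cv_o2)) {
    stop("shunt_equation: end-capillary content must exceed venous content",
         call. = FALSE)
  }
  q <- (cc_o2 - ca_o2) / (cc_o2 - cv_o2)
  if (any(q < 0) || any(q > 1)) {
    warning("shunt_equation: shunt fraction outside [0, 1] clamped", call. = FALSE)
    q <- pmin(pmax(q, 0), 1)
  }
  q
}

# Invert total O2 content -> (SaO2, PaO2) along the dissociation curve.
# content(P) = cap*hb*S(P) + sol*P is strictly increasing in P; solved by
# vectorised Newton from a log-spaced starting guess, polishing to ~1e-12.
# Contents at or below zero map to (0, 0); contents above the curve's value
# at 1500 mmHg are clamped there.
sao2_from_content <- function(ca, hb, constants = physio_constants()) {
  cap <- constants$hb_O2_capacity * hb
  sol <- constants$dissolved_O2_coeff
  n <- max(length(ca), length(hb))
  ca <- rep_len(ca, n)
  cap <- rep_len(cap, n)

  content_at <- function(p) cap * hb_saturation(p) + sol * p
  p_hi <- 1500
  out_s <- numeric(n)
  out_p <- numeric(n)
  lo <- ca <= 0
  hi <- ca >= content_at(p_hi)
  out_p[hi] <- p_hi
  out_s[hi] <- hb_saturation(p_hi)
  mid <- !(lo | hi)
  if (any(mid)) {
    p <- rep(30, sum(mid))
    cam <- ca[mid]
    capm <- cap[mid]
    for (i in 1:60) {
      f <- capm * hb_saturation(p) + sol * p - cam
      fp <- capm * hb_saturation_deriv(p) + sol
      step <- f / fp
      p <- pmin(pmax(p - step, 1e-9), p_hi)
      if (max(abs(step)) < 1e-12) break
    }
    out_p[mid] <- p
    out_s[mid] <- hb_saturation(p)
  }
  list(sao2 = out_s, pao2 = out_p)
}

#' Predict arterial saturation from FiO2 under a shunt + V:Q-shift model
#'
#' Forward model behind the shunt estimator. End-capillary PO2 is the alveolar
#' PO2 reduced by a rightward displacement `vq_shift` (low regional V:Q lowers
#' effective alveolar oxygen tension), floored at zero. End-capillary content
#' follows from the dissociation curve; arterial content mixes shunted venous
#' blood with end-capillary blood, `Ca = (1 - Qs/Qt) Cc + Qs/Qt * Cv`, with the
#' venous side closed by a fixed arteriovenous content difference
#' `Cv = Ca - avDO2` and solved by damped fixed-point iteration. Arterial
#' saturation is then read back off the dissociation curve from the arterial
#' content.
#'
#' @param fio2 Inspired oxygen fraction, (0, 1].
#' @param qs_qt Intrapulmonary shunt fraction, [0, 1).
#' @param vq_shift Rightward displacement of the FiO2-SaO2 curve, mmHg (>= 0).
#' @param paco2 Arterial CO2 tension, mmHg.
#' @param hb Haemoglobin, g/dL; defaults to `constants$Hb_default`.
#' @param constants A [physio_constants()] object.
#' @return Predicted SaO2 as a fraction in [0, 1]. Vectorised over `qs_qt`
#'   and `vq_shift`.
#' @examples
#' predict_sao2(0.5, qs_qt = 0.2, vq_shift = 0, paco2 = 40)
#' predict_sao2(0.21, qs_qt = c(0.1, 0.3), vq_shift = 20, paco2 = 45)
#' @export
predict_sao2 <- function(fio2, qs_qt, vq_shift, paco2,
                         hb = NULL, constants = physio_constants()) {
  if (is.null(hb)) hb <- constants$Hb_default
  if (any(qs_qt < 0) || any(qs_qt >= 1)) {
    stop("predict_sao2: qs_qt must lie in [0, 1)", call. = FALSE)
  }
  if (any(vq_shift < 0)) stop("predict_sao2: vq_shift must be >= 0", call. = FALSE)
  n <- max(length(fio2), length(qs_qt), length(vq_shift), length(paco2))
  fio2 <- rep_len(fio2, n); qs_qt <- rep_len(qs_qt, n)
  vq_shift <- rep_len(vq_shift, n); paco2 <- rep_len(paco2, n)

  pao2_alv <- suppressWarnings(alveolar_po2(fio2, paco2, constants))
  pc <- pmax(pao2_alv - vq_shift, 0)
  cc <- o2_content(hb, hb_saturation(pc), pc, constants)

  # damped fixed point on arterial content: Ca <- (1-q) Cc + q (Ca - avDO2)
  ca <- cc
  lambda <- 0.5
  converged <- FALSE
  for (i in 1:100) {
    ca_new <- (1 - lambda) * ca + lambda * ((1 - qs_qt) * cc + qs_qt * (ca - constants$avDO2))
    if (max(abs(ca_new - ca)) < 1e-8) {
      ca <- ca_new
      converged <- TRUE
      break
    }
    ca <- ca_new
  }
  if (!converged) {
    stop("predict_sao2: arterial-content fixed point failed to converge in 100 iterations",
         call. = FALSE)
  }
  sao2_from_content(ca, hb, constants)$sao2
}

#' Fit shunt fraction and V:Q displacement to FiO2 step-down data
#'
#' Least-squares inversion of [predict_sao2()]: finds the (Qs/Qt, V:Q shift)
#' pair minimising the sum of squared SaO2 residuals over the observed FiO2
#' steps. The search is an exhaustive grid (Qs/Qt 0 to 0.6 by 0.01; shift 0 to
#' 200 mmHg by 2) followed by Nelder-Mead refinement from the grid optimum —
#' deterministic, no random restarts.
#'
#' @param steps A data frame with columns `fio2` (fraction), `sao2`
#'   (fraction or percent; percent is detected and rescaled), and `paco2`
#'   (mmHg). At least two distinct FiO2 values are required.
#' @param hb Haemoglobin, g/dL; defaults to `constants$Hb_default`.
#' @param constants A [physio_constants()] object.
#' @return An object of class `shunt_fit`: a list with elements `qs_qt`,
#'   `vq_shift`, `rss`, `n_points`, `converged`, and `data` (the normalised
#'   input). `tidy()` and `glance()` methods are provided.
#' @examples
#' steps <- data.frame(
#'   fio2 = c(0.5, 0.4, 0.3, 0.21), paco2 = 40,
#'   sao2 = predict_sao2(c(0.5, 0.4, 0.3, 0.21), 0.2, 20, 40)
#' )
#' fit_shunt_vq(steps)
#' @export
fit_shunt_vq <- function(steps, hb = NULL, constants = physio_constants()) {
  stopifnot(is.data.frame(steps))
  need <- c("fio2", "sao2", "paco2")
  miss <- setdiff(need, names(steps))
  if (length(miss)) {
    stop("fit_shunt_vq: missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(hb)) hb <- constants$Hb_default
  sao2 <- normalize_so2(steps$sao2)
  fio2 <- steps$fio2
  paco2 <- steps$paco2
  if (length(unique(fio2)) < 2) {
    stop("fit_shunt_vq: need at least 2 distinct FiO2 steps", call. = FALSE)
  }

  if (all(sao2 >= 0.995)) {
    warning("fit_shunt_vq: all SaO2 at ceiling; shunt unidentifiable, returning qs_qt = 0",
            call. = FALSE)
    pred <- predict_sao2(fio2, 0, 0, paco2, hb, constants)
    return(new_shunt_fit(0, 0, sum((pred - sao2)^2), length(sao2), FALSE,
                         tibble::tibble(fio2 = fio2, sao2 = sao2, paco2 = paco2)))
  }

  q_grid <- seq(0, 0.6, by = 0.01)
  v_grid <- seq(0, 200, by = 2)
  grid <- expand.grid(q = q_grid, v = v_grid)
  rss_grid <- numeric(nrow(grid))
  for (k in seq_along(fio2)) {
    pred <- predict_sao2(fio2[k], grid$q, grid$v, paco2[k], hb, constants)
    rss_grid <- rss_grid + (pred - sao2[k])^2
  }
  best <- which.min(rss_grid)
  start <- c(grid$q[best], grid$v[best])

  obj <- function(par) {
    q <- par[1]; v <- par[2]
    if (q < 0 || q > 0.65 || v < 0) return(1e6)
    pred <- tryCatch(predict_sao2(fio2, q, v, paco2, hb, constants),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    sum((pred - sao2)^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  # Nelder-Mead from a grid corner can stall; keep the better of grid and refined
  if (opt$value <= rss_grid[best]) {
    par <- opt$par; rss <- opt$value; conv <- opt$convergence == 0
  } else {
    par <- start; rss <- rss_grid[best]; conv <- TRUE
  }
  new_shunt_fit(max(0, min(par[1], 1)), max(0, par[2]), rss, length(sao2), conv,
                tibble::tibble(fio2 = fio2, sao2 = sao2, paco2 = paco2))
}

new_shunt_fit <- function(qs_qt, vq_shift, rss, n_points, converged, data) {
  structure(
    list(qs_qt = qs_qt, vq_shift = vq_shift, rss = rss,
         n_points = n_points, converged = converged, data = data),
    class = "shunt_fit"
  )
}

#' @export
print.shunt_fit <- function(x, ...) {
  cat("<shunt_fit>\n")
  cat(sprintf("  Qs/Qt      %.3f\n", x$qs_qt))
  cat(sprintf("  V:Q shift  %.1f mmHg\n", x$vq_shift))
  cat(sprintf("  RSS        %.3g over %d points (converged: %s)\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy shunt_fit
#' @export
tidy.shunt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("qs_qt", "vq_shift"),
    estimate = c(x$qs_qt, x$vq_shift)
  )
}

#' @method glance shunt_fit
#' @export
glance.shunt_fit <- function(x, ...) {
  tibble::tibble(
    qs_qt = x$qs_qt, vq_shift = x$vq_shift, rss = x$rss,
    n_points = x$n_points, converged = x$converged
  )
}

# Normalise an SO2 vector to fractions. Columns entirely <= 1 are taken as
# fractions; columns entirely > 1 as percent. A mix (e.g. a stray 1.5 among
# fractions) is rejected as a scale violation.
normalize_so2 <- function(x, what = "SO2") {
  x_ok <- x[is.finite(x)]
  if (!length(x_ok)) return(x)
  if (any(x_ok < 0)) stop(what, " values must be non-negative", call. = FALSE)
  if (all(x_ok <= 1)) return(x)
  if (all(x_ok > 1)) {
    if (any(x_ok > 100)) stop(what, " values above 100 are invalid", call. = FALSE)
    return(x / 100)
  }
  stop(what, " values mix fraction and percent scales (e.g. 1.5 among fractions)",
       call. = FALSE)
}
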