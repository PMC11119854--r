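#' Cerebral autoregulation nomogram
#'
#' Parameterises the reference ("expected") cerebral saturation as a function
#' of mean arterial pressure, PaCO2 and PaO2, against which observed rcSO2 is
#' scored. The model is piecewise-linear and multiplicative around the
#' animal's own baseline: flow (hence rcSO2) is pressure-independent across
#' the autoregulatory plateau and pressure-passive below it; CO2 reactivity is
#' linear around normocapnia (40 mmHg); intact hypoxic vasodilation augments
#' expected rcSO2 below a PaO2 threshold. All parameters are exposed because
#' published neonatal nomograms differ; defaults are plausible for term
#' neonates and every classification result in this package is checked by
#' parameter recovery, not by the specific default values.
#'
#' @param bp_lower,bp_upper Autoregulatory plateau limits, mmHg.
#' @param bp_passive_slope Fractional fall in expected rcSO2 per mmHg of mBP
#'   below `bp_lower`.
#' @param co2_reactivity Fractional change in expected rcSO2 per mmHg PaCO2
#'   away from 40 mmHg.
#' @param hypox_threshold PaO2 below which hypoxic flow augmentation begins,
#'   mmHg.
#' @param hypox_slope Fractional augmentation of expected rcSO2 per mmHg PaO2
#'   below `hypox_threshold`.
#' @param deviation_cut Relative deviation from the expected value beyond
#'   which autoregulation is called impaired (default 0.20).
#' @param trendline_ref Whether the deviation denominator is the nomogram
#'   `"expected"` value (default) or the animal's `"baseline"`.
#' @param hypox_driver Which measurement drives the hypoxemia attribution:
#'   arterial `"pao2"` (default) or `"sao2"`.
#' @param tie_break Factor priority when standardized excursions tie; default
#'   hypoxemia over blood pressure over CO2.
#' @return An object of class `autoreg_nomogram`.
#' @examples
#' autoreg_nomogram()
#' @export
autoreg_nomogram <- function(bp_lower = 40, bp_upper = 90,
                             bp_passive_slope = 0.01,
                             co2_reactivity = 0.03,
                             hypox_threshold = 50, hypox_slope = 0.012,
                             deviation_cut = 0.20,
                             trendline_ref = c("expected", "baseline"),
                             hypox_driver = c("pao2", "sao2"),
                             tie_break = c("o2", "bp", "co2")) {
  trendline_ref <- match.arg(trendline_ref)
  hypox_driver <- match.arg(hypox_driver)
  stopifnot(
    bp_lower < bp_upper,
    bp_passive_slope >= 0, co2_reactivity >= 0, hypox_slope >= 0,
    deviation_cut > 0, deviation_cut < 1,
    setequal(tie_break, c("o2", "bp", "co2"))
  )
  structure(
    list(bp_lower = bp_lower, bp_upper = bp_upper,
         bp_passive_slope = bp_passive_slope,
         co2_reactivity = co2_reactivity,
         hypox_threshold = hypox_threshold, hypox_slope = hypox_slope,
         deviation_cut = deviation_cut,
         trendline_ref = trendline_ref, hypox_driver = hypox_driver,
         tie_break = tie_break),
    class = "autoreg_nomogram"
  )
}

#' @export
print.autoreg_nomogram <- function(x, ...) {
  cat("<autoreg_nomogram>\n")
  cat(sprintf("  plateau          %g-%g mmHg (passive slope %g/mmHg below)\n",
              x$bp_lower, x$bp_upper, x$bp_passive_slope))
  cat(sprintf("  CO2 reactivity   %g/mmHg about 40 mmHg\n", x$co2_reactivity))
  cat(sprintf("  hypoxic augment  %g/mmHg below PaO2 %g mmHg\n",
              x$hypox_slope, x$hypox_threshold))
  cat(sprintf("  deviation cut    %g (ref: %s; hypoxemia driver: %s)\n",
              x$deviation_cut, x$trendline_ref, x$hypox_driver))
  invisible(x)
}

#' Read an autoregulation nomogram from a YAML file
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [autoreg_nomogram()]; missing keys keep their defaults.
#' @return An `autoreg_nomogram` object.
#' @export
read_nomogram <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(autoreg_nomogram)))
  do.call(autoreg_nomogram, vals[keep])
}

#' Expected cerebral saturation under intact autoregulation
#'
#' Evaluates the nomogram forward model:
#' `baseline_rcso2 * f_bp(mBP) * f_co2(PaCO2) * f_o2(PaO2)`, where `f_bp` is 1
#' on the plateau and declines linearly below its lower limit, `f_co2` is
#' `1 + co2_reactivity * (PaCO2 - 40)`, and `f_o2` is
#' `1 + hypox_slope * max(0, hypox_threshold - PaO2)` (intact hypoxic flow
#' augmentation raises regional saturation relative to an unregulated bed).
#' Output is clamped to [0, 100].
#'
#' @param nomogram An [autoreg_nomogram()].
#' @param mbp Mean arterial pressure, mmHg.
#' @param pao2 Arterial PO2, mmHg.
#' @param paco2 Arterial PCO2, mmHg.
#' @param baseline_rcso2 The animal's baseline rcSO2, percent.
#' @return Expected rcSO2, percent. Vectorised.
#' @examples
#' expected_rcso2(autoreg_nomogram(), mbp = 60, pao2 = 100, paco2 = 40,
#'                baseline_rcso2 = 50)
#' @export
expected_rcso2 <- function(nomogram, mbp, pao2, paco2, baseline_rcso2) {
  stopifnot(inherits(nomogram, "autoreg_nomogram"))
  if (any(is.na(baseline_rcso2))) {
    stop("expected_rcso2: baseline rcSO2 is required", call. = FALSE)
  }
  if (any(mbp < 10 | mbp > 200)) {
    warning("expected_rcso2: mBP outside [10, 200] mmHg", call. = FALSE)
  }
  f_bp <- ifelse(mbp >= nomogram$bp_lower, 1,
                 1 - nomogram$bp_passive_slope * (nomogram$bp_lower - mbp))
  f_co2 <- 1 + nomogram$co2_reactivity * (paco2 - 40)
  f_o2 <- 1 + nomogram$hypox_slope * pmax(0, nomogram$hypox_threshold - pao2)
  pmin(pmax(baseline_rcso2 * pmax(f_bp, 0) * pmax(f_co2, 0) * f_o2, 0), 100)
}

autoreg_labels <- c("intact", "impaired_bp", "impaired_o2", "impaired_co2",
                    "impaired_unattributed")

#' Classify cerebral autoregulation observations
#'
#' For each observation, compares measured rcSO2 with the nomogram-expected
#' value. The deviation is `(rcSO2 - expected) / expected` (or `/ baseline`
#' when the nomogram's `trendline_ref` is `"baseline"`). Observations within
#' the cut, or above expectation, are `intact`; only desaturation beyond the
#' cut is called impaired. Impairment is attributed to the physiological
#' factor with the largest standardized excursion:
#' * blood pressure — the larger of the plateau shortfall
#'   `max(0, bp_lower - mBP) / bp_lower` and the relative mBP drop from the
#'   animal's baseline;
#' * hypoxemia — `max(0, hypox_threshold - PaO2) / hypox_threshold` (or the
#'   analogous SaO2 shortfall below 90% when `hypox_driver = "sao2"`);
#' * CO2 — `|PaCO2 - 40| / 40`.
#' Ties break by the nomogram's `tie_break` order (default hypoxemia, then
#' pressure, then CO2). An impaired observation with all excursions zero is
#' labelled `impaired_unattributed` with a warning.
#'
#' @param observations A data frame with columns `mbp`, `pao2`, `paco2`,
#'   `rcso2`, `baseline_rcso2`, and optionally `sao2` (needed when
#'   `hypox_driver = "sao2"`), `baseline_mbp`, plus any id columns, which are
#'   carried through.
#' @param nomogram An [autoreg_nomogram()].
#' @return The input as a tibble with `expected`, `deviation`, `exc_bp`,
#'   `exc_o2`, `exc_co2` and `autoreg` (factor) columns appended.
#' @examples
#' obs <- data.frame(mbp = c(60, 28), pao2 = c(100, 95), paco2 = 40,
#'                   rcso2 = c(50, 30), baseline_rcso2 = 50)
#' classify_autoreg(obs)
#' @export
classify_autoreg <- function(observations, nomogram = autoreg_nomogram()) {
  stopifnot(is.data.frame(observations), inherits(nomogram, "autoreg_nomogram"))
  need <- c("mbp", "pao2", "paco2", "rcso2", "baseline_rcso2")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("classify_autoreg: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  obs <- tibble::as_tibble(observations)
  expected <- expected_rcso2(nomogram, obs$mbp, obs$pao2, obs$paco2,
                             obs$baseline_rcso2)
  ref <- if (nomogram$trendline_ref == "expected") expected else obs$baseline_rcso2
  deviation <- (obs$rcso2 - expected) / ref

  exc_bp_plateau <- pmax(0, nomogram$bp_lower - obs$mbp) / nomogram$bp_lower
  exc_bp_base <- if ("baseline_mbp" %in% names(obs)) {
    pmax(0, obs$baseline_mbp - obs$mbp) / obs$baseline_mbp
  } else {
    0
  }
  exc_bp <- pmax(exc_bp_plateau, exc_bp_base)
  exc_o2 <- if (nomogram$hypox_driver == "pao2") {
    pmax(0, nomogram$hypox_threshold - obs$pao2) / nomogram$hypox_threshold
  } else {
    if (!"sao2" %in% names(obs)) {
      stop("classify_autoreg: hypox_driver = 'sao2' requires an sao2 column",
           call. = FALSE)
    }
    pmax(0, 0.90 - normalize_so2(obs$sao2, "SaO2")) / 0.90
  }
  exc_co2 <- abs(obs$paco2 - 40) / 40

  exc <- cbind(o2 = exc_o2, bp = exc_bp, co2 = exc_co2)
  exc <- exc[, nomogram$tie_break, drop = FALSE] # tie-break by column order
  winner <- nomogram$tie_break[max.col(exc, ties.method = "first")]
  label <- ifelse(
    deviation >= -nomogram$deviation_cut,
    "intact",
    ifelse(exc[cbind(seq_len(nrow(exc)), max.col(exc, ties.method = "first"))] > 0,
           paste0("impaired_", winner), "impaired_unattributed")
  )
  if (any(label == "impaired_unattributed")) {
    warning("classify_autoreg: impaired observations with no measurable excursion",
            call. = FALSE)
  }
  obs$expected <- expected
  obs$deviation <- deviation
  obs$exc_bp <- exc_bp
  obs$exc_o2 <- exc_o2
  obs$exc_co2 <- exc_co2
  obs$autoreg <- factor(label, levels = autoreg_labels)
  obs
}

#' Tabulate autoregulation classes by group and period
#'
#' @param observations A data frame accepted by [classify_autoreg()] with
#'   additional `group` and `period` columns.
#' @param nomogram An [autoreg_nomogram()].
#' @return A tibble of counts and within-cell proportions, one row per
#'   group x period x class (classes with zero counts included).
#' @examples
#' obs <- data.frame(group = "control", period = "fio2_21", mbp = 60,
#'                   pao2 = 100, paco2 = 40, rcso2 = 50, baseline_rcso2 = 50)
#' attribute_cohort(obs)
#' @export
attribute_cohort <- function(observations, nomogram = autoreg_nomogram()) {
  need <- c("group", "period")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("attribute_cohort: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  classified <- classify_autoreg(observations, nomogram)
  classified |>
    dplyr::count(.data$group, .data$period, .data$autoreg, .drop = FALSE,
                 name = "n") |>
    dplyr::group_by(.data$group, .data$period) |>
    dplyr::mutate(
      n_cell = sum(.data$n),
      proportion = ifelse(.data$n_cell > 0, .data$n / .data$n_cell, NA_real_)
    ) |>
    dplyr::ungroup()
}

#' Chi-squared comparison of class distributions between groups
#'
#' Pearson chi-squared test without continuity correction on the
#' control-versus-injury contingency table of autoregulation classes.
#'
#' @param control_counts,oa_counts Non-negative integer vectors of per-class
#'   counts, same length (>= 2), aligned by class.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' compare_groups_chi2(c(10, 0), c(0, 10))
#' @export
compare_groups_chi2 <- function(control_counts, oa_counts) {
  stopifnot(length(control_counts) == length(oa_counts),
            all(control_counts >= 0), all(oa_counts >= 0))
  tab <- rbind(control = control_counts, oa = oa_counts)
  # drop all-zero class columns so that df reflects observed classes
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) {
    stop("compare_groups_chi2: fewer than 2 classes with observations", call. = FALSE)
  }
  if (any(rowSums(tab) == 0)) {
    bad <- rownames(tab)[rowSums(tab) == 0]
    stop("compare_groups_chi2: zero marginal total for group: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}
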