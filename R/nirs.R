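#' Fractional oxygen extraction
#'
#' `foe_from_nirs()` computes regional fractional oxygen extraction from
#' arterial saturation and an NIRS regional saturation,
#' FOE = (SaO2 - rSO2) / SaO2: the fraction of delivered oxygen removed by the
#' tissue bed under the probe. `foe_from_gases()` is the same quantity with a
#' co-oximetry venous saturation (SvO2) in place of the NIRS reading, used to
#' validate NIRS-derived extraction against regional blood gases.
#'
#' Inputs on the percent scale (all values > 1) are detected and rescaled to
#' fractions; both arguments must use the same scale.
#'
#' @param sao2 Arterial saturation, fraction in (0, 1] (or percent).
#' @param rso2 Regional NIRS saturation, fraction in [0, 1] (or percent).
#' @return FOE as a fraction. Vectorised.
#' @examples
#' foe_from_nirs(0.96, 0.48)
#' foe_from_gases(0.95, 0.70)
#' @export
foe_from_nirs <- function(sao2, rso2) {
  sao2 <- normalize_so2(sao2, "SaO2")
  rso2 <- normalize_so2(rso2, "rSO2")
  if (any(sao2 <= 0)) stop("foe_from_nirs: SaO2 must be > 0", call. = FALSE)
  (sao2 - rso2) / sao2
}

#' @rdname foe_from_nirs
#' @param svo2 Regional venous saturation, fraction in [0, 1] (or percent).
#' @export
foe_from_gases <- function(sao2, svo2) {
  foe_from_nirs(sao2, svo2)
}

#' Per-animal change from baseline
#'
#' With each animal serving as its own control, computes absolute and relative
#' deltas of a measurement against that animal's baseline-period value, within
#' groups defined by `animal_id` and `site`.
#'
#' @param data A data frame with columns `animal_id`, `period`, `value`, and
#'   optionally `site` (grouping is per animal x site when present).
#' @param baseline_period Label of the baseline period (default `"baseline"`).
#' @return The input as a tibble with `baseline`, `delta_abs`
#'   (value - baseline) and `delta_rel` ((value - baseline) / baseline)
#'   columns appended. The baseline row has both deltas equal to 0.
#' @examples
#' d <- data.frame(animal_id = 1, period = c("baseline", "fio2_21"),
#'                 value = c(50.4, 41.2))
#' delta_from_baseline(d)
#' @export
delta_from_baseline <- function(data, baseline_period = "baseline") {
  stopifnot(is.data.frame(data))
  need <- c("animal_id", "period", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("delta_from_baseline: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keys <- intersect(c("animal_id", "site"), names(data))
  out <- data |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      baseline = {
        b <- .data$value[.data$period == baseline_period]
        if (length(b) != 1L) {
          key <- paste(vapply(dplyr::cur_group(), as.character, character(1)),
                       collapse = "/")
          stop("delta_from_baseline: no unique baseline for ", key, call. = FALSE)
        }
        b
      },
      delta_abs = .data$value - .data$baseline,
      delta_rel = (.data$value - .data$baseline) / .data$baseline
    ) |>
    dplyr::ungroup()
  out
}

#' Cerebral desaturation risk flags
#'
#' Flags an rSO2 reading as at-risk when the absolute value falls below 45%
#' or when it has dropped by more than 20% relative to the animal's own
#' baseline. Both thresholds are strict inequalities: exactly 45% or exactly
#' a 20% drop is not flagged.
#'
#' @param rso2 Regional saturation, percent scale, in [0, 100].
#' @param baseline Baseline regional saturation, percent, in (0, 100].
#' @param abs_threshold Absolute threshold, percent (default 45).
#' @param drop_threshold Relative-drop threshold as a fraction (default 0.20).
#' @return A tibble with columns `below_45`, `drop_gt20` (logical) and
#'   `relative_drop` (positive fraction when below baseline). Vectorised.
#' @examples
#' flag_risk(c(44.9, 45, 39), c(50, 45, 50))
#' @export
flag_risk <- function(rso2, baseline, abs_threshold = 45, drop_threshold = 0.20) {
  stopifnot(all(rso2 >= 0), all(rso2 <= 100), all(baseline > 0), all(baseline <= 100))
  rel_drop <- (baseline - rso2) / baseline
  tibble::tibble(
    below_45 = rso2 < abs_threshold,
    drop_gt20 = rel_drop > drop_threshold,
    relative_drop = rel_drop
  )
}

sao2_bin_levels <- c("95-100", "90-95", "85-90", "<85")

# Assign percent-scale SaO2 values to the published four ranges:
# half-open [lower, upper) except the top bin, closed at 100.
assign_sao2_bin <- function(sao2_pct) {
  stopifnot(all(sao2_pct >= 0), all(sao2_pct <= 100))
  cut(sao2_pct,
      breaks = c(-Inf, 85, 90, 95, 100),
      labels = rev(sao2_bin_levels),
      right = FALSE) |>
    as.character() |>
    (\(x) ifelse(sao2_pct == 100, "95-100", x))() |>
    factor(levels = sao2_bin_levels)
}

# round half away from zero, matching printed percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise cerebral NIRS by arterial-saturation range
#'
#' Bins post-injury observations into the arterial saturation ranges 95-100,
#' 90-95, 85-90 and <85 percent (half-open [lower, upper), top bin closed at
#' 100) and tabulates, per group and range: the number of observations, mean
#' and standard error of rcSO2, and the number and percent of readings more
#' than 20% below the animal's baseline.
#'
#' @param observations A data frame with columns `sao2` (percent or fraction),
#'   `rcso2` (percent), `group`, and `baseline` (percent). Baseline-period
#'   rows should be excluded before calling.
#' @param drop_threshold Relative-drop threshold (default 0.20).
#' @return A tibble with one row per group x saturation range: `group`,
#'   `sao2_range`, `n`, `mean_rcso2`, `se_rcso2`, `n_flagged`, `pct_flagged`.
#'   Empty bins are reported with `n = 0` and `NA` statistics.
#' @examples
#' obs <- data.frame(sao2 = c(97, 88, 82), rcso2 = c(48, 36, 30),
#'                   group = "oa", baseline = 54)
#' bin_by_sao2(obs)
#' @export
bin_by_sao2 <- function(observations, drop_threshold = 0.20) {
  stopifnot(is.data.frame(observations))
  need <- c("sao2", "rcso2", "group", "baseline")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("bin_by_sao2: missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::as_tibble(observations)
  sao2_pct <- normalize_so2(obs$sao2, "SaO2") * 100
  obs$sao2_range <- assign_sao2_bin(sao2_pct)
  obs$flagged <- (obs$baseline - obs$rcso2) / obs$baseline > drop_threshold

  obs |>
    dplyr::group_by(.data$group, .data$sao2_range, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rcso2 = if (dplyr::n() > 0) mean(.data$rcso2) else NA_real_,
      se_rcso2 = if (dplyr::n() > 1) stats::sd(.data$rcso2) / sqrt(dplyr::n()) else NA_real_,
      n_flagged = sum(.data$flagged),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_rcso2 = ifelse(.data$n == 0, NA_real_, .data$mean_rcso2),
      pct_flagged = ifelse(.data$n == 0, NA_real_,
                           round_half_up(100 * .data$n_flagged / .data$n))
    )
}

#' Ordinary least-squares linear trend
#'
#' Simple linear regression used for slope comparisons of regional saturation
#' or extraction against PaO2 or FiO2.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points.
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' fit_linear_trend(1:5, 2 * (1:5) + 1)
#' @export
fit_linear_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fit_linear_trend: need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("fit_linear_trend: degenerate design (identical x values)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_,
    n = length(x)
  )
}
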