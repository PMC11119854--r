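cohort_mandatory_cols <- c("animal_id", "group", "period", "fio2", "sao2",
                           "paco2", "nirs_brain", "mbp")
cohort_numeric_cols <- c("fio2", "weight", "vt_ml", "rr", "peep", "sao2",
                         "pao2", "paco2", "ph", "hco3", "svc_so2", "svc_po2",
                         "ivc_so2", "ivc_po2", "nirs_brain", "nirs_gut",
                         "nirs_kidney", "mbp", "hr", "cvp", "temp")

#' Read and write cohort data
#'
#' `write_cohort()` writes the per-period table of a cohort to CSV;
#' `read_cohort()` reads it back with schema validation: mandatory columns
#' must be present, period labels must come from the fixed five-period
#' vocabulary, numeric columns must parse, each (animal, period) may appear
#' at most once, and saturation columns must respect their scale (fractions
#' in [0, 1] for blood-gas saturations, percent in [0, 100] for NIRS).
#' Unknown columns are preserved with a warning. `read_cohort(write_cohort(x))`
#' returns the same table.
#'
#' @param cohort A `neonoxy_cohort` or a data frame shaped like its `data`.
#' @param path File path.
#' @return `read_cohort()` returns a `neonoxy_cohort` (without waveforms or
#'   ground truth); `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  data <- if (inherits(cohort, "neonoxy_cohort")) cohort$data else cohort
  stopifnot(is.data.frame(data))
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
  miss <- setdiff(cohort_mandatory_cols, names(data))
  if (length(miss)) {
    stop("read_cohort: missing mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(data), c(cohort_mandatory_cols, cohort_numeric_cols))
  if (length(unknown)) {
    warning("read_cohort: unknown columns preserved: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  for (col in intersect(cohort_numeric_cols, names(data))) {
    if (!is.numeric(data[[col]])) {
      v <- suppressWarnings(as.numeric(data[[col]]))
      if (any(is.na(v) & !is.na(data[[col]]))) {
        bad <- which(is.na(v) & !is.na(data[[col]]))[1]
        stop("read_cohort: non-numeric value in column '", col, "' at data row ",
             bad, call. = FALSE)
      }
      data[[col]] <- v
    }
  }
  bad_period <- setdiff(unique(data$period), names(step_periods()))
  if (length(bad_period)) {
    stop("read_cohort: unknown period labels: ", paste(bad_period, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data[c("animal_id", "period")])) {
    stop("read_cohort: duplicated (animal_id, period) records", call. = FALSE)
  }
  for (col in intersect(c("sao2", "svc_so2", "ivc_so2"), names(data))) {
    v <- data[[col]][is.finite(data[[col]])]
    if (length(v) && (any(v < 0) || (any(v > 1) && any(v <= 1)) || any(v > 100))) {
      stop("read_cohort: column '", col, "' violates its saturation scale ",
           "(fractions in [0, 1], or percent throughout)", call. = FALSE)
    }
    data[[col]] <- normalize_so2(data[[col]], col)
  }
  for (col in intersect(c("nirs_brain", "nirs_gut", "nirs_kidney"), names(data))) {
    v <- data[[col]][is.finite(data[[col]])]
    if (length(v) && (any(v < 0) || any(v > 100))) {
      stop("read_cohort: NIRS column '", col, "' outside [0, 100] percent",
           call. = FALSE)
    }
  }
  structure(
    list(data = tibble::as_tibble(data), truth = NULL, waveforms = NULL,
         master_seed = NA_integer_),
    class = "neonoxy_cohort"
  )
}

#' Packaged reference tables
#'
#' The study's printed summary tables, shipped as plain-text fixtures:
#' `"hemodynamics"` (group characteristics by period), `"regional_nirs"`
#' (mean and SE of brain, gut and kidney NIRS by group and period) and
#' `"sao2_bins"` (cerebral NIRS grouped by arterial-saturation range, with
#' flagged counts).
#'
#' @param name Which table to load.
#' @return A tibble.
#' @examples
#' reference_table("regional_nirs")
#' @export
reference_table <- function(name = c("hemodynamics", "regional_nirs", "sao2_bins")) {
  name <- match.arg(name)
  file <- c(hemodynamics = "table1_hemodynamics.csv",
            regional_nirs = "table2_regional_nirs.csv",
            sao2_bins = "table3_sao2_bins.csv")[[name]]
  path <- system.file("extdata", file, package = "neonoxy", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

post_injury_periods <- function() setdiff(names(step_periods()), "baseline")

#' Run the full analysis pipeline on a cohort
#'
#' Chains every stage of the package over a cohort: per-animal shunt/V:Q fits
#' on the post-injury FiO2 steps, regional fractional oxygen extraction with
#' baseline deltas and risk flags, the saturation-range binning table,
#' autoregulation classification with per-period and pooled chi-squared group
#' comparisons, and (when waveforms are attached) respiratory-mechanics fits.
#' The result is deterministic given the cohort and carries a manifest of
#' content hashes for every component.
#'
#' @param cohort A `neonoxy_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param nomogram An [autoreg_nomogram()].
#' @param constants A [physio_constants()] object.
#' @return An object of class `neonoxy_report`: a list with tibbles
#'   `shunt`, `foe`, `bins`, `autoreg_counts`, `autoreg_chi2`, `mechanics`
#'   (NULL without waveforms) and `manifest`.
#' @examples
#' coh <- generate_cohort(2, 2, master_seed = 1, waveforms = FALSE)
#' rep <- run_report(coh)
#' rep$bins
#' @export
run_report <- function(cohort, nomogram = autoreg_nomogram(),
                       constants = physio_constants()) {
  stopifnot(inherits(cohort, "neonoxy_cohort"))
  data <- cohort$data

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_report: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  shunt <- stage("shunt", {
    data |>
      dplyr::filter(.data$period %in% post_injury_periods()) |>
      dplyr::group_by(.data$animal_id, .data$group) |>
      dplyr::group_modify(function(d, key) {
        glance(fit_shunt_vq(d[c("fio2", "sao2", "paco2")], constants = constants))
      }) |>
      dplyr::ungroup()
  })

  foe <- stage("foe", {
    long <- data |>
      tidyr::pivot_longer(dplyr::all_of(c("nirs_brain", "nirs_gut", "nirs_kidney")),
                          names_to = "site", names_prefix = "nirs_",
                          values_to = "rso2") |>
      dplyr::select(dplyr::all_of(c("animal_id", "group", "period", "site",
                                    "sao2", "rso2")))
    long$foe <- foe_from_nirs(long$sao2, long$rso2 / 100)
    base <- long |>
      dplyr::filter(.data$period == "baseline") |>
      dplyr::select(dplyr::all_of(c("animal_id", "site")), baseline_rso2 = "rso2")
    long <- dplyr::left_join(long, base, by = c("animal_id", "site"))
    flags <- flag_risk(long$rso2, long$baseline_rso2)
    dplyr::bind_cols(long, flags)
  })

  bins <- stage("bins", {
    base <- data |>
      dplyr::filter(.data$period == "baseline") |>
      dplyr::select(dplyr::all_of(c("animal_id")), baseline = "nirs_brain")
    data |>
      dplyr::filter(.data$period %in% post_injury_periods()) |>
      dplyr::left_join(base, by = "animal_id") |>
      dplyr::select(dplyr::all_of(c("sao2", "group", "baseline")),
                    rcso2 = "nirs_brain") |>
      bin_by_sao2()
  })

  autoreg_in <- stage("autoreg", {
    base <- data |>
      dplyr::filter(.data$period == "baseline") |>
      dplyr::select(dplyr::all_of(c("animal_id")),
                    baseline_rcso2 = "nirs_brain", baseline_mbp = "mbp")
    obs <- data |>
      dplyr::filter(.data$period %in% post_injury_periods()) |>
      dplyr::left_join(base, by = "animal_id") |>
      dplyr::select(dplyr::all_of(c("animal_id", "group", "period", "mbp",
                                    "pao2", "paco2", "sao2", "baseline_rcso2",
                                    "baseline_mbp")),
                    rcso2 = "nirs_brain")
    obs
  })
  autoreg_counts <- stage("autoreg", attribute_cohort(autoreg_in, nomogram))

  autoreg_chi2 <- stage("autoreg_chi2", {
    per_period <- purrr::map(post_injury_periods(), function(p) {
      cell <- autoreg_counts |> dplyr::filter(.data$period == p)
      ctr <- cell$n[cell$group == "control"]
      oa <- cell$n[cell$group == "oa"]
      res <- tryCatch(compare_groups_chi2(ctr, oa),
                      error = function(e) tibble::tibble(
                        statistic = NA_real_, df = NA_real_, p_value = NA_real_))
      dplyr::bind_cols(tibble::tibble(period = p), res)
    })
    pooled <- autoreg_counts |>
      dplyr::group_by(.data$group, .data$autoreg) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    ctr <- pooled$n[pooled$group == "control"]
    oa <- pooled$n[pooled$group == "oa"]
    pooled_res <- tryCatch(compare_groups_chi2(ctr, oa),
                           error = function(e) tibble::tibble(
                             statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    dplyr::bind_rows(purrr::list_rbind(per_period),
                     dplyr::bind_cols(tibble::tibble(period = "pooled"), pooled_res))
  })

  mechanics <- NULL
  if (!is.null(cohort$waveforms)) {
    mechanics <- stage("mechanics", {
      purrr::list_rbind(purrr::imap(cohort$waveforms, function(wlist, id) {
        purrr::list_rbind(purrr::imap(wlist, function(w, per) {
          dplyr::bind_cols(tibble::tibble(animal_id = id, period = per),
                           glance(fit_single_compartment(w)))
        }))
      }))
    })
  }

  components <- list(shunt = shunt, foe = foe, bins = bins,
                     autoreg_counts = autoreg_counts,
                     autoreg_chi2 = autoreg_chi2, mechanics = mechanics)
  manifest <- tibble::tibble(
    component = names(components),
    rows = vapply(components, function(x) if (is.null(x)) 0L else nrow(x), integer(1)),
    hash = vapply(components, rlang::hash, character(1))
  )
  structure(c(components, list(manifest = manifest)), class = "neonoxy_report")
}

#' @export
print.neonoxy_report <- function(x, ...) {
  cat("<neonoxy_report>\n")
  print(x$manifest)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each tabular component of a [run_report()] result as CSV into
#' `dir`, plus a JSON manifest of row counts and content hashes.
#'
#' @param report A `neonoxy_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "neonoxy_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(report), "manifest")) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
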