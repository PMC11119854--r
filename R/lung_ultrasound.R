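#' Lung-ultrasound zone names
#'
#' Eight zones: three anterior (upper, middle, lower) plus one posterolateral
#' zone per lung. Each zone scores 0 (A-lines only), 1 (>= 3 well-spaced
#' B-lines), 2 (crowded B-lines and/or subpleural consolidation) or 3
#' (extended consolidation), so the composite ranges 0-24.
#'
#' @return Character vector of the 8 zone column names.
#' @examples
#' lus_zones()
#' @export
lus_zones <- function() {
  as.vector(outer(c("left", "right"),
                  c("ant_upper", "ant_middle", "ant_lower", "posterolateral"),
                  paste, sep = "_"))
}

#' Composite lung-ultrasound aeration score
#'
#' Sums the 8 per-zone scores of each exam row; maximum 24 per animal.
#'
#' @param exams A data frame with one row per exam and the 8 zone columns of
#'   [lus_zones()] holding integer scores in 0..3. Additional columns
#'   (e.g. `animal_id`, `period`) are carried through.
#' @return The input as a tibble with a `lus_total` column appended.
#' @examples
#' exam <- as.data.frame(as.list(setNames(rep(3, 8), lus_zones())))
#' composite_score(exam)$lus_total
#' @export
composite_score <- function(exams) {
  stopifnot(is.data.frame(exams))
  zones <- lus_zones()
  miss <- setdiff(zones, names(exams))
  if (length(miss)) {
    stop("composite_score: missing zone columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (z in zones) {
    v <- exams[[z]]
    bad <- !is.finite(v) | v != as.integer(v) | v < 0 | v > 3
    if (any(bad)) {
      stop("composite_score: zone '", z, "' has scores outside {0, 1, 2, 3} at row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  out <- tibble::as_tibble(exams)
  out$lus_total <- as.integer(rowSums(out[zones]))
  out
}
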