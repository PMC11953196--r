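#' Fit cohort min-max normalization bounds for PRA and LA
#'
#' The index is cohort-relative: photoreceptor-remnant area (PRA) and
#' luminal area (LA) are rescaled by the min-max method using the minima and
#' maxima observed in the study cohort, so the normalized variables span
#' exactly \[0, 1\] within that cohort.  A cohort in which either channel has
#' zero range leaves the rescaling undefined and is rejected.
#'
#' @param cohort Either a list of [`area_set`][compute_pra] objects or a data
#'   frame with columns `la_mm2` and either `pra_mm2` or `ta_mm2` (PRA then
#'   derived as `ta_mm2 - la_mm2`).
#' @return An object of class `piin_normalization`: list with `pra_min`,
#'   `pra_max`, `la_min`, `la_max` (mm^2) and `cohort_size`.
#' @seealso [normalize_areas()], [compute_piin()], [score_cohort()]
#' @export
fit_normalization <- function(cohort) {
  if (is.data.frame(cohort)) {
    la <- cohort$la_mm2
    if (is.null(la)) stop("cohort data frame needs a la_mm2 column")
    pra <- cohort$pra_mm2
    if (is.null(pra)) {
      if (is.null(cohort$ta_mm2)) stop("cohort needs pra_mm2 or ta_mm2")
      pra <- cohort$ta_mm2 - la
    }
  } else if (is.list(cohort) && all(vapply(cohort, is_area_set, logical(1L)))) {
    la <- vapply(cohort, `[[`, numeric(1L), "luminal_area")
    pra <- vapply(cohort, `[[`, numeric(1L), "photoreceptor_area")
  } else {
    stop("cohort must be a data frame or a list of area_set objects")
  }
  keep <- !(is.na(la) | is.na(pra))
  la <- la[keep]; pra <- pra[keep]
  n <- length(la)
  if (n < 2L) stop("degenerate cohort: at least two eyes are required")
  if (min(pra) == max(pra) || min(la) == max(la))
    stop("degenerate cohort: zero range in PRA or LA leaves min-max ",
         "normalization undefined")
  structure(
    list(pra_min = min(pra), pra_max = max(pra),
         la_min = min(la), la_max = max(la), cohort_size = n),
    class = "piin_normalization")
}

#' @export
print.piin_normalization <- function(x, ...) {
  cat(sprintf(
    "Min-max normalization bounds (n = %d eyes)\n  PRA: [%.4f, %.4f] mm^2\n  LA : [%.4f, %.4f] mm^2\n",
    x$cohort_size, x$pra_min, x$pra_max, x$la_min, x$la_max))
  invisible(x)
}

minmax_scale <- function(x, lo, hi, clamp, what) {
  y <- (x - lo) / (hi - lo)
  out <- !is.na(y) & (y < 0 | y > 1)
  if (any(out)) {
    if (!clamp)
      stop("out-of-cohort value: ", what, " outside the fitted range [",
           lo, ", ", hi, "]; refit the model or use clamp = TRUE")
    y <- pmin(pmax(y, 0), 1)
  }
  y
}

#' Min-max normalize an eye's areas under a fitted cohort model
#'
#' Applies `(x - min) / (max - min)` per channel using the cohort bounds
#' from [fit_normalization()].  Within the fitting cohort the result lies in
#' \[0, 1\] by construction; for a prospective eye outside the fitted range,
#' `clamp = TRUE` maps it to the nearest endpoint while the default
#' `clamp = FALSE` raises an error.
#'
#' @param model A `piin_normalization` object.
#' @param areas An `area_set`, or a data frame with `la_mm2` and `pra_mm2`.
#' @param clamp Clamp out-of-range values into \[0, 1\]? Default `FALSE`.
#' @return A list (or data frame columns) with `norm_pra` and `norm_la`,
#'   each dimensionless in \[0, 1\].
#' @export
normalize_areas <- function(model, areas, clamp = FALSE) {
  if (!inherits(model, "piin_normalization"))
    stop("model must come from fit_normalization()")
  if (is_area_set(areas)) {
    pra <- areas$photoreceptor_area; la <- areas$luminal_area
  } else if (is.data.frame(areas)) {
    pra <- areas$pra_mm2; la <- areas$la_mm2
    if (is.null(pra) || is.null(la)) stop("areas needs pra_mm2 and la_mm2")
  } else stop("areas must be an area_set or a data frame")
  list(norm_pra = minmax_scale(pra, model$pra_min, model$pra_max, clamp, "PRA"),
       norm_la  = minmax_scale(la, model$la_min, model$la_max, clamp, "LA"))
}

#' The Photoreceptor Integrity Index
#'
#' `PIIN = NORM-PRA / (NORM-LA + 1)`.  Adding 1 to the denominator avoids
#' division by zero at the cohort's luminal-area minimum; with both inputs
#' in \[0, 1\] the index is bounded, `0 <= PIIN <= 1`.  Values near 0 mean
#' poor photoreceptor survival at the hole edge, values near 1 maximal
#' survival.
#'
#' @param norm_pra Normalized photoreceptor-remnant area in \[0, 1\]
#'   (vectorised), or the list returned by [normalize_areas()].
#' @param norm_la Normalized luminal area in \[0, 1\]; ignored when
#'   `norm_pra` is a `normalize_areas()` result.
#' @return Numeric vector of index values in \[0, 1\].
#' @examples
#' compute_piin(1, 0)    # 1: maximal survival
#' compute_piin(0.5, 1)  # 0.25
#' @export
compute_piin <- function(norm_pra, norm_la = NULL) {
  if (is.list(norm_pra) && !is.null(norm_pra$norm_pra)) {
    norm_la <- norm_pra$norm_la
    norm_pra <- norm_pra$norm_pra
  }
  if (any(norm_pra < -1e-12 | norm_pra > 1 + 1e-12, na.rm = TRUE) ||
      any(norm_la < -1e-12 | norm_la > 1 + 1e-12, na.rm = TRUE))
    stop("normalized inputs must lie in [0, 1]")
  norm_pra / (norm_la + 1)
}

#' Score a whole cohort: normalization fit plus per-eye index
#'
#' Fits min-max normalization on the full cohort, then adds the derived
#' per-eye columns: `pra_mm2` (if absent), `norm_pra`, `norm_la`, `piin`,
#' `ivts_class` (when `minimum_diameter_um` is present) and the absolute
#' delta columns (when T0/T1 pairs are present).  Row order is preserved.
#'
#' @param cohort A cohort data frame with at least `la_mm2` and `ta_mm2`.
#' @param clamp Passed to [normalize_areas()]; with the default `FALSE` the
#'   fitting cohort itself can never be out of range.
#' @return A list with `cohort` (the scored data frame) and `model` (the
#'   fitted `piin_normalization`).
#' @export
score_cohort <- function(cohort, clamp = FALSE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  if (is.null(cohort$la_mm2) || is.null(cohort$ta_mm2))
    stop("cohort needs la_mm2 and ta_mm2 columns")
  bad <- which(!is.na(cohort$la_mm2) & !is.na(cohort$ta_mm2) &
                 (cohort$ta_mm2 <= 0 | cohort$la_mm2 < 0 |
                    cohort$la_mm2 > cohort$ta_mm2))
  if (length(bad))
    stop("inconsistent segmentation in rows: ", paste(bad, collapse = ", "))
  if (is.null(cohort$pra_mm2))
    cohort$pra_mm2 <- cohort$ta_mm2 - cohort$la_mm2
  model <- fit_normalization(cohort)
  nn <- normalize_areas(model, cohort, clamp = clamp)
  cohort$norm_pra <- nn$norm_pra
  cohort$norm_la <- nn$norm_la
  cohort$piin <- compute_piin(nn$norm_pra, nn$norm_la)
  if (!is.null(cohort$minimum_diameter_um))
    cohort$ivts_class <- classify_ivts(cohort$minimum_diameter_um)
  cohort <- compute_deltas(cohort)
  list(cohort = cohort, model = model)
}
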