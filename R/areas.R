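#' Area triple for one eye: total, luminal, photoreceptor-remnant
#'
#' The en-face protocol measures two areas per eye: the total hole area
#' (`TA`, the region enclosed by the hyperreflective circumferential line
#' where surviving photoreceptors lodge) and the luminal area (`LA`, the
#' dark central lumen).  The photoreceptor-remnant area is their difference,
#' `PRA = TA - LA`, the annulus of surviving photoreceptors at the hole
#' edge.  `compute_pra()` constructs the triple and enforces the identity
#' exactly.
#'
#' @param total_area Total hole area in mm^2; must be strictly positive.
#' @param luminal_area Luminal area in mm^2; must satisfy
#'   `0 <= luminal_area <= total_area`.
#' @return An object of class `area_set`: a list with fields `total_area`,
#'   `luminal_area` and `photoreceptor_area` (all mm^2).
#' @examples
#' compute_pra(0.30, 0.15)
#' @export
compute_pra <- function(total_area, luminal_area) {
  if (!is.numeric(total_area) || length(total_area) != 1L || is.na(total_area) ||
      !is.numeric(luminal_area) || length(luminal_area) != 1L || is.na(luminal_area))
    stop("total_area and luminal_area must be single non-missing numbers")
  if (total_area <= 0)
    stop("non-zero total area required: the index is defined only for TA > 0")
  if (luminal_area < 0)
    stop("luminal area must be non-negative")
  if (luminal_area > total_area)
    stop("inconsistent segmentation: luminal area (", luminal_area,
         ") exceeds total area (", total_area, ")")
  structure(
    list(total_area = as.numeric(total_area),
         luminal_area = as.numeric(luminal_area),
         photoreceptor_area = as.numeric(total_area) - as.numeric(luminal_area)),
    class = "area_set")
}

#' @export
print.area_set <- function(x, ...) {
  cat(sprintf("En-face hole areas (mm^2): TA %.4f | LA %.4f | PRA %.4f\n",
              x$total_area, x$luminal_area, x$photoreceptor_area))
  invisible(x)
}

is_area_set <- function(x) inherits(x, "area_set")

#' Macular hole size class by minimum aperture diameter
#'
#' Full-thickness macular holes are classed by the minimum hole diameter on
#' the B-scan: small (<= 250 um), medium (> 250 and <= 400 um) or large
#' (> 400 um).  Boundary values are assigned to the smaller class.
#'
#' @param minimum_diameter Minimum hole diameter(s) in micrometres; strictly
#'   positive.  Vectorised; `NA` propagates.
#' @return A character vector with levels `"small"`, `"medium"`, `"large"`.
#' @examples
#' classify_ivts(c(226, 300, 492))
#' @export
classify_ivts <- function(minimum_diameter) {
  if (!is.numeric(minimum_diameter))
    stop("minimum_diameter must be numeric")
  if (any(minimum_diameter <= 0, na.rm = TRUE))
    stop("minimum_diameter must be strictly positive (micrometres)")
  out <- rep(NA_character_, length(minimum_diameter))
  ok <- !is.na(minimum_diameter)
  out[ok] <- ifelse(minimum_diameter[ok] <= 250, "small",
                    ifelse(minimum_diameter[ok] <= 400, "medium", "large"))
  out
}

#' Absolute follow-up changes for BCVA, EZ and ELM
#'
#' Adds the absolute change from baseline (T0) to follow-up (T1),
#' `|delta| = |T1 - T0|`, for best-corrected visual acuity (logMAR) and the
#' ellipsoid-zone / external-limiting-membrane defect lengths (um).  A
#' missing T0 or T1 yields a missing delta; nothing is imputed.
#'
#' @param cohort A cohort data frame with (any of) the paired columns
#'   `bcva_t0_logmar`/`bcva_t1_logmar`, `ez_t0_um`/`ez_t1_um`,
#'   `elm_t0_um`/`elm_t1_um`.
#' @return `cohort` with columns `abs_delta_bcva_logmar`, `abs_delta_ez_um`,
#'   `abs_delta_elm_um` added for each pair present.
#' @export
compute_deltas <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  pairs <- list(
    abs_delta_bcva_logmar = c("bcva_t0_logmar", "bcva_t1_logmar"),
    abs_delta_ez_um       = c("ez_t0_um", "ez_t1_um"),
    abs_delta_elm_um      = c("elm_t0_um", "elm_t1_um"))
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (all(p %in% names(cohort)))
      cohort[[nm]] <- abs(cohort[[p[2L]]] - cohort[[p[1L]]])
  }
  cohort
}
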