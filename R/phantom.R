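# named RNG streams derived from one top-level seed; each stage draws from
# its own stream so stages can be re-run in isolation
stream_seed <- function(seed, stream) {
  streams <- c(cohort = 1L, grader = 2L, phantom = 3L, speckle = 4L,
               geometry = 5L, stats = 6L)
  idx <- streams[[stream]]
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * idx
}

#' Specification of a synthetic en-face macular-hole phantom
#'
#' Describes a dark elliptical lumen surrounded by a bright photoreceptor
#' ring on a mid-gray background, emulating the appearance of a
#' full-thickness macular hole on an en-face slab: densely packed surviving
#' photoreceptors form a hyperreflective rim around the dark lumen.  The
#' outer ring boundary is the lumen ellipse grown by `ring_width_mm` in
#' each semi-axis, optionally perturbed radially by a sinusoid ("bumpy
#' border").  Ground-truth areas are analytic for smooth boundaries and
#' polygon-integrated for bumpy ones.
#'
#' @param lumen_a_mm,lumen_b_mm Lumen ellipse semi-axes in mm (> 0).
#' @param center_dx_mm,center_dy_mm Hole center offset from the field
#'   center, mm.
#' @param ring_width_mm Added to both semi-axes for the outer boundary (> 0).
#' @param bump_amplitude_mm Radial perturbation amplitude of the outer
#'   boundary, mm (0 = smooth).
#' @param bump_lobes Number of sinusoidal lobes.
#' @param bump_phase Phase of the perturbation, radians.
#' @param bg_intensity,ring_intensity,lumen_intensity Intensity levels in
#'   \[0, 1\].
#' @param speckle_sigma Multiplicative speckle noise sd (0 = noise-free).
#' @param pixel_size_um Pixel pitch in micrometres (default 10, giving
#'   300 x 300 px over the 3 mm field).
#' @param field_mm Physical field width/height in mm (square, default 3).
#' @param seed Integer seed for the speckle stream.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(lumen_a_mm = 0.20, lumen_b_mm = lumen_a_mm,
                         center_dx_mm = 0, center_dy_mm = 0,
                         ring_width_mm = 0.10, bump_amplitude_mm = 0,
                         bump_lobes = 8, bump_phase = 0,
                         bg_intensity = 0.40, ring_intensity = 0.90,
                         lumen_intensity = 0.05, speckle_sigma = 0,
                         pixel_size_um = 10, field_mm = 3, seed = 1) {
  if (lumen_a_mm <= 0 || lumen_b_mm <= 0) stop("lumen semi-axes must be > 0")
  if (ring_width_mm <= 0) stop("ring width must be > 0")
  if (bump_amplitude_mm < 0) stop("bump amplitude must be >= 0")
  spec <- structure(as.list(environment()), class = "phantom_spec")
  rmax <- max(lumen_a_mm, lumen_b_mm) + ring_width_mm + bump_amplitude_mm
  if (rmax + max(abs(center_dx_mm), abs(center_dy_mm)) >= field_mm / 2)
    stop("phantom spec error: geometry exceeds the ", field_mm, " mm field")
  if (bump_amplitude_mm >= ring_width_mm)
    stop("phantom spec error: bump amplitude must stay below the ring width")
  spec
}

# polar radius of the outer boundary at angle theta
outer_radius <- function(spec, theta) {
  a <- spec$lumen_a_mm + spec$ring_width_mm
  b <- spec$lumen_b_mm + spec$ring_width_mm
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  r + spec$bump_amplitude_mm * cos(spec$bump_lobes * theta + spec$bump_phase)
}

# shoelace area of the star-shaped outer boundary sampled at n vertices
outer_polygon_area <- function(spec, n_vertices = 4096L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- outer_radius(spec, th)
  x <- r * cos(th); y <- r * sin(th)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Render a phantom and return its exact ground truth
#'
#' Rasterizes the phantom at pixel centers, applies multiplicative speckle
#' when requested (deterministic per seed), and emits the ground-truth area
#' triple: luminal area analytically (`pi * a * b`), total area analytically
#' for smooth boundaries or by 4096-vertex polygon quadrature for bumpy
#' ones.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (an [enface_image]), `truth` (an
#'   [`area_set`][compute_pra]) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(lumen_a_mm = 0.2, ring_width_mm = 0.1))
#' ph$truth  # LA = pi * 0.04, TA = pi * 0.09
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  px_mm <- spec$pixel_size_um / 1000
  n <- round(spec$field_mm / px_mm)
  coord <- (seq_len(n) - 0.5) * px_mm - spec$field_mm / 2
  x <- matrix(coord, n, n, byrow = TRUE) - spec$center_dx_mm
  y <- matrix(coord, n, n) - spec$center_dy_mm
  rr <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  inside_outer <- rr <= outer_radius(spec, th)
  inside_lumen <- (x / spec$lumen_a_mm)^2 + (y / spec$lumen_b_mm)^2 <= 1
  img <- matrix(spec$bg_intensity, n, n)
  img[inside_outer] <- spec$ring_intensity
  img[inside_lumen] <- spec$lumen_intensity
  if (spec$speckle_sigma > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(stream_seed(spec$seed, "speckle"))
    img <- img * (1 + spec$speckle_sigma * stats::rnorm(length(img)))
    img <- pmin(pmax(img, 0), 1)
    img <- matrix(img, n, n)
  }
  la <- pi * spec$lumen_a_mm * spec$lumen_b_mm
  ta <- if (spec$bump_amplitude_mm == 0) {
    pi * (spec$lumen_a_mm + spec$ring_width_mm) *
      (spec$lumen_b_mm + spec$ring_width_mm)
  } else {
    outer_polygon_area(spec)
  }
  list(image = enface_image(img, spec$field_mm, spec$field_mm),
       truth = compute_pra(ta, la), spec = spec)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Render phantom images for every eye of a tabular cohort
#'
#' For each eye, solves a lumen ellipse and ring width whose analytic areas
#' reproduce the tabulated `la_mm2` and `ta_mm2` (ellipse eccentricity is
#' sampled per eye; the ring width solves
#' `pi (a + w)(b + w) = TA`), then renders the phantom.  Eyes whose area
#' pair is infeasible for the geometry model are flagged with a warning and
#' skipped.
#'
#' @param cohort Cohort data frame with `la_mm2` and `ta_mm2` (and
#'   optionally `eye_id`).
#' @param pixel_size_um Pixel pitch, micrometres.
#' @param speckle_sigma Speckle noise sd applied to every rendering.
#' @param seed Top-level seed (expanded into geometry and speckle streams).
#' @param axis_ratio_range Range of the sampled lumen axis ratio a/b.
#' @return List with `phantoms` (named list of [generate_phantom] results)
#'   and `truth` (data frame: eye_id, la/ta/pra ground truth, rendered flag).
#' @export
render_cohort_phantoms <- function(cohort, pixel_size_um = 10,
                                   speckle_sigma = 0, seed = 1,
                                   axis_ratio_range = c(1, 1.4)) {
  if (!is.data.frame(cohort) || is.null(cohort$la_mm2) || is.null(cohort$ta_mm2))
    stop("cohort needs la_mm2 and ta_mm2 columns")
  ids <- if (!is.null(cohort$eye_id)) as.character(cohort$eye_id)
         else sprintf("eye%03d", seq_len(nrow(cohort)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(stream_seed(seed, "geometry"))
  q <- stats::runif(nrow(cohort), axis_ratio_range[1], axis_ratio_range[2])
  phantoms <- list()
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    la <- cohort$la_mm2[i]; ta <- cohort$ta_mm2[i]
    rendered <- FALSE
    if (!is.na(la) && !is.na(ta) && la > 0 && ta > la) {
      a <- sqrt(la * q[i] / pi); b <- a / q[i]
      disc <- (a + b)^2 - 4 * (a * b - ta / pi)
      w <- (-(a + b) + sqrt(disc)) / 2
      ok <- w > 0.005 &&
        max(a, b) + w < 3 / 2 * 0.95  # must fit the 3 mm field
      if (ok) {
        sp <- phantom_spec(lumen_a_mm = a, lumen_b_mm = b, ring_width_mm = w,
                           speckle_sigma = speckle_sigma,
                           pixel_size_um = pixel_size_um,
                           seed = stream_seed(seed, "phantom") + i)
        phantoms[[ids[i]]] <- generate_phantom(sp)
        rendered <- TRUE
        tr <- phantoms[[ids[i]]]$truth
        rows[[i]] <- data.frame(eye_id = ids[i], la_true = tr$luminal_area,
                                ta_true = tr$total_area,
                                pra_true = tr$photoreceptor_area,
                                rendered = TRUE)
      }
    }
    if (!rendered) {
      warning("eye ", ids[i], ": area pair (LA ", la, ", TA ", ta,
              ") infeasible for the phantom geometry; skipped")
      rows[[i]] <- data.frame(eye_id = ids[i], la_true = NA_real_,
                              ta_true = NA_real_, pra_true = NA_real_,
                              rendered = FALSE)
    }
  }
  list(phantoms = phantoms, truth = do.call(rbind, rows))
}
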