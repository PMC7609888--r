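#' Constants of the closed-form threshold expressions
#'
#' The seven fitted dimensionless constants of the two-branch threshold
#' formula: the small-tumor power law
#' \code{threshold = k1 * (D/FWHM)^(-k2)} for D < 2 FWHM, and the
#' large-tumor form
#' \code{threshold = c1 * exp(-c2 * PS/FWHM) *
#' (1 - exp(-c3 * (D/FWHM) * exp(c4 * PS/FWHM))) + c5 * PS/FWHM}
#' for D >= 2 FWHM. Defaults are the published fitted values.
#'
#' @param k1,k2 small-tumor branch constants.
#' @param c1,c2,c3,c4,c5 large-tumor branch constants.
#' @return An object of class \code{formula_constants}.
#' @export
formula_constants <- function(k1 = 46.57, k2 = 0.63,
                              c1 = 50.568, c2 = 2.4758, c3 = 0.4617,
                              c4 = 1.658, c5 = 34.392) {
  vals <- c(k1 = k1, k2 = k2, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  if (any(!is.finite(vals)))
    stop("all formula constants must be finite")
  if (any(vals <= 0))
    warning("non-positive formula constants: outside the published regime")
  structure(as.list(vals), class = "formula_constants")
}

#' @export
print.formula_constants <- function(x, ...) {
  cat("formula_constants:\n")
  cat(sprintf("  D < 2 FWHM : k1 = %g, k2 = %g\n", x$k1, x$k2))
  cat(sprintf("  D >= 2 FWHM: c1 = %g, c2 = %g, c3 = %g, c4 = %g, c5 = %g\n",
              x$c1, x$c2, x$c3, x$c4, x$c5))
  invisible(x)
}

#' Validity domain of the threshold formula
#'
#' The parameter ranges over which the constants were fitted: sphere
#' diameter 2-100 mm, system FWHM 2-9 mm, pixel size FWHM/20 to FWHM/2.
#'
#' @return A list with \code{d_range_mm}, \code{fwhm_range_mm},
#'   \code{ps_over_fwhm_range}.
#' @export
formula_domain <- function() {
  list(d_range_mm = c(2, 100), fwhm_range_mm = c(2, 9),
       ps_over_fwhm_range = c(1 / 20, 1 / 2))
}

#' Scalar effective pixel size of an anisotropic voxel
#'
#' The cube root of the voxel volume (geometric mean of the three
#' spacings): the isotropic pixel size with the same voxel volume, used
#' wherever the threshold formula needs a single PS for an anisotropic
#' reconstruction grid.
#'
#' @param spacing_mm length-3 (or scalar) voxel spacing in mm.
#' @return Effective pixel size in mm.
#' @examples
#' effective_pixel_size(c(3.65, 3.65, 3.27))  # 3.5187
#' @export
effective_pixel_size <- function(spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("all spacings must be positive")
  prod(spacing_mm)^(1 / 3)
}

#' Closed-form volume-matching threshold
#'
#' Evaluates the two-branch threshold formula. For D < 2 FWHM the
#' small-tumor power law applies and is independent of pixel size; at
#' and above D = 2 FWHM the large-tumor form applies (the two branches
#' agree to about 1 point at the joint). Inputs outside the fitted
#' domain (see \code{\link{formula_domain}}) warn and extrapolate;
#' results above 100\% (possible for D/FWHM below about 0.3) are
#' clamped to 100 with a warning.
#'
#' @param d_mm tumor diameter in mm; vectorized.
#' @param fwhm_mm system FWHM in mm.
#' @param ps_mm reconstruction pixel size in mm (scalar; use
#'   \code{\link{effective_pixel_size}} for anisotropic voxels).
#' @param constants a \code{\link{formula_constants}} object.
#' @return Relative threshold(s) in percent.
#' @examples
#' formula_threshold(10, 8, 3.5187)  # 40.46
#' @export
formula_threshold <- function(d_mm, fwhm_mm, ps_mm,
                              constants = formula_constants()) {
  stopifnot(inherits(constants, "formula_constants"))
  if (any(d_mm <= 0) || fwhm_mm <= 0 || ps_mm <= 0)
    stop("'d_mm', 'fwhm_mm' and 'ps_mm' must be positive")
  dom <- formula_domain()
  p <- ps_mm / fwhm_mm
  if (any(d_mm < dom$d_range_mm[1]) || any(d_mm > dom$d_range_mm[2]) ||
      fwhm_mm < dom$fwhm_range_mm[1] || fwhm_mm > dom$fwhm_range_mm[2] ||
      p < dom$ps_over_fwhm_range[1] - 1e-9 ||
      p > dom$ps_over_fwhm_range[2] + 1e-9)
    warning("inputs outside the fitted domain; extrapolating")
  x <- d_mm / fwhm_mm
  out <- ifelse(
    x < 2,
    constants$k1 * x^(-constants$k2),
    constants$c1 * exp(-constants$c2 * p) *
      (1 - exp(-constants$c3 * x * exp(constants$c4 * p))) +
      constants$c5 * p
  )
  if (any(out > 100)) {
    warning("threshold above 100% (very small D/FWHM); clamped to 100")
    out <- pmin(out, 100)
  }
  out
}

#' Absolute SUV cutoff from the closed-form threshold
#'
#' Composes \code{\link{formula_threshold}} with
#' \code{\link{absolute_from_relative}}: the SUV at the target boundary
#' for a lesion of diameter D imaged at the given FWHM and pixel size.
#'
#' @inheritParams formula_threshold
#' @param suvmax maximum SUV of the lesion image.
#' @param suvbg background SUV.
#' @return Absolute SUV cutoff(s).
#' @export
formula_absolute_threshold <- function(d_mm, fwhm_mm, ps_mm, suvmax, suvbg,
                                       constants = formula_constants()) {
  t <- formula_threshold(d_mm, fwhm_mm, ps_mm, constants)
  absolute_from_relative(t, suvmax, suvbg)
}
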