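#' Radial profile of a uniform sphere blurred by a Gaussian
#'
#' Closed form for the convolution of the indicator of a sphere of
#' radius R with a normalized isotropic 3-D Gaussian of standard
#' deviation sigma, evaluated at distance d from the sphere center:
#' \deqn{A(d) = \tfrac12\left[\mathrm{erf}\tfrac{R+d}{\sigma\sqrt2} +
#'   \mathrm{erf}\tfrac{R-d}{\sigma\sqrt2}\right] -
#'   \frac{\sigma}{d\sqrt{2\pi}}\left[e^{-(R-d)^2/2\sigma^2} -
#'   e^{-(R+d)^2/2\sigma^2}\right]}
#' with the limit
#' \eqn{A(0) = \mathrm{erf}(R/\sigma\sqrt2) -
#' \sqrt{2/\pi}\,(R/\sigma)\,e^{-R^2/2\sigma^2}} used for
#' \eqn{d < 10^{-6}\sigma}. A is 1 inside a sphere much larger than
#' sigma, decays monotonically with d, and tends to 0 far away. It
#' serves as the continuous-limit (infinitesimal-pixel, noise-free)
#' oracle for the numeric simulator.
#'
#' @param d distance(s) from the sphere center, mm; >= 0.
#' @param radius_mm sphere radius R in mm.
#' @param sigma_mm Gaussian standard deviation in mm
#'   (\eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}).
#' @return Normalized intensity in [0, 1] (contrast 1 sphere on zero
#'   background), vectorized over \code{d}.
#' @export
sphere_blur_profile <- function(d, radius_mm, sigma_mm) {
  if (radius_mm <= 0 || sigma_mm <= 0)
    stop("'radius_mm' and 'sigma_mm' must be positive")
  if (any(d < 0)) stop("'d' must be non-negative")
  R <- radius_mm
  s <- sigma_mm
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  small <- d < 1e-6 * s
  out <- numeric(length(d))
  if (any(small))
    out[small] <- erf(R / (s * sqrt(2))) -
      sqrt(2 / pi) * (R / s) * exp(-R^2 / (2 * s^2))
  if (any(!small)) {
    dd <- d[!small]
    out[!small] <- 0.5 * (erf((R + dd) / (s * sqrt(2))) +
                            erf((R - dd) / (s * sqrt(2)))) -
      (s / (dd * sqrt(2 * pi))) *
      (exp(-(R - dd)^2 / (2 * s^2)) - exp(-(R + dd)^2 / (2 * s^2)))
  }
  out
}

#' Continuous-limit volume-matching threshold
#'
#' In the noise-free, infinitesimal-pixel limit, the blurred image of a
#' sphere is radially non-increasing, so the iso-contour through the
#' true surface (d = R) encloses exactly the true volume. The
#' volume-matching relative threshold is therefore
#' \code{100 * A(R) / A(0)}, a function of D/FWHM alone (scale-free in
#' FWHM).
#'
#' @param d_over_fwhm tumor diameter divided by system FWHM; > 0.
#' @param fwhm_mm FWHM used internally; the result does not depend on
#'   it (any positive value gives the same threshold).
#' @return Relative threshold in percent, vectorized over
#'   \code{d_over_fwhm}.
#' @export
continuous_threshold <- function(d_over_fwhm, fwhm_mm = 1) {
  if (any(d_over_fwhm <= 0)) stop("'d_over_fwhm' must be positive")
  sigma <- fwhm_mm * FWHM_TO_SIGMA
  vapply(d_over_fwhm, function(x) {
    R <- x * fwhm_mm / 2
    100 * sphere_blur_profile(R, R, sigma) /
      sphere_blur_profile(0, R, sigma)
  }, numeric(1))
}
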