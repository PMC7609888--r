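#' Convert a relative threshold to an absolute SUV cutoff
#'
#' The relative threshold expresses the cutoff as a percentage of the
#' background-subtracted peak: the absolute cutoff is
#' \code{(suvmax - suvbg) * percent/100 + suvbg}. Subtracting the
#' background here is what makes the volume-matching relative threshold
#' independent of background level.
#'
#' @param percent relative threshold in percent.
#' @param suvmax maximum SUV of the lesion image.
#' @param suvbg background SUV; must satisfy \code{suvmax > suvbg >= 0}.
#' @return Absolute SUV cutoff (vectorized over \code{percent}).
#' @export
absolute_from_relative <- function(percent, suvmax, suvbg) {
  if (suvbg < 0) stop("'suvbg' must be non-negative")
  if (suvmax <= suvbg) stop("'suvmax' must exceed 'suvbg'")
  (suvmax - suvbg) * percent / 100 + suvbg
}

#' Convert an absolute SUV cutoff to a relative threshold
#'
#' Exact inverse of \code{\link{absolute_from_relative}}:
#' \code{100 * (absolute - suvbg) / (suvmax - suvbg)}.
#'
#' @param absolute absolute SUV cutoff; must lie in \code{[suvbg, suvmax]}.
#' @param suvmax maximum SUV of the lesion image.
#' @param suvbg background SUV.
#' @return Relative threshold in percent (vectorized over \code{absolute}).
#' @export
relative_from_absolute <- function(absolute, suvmax, suvbg) {
  if (suvmax <= suvbg) stop("'suvmax' must exceed 'suvbg'")
  if (any(absolute < suvbg - 1e-12) || any(absolute > suvmax + 1e-12))
    stop("'absolute' must lie between 'suvbg' and 'suvmax'")
  100 * (absolute - suvbg) / (suvmax - suvbg)
}

#' Metabolic tumor volume above an absolute cutoff
#'
#' Whole-voxel counting: the number of voxels with value >= cutoff times
#' the voxel volume. The comparison is \code{>=}, so a cutoff equal to a
#' uniform image value selects the whole field of view.
#'
#' @param image an \code{image_volume}.
#' @param absolute absolute SUV cutoff (scalar or vector).
#' @return Volume(s) in mm^3, one per cutoff.
#' @export
measure_mtv <- function(image, absolute) {
  stopifnot(inherits(image, "image_volume"))
  sv <- sort(as.vector(image$values))
  n <- length(sv)
  # count of values >= cutoff; left-open intervals count values < cutoff
  n_ge <- n - findInterval(absolute, sv, left.open = TRUE)
  n_ge * voxel_volume(image)
}

#' Sweep relative thresholds against the true volume
#'
#' For each relative threshold percentage, measures the metabolic tumor
#' volume (MTV) enclosed by the corresponding absolute cutoff and its
#' percent error against the true volume,
#' \code{(MTV - true) / true * 100}. The default sweep is 11\% to 90\%
#' in 1-point steps (80 values); MTV is non-increasing in the threshold.
#'
#' @param image an \code{image_volume}.
#' @param true_volume_mm3 true object volume in mm^3.
#' @param suvbg background SUV.
#' @param percents strictly increasing threshold percentages.
#' @return A data frame with columns \code{percent}, \code{mtv_mm3},
#'   \code{percent_error}.
#' @export
threshold_sweep <- function(image, true_volume_mm3, suvbg, percents = 11:90) {
  stopifnot(inherits(image, "image_volume"))
  if (length(percents) < 1L || any(diff(percents) <= 0))
    stop("'percents' must be strictly increasing")
  cutoffs <- absolute_from_relative(percents, suv_max(image), suvbg)
  mtv <- measure_mtv(image, cutoffs)
  data.frame(
    percent = as.numeric(percents),
    mtv_mm3 = mtv,
    percent_error = (mtv - true_volume_mm3) / true_volume_mm3 * 100
  )
}

#' Solve for the volume-matching relative threshold
#'
#' Finds the relative threshold at which the delineated MTV equals the
#' true volume: a 1-point-step sweep over \code{percents} followed by
#' linear interpolation of MTV versus percent across the sign change of
#' the volume error. If the error crosses zero more than once (possible
#' at coarse pixel sizes, where MTV is a step function), the first
#' crossing from low percent is taken with a warning. The result is
#' reported to 0.01 point.
#'
#' @param image an \code{image_volume}.
#' @param true_volume_mm3 true object volume in mm^3.
#' @param suvbg background SUV.
#' @param percents strictly increasing sweep percentages (default 11:90).
#' @return An object of class \code{threshold_result} with elements
#'   \code{relative_percent}, \code{absolute_suv},
#'   \code{matched_volume_mm3}, \code{suvmax}, \code{suvbg}, and the
#'   \code{sweep} data frame.
#' @export
volume_matching_threshold <- function(image, true_volume_mm3, suvbg,
                                      percents = 11:90) {
  sw <- threshold_sweep(image, true_volume_mm3, suvbg, percents)
  err <- sw$percent_error
  m <- nrow(sw)
  if (err[1] < 0 || err[m] > 0)
    stop(sprintf(
      "threshold outside sweep range [%g, %g]: volume error spans [%.3g, %.3g]%%",
      sw$percent[1], sw$percent[m], err[m], err[1]))
  cross <- which(err[-m] >= 0 & err[-1] < 0)
  if (length(cross) == 0L) {
    # error hits zero exactly at the last sample
    p <- sw$percent[max(which(err >= 0))]
  } else {
    if (length(cross) > 1L)
      warning("multiple volume-error crossings; taking the first from low percent")
    i <- cross[1]
    if (err[i] == 0) {
      p <- sw$percent[i]
    } else {
      p <- sw$percent[i] + err[i] / (err[i] - err[i + 1]) *
        (sw$percent[i + 1] - sw$percent[i])
    }
  }
  p <- round(p, 2)
  smax <- suv_max(image)
  abs_thr <- absolute_from_relative(p, smax, suvbg)
  structure(
    list(relative_percent = p,
         absolute_suv = abs_thr,
         matched_volume_mm3 = as.numeric(measure_mtv(image, abs_thr)),
         suvmax = smax, suvbg = suvbg, sweep = sw),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result: %.2f%% relative (absolute %.4g SUV), MTV %.4g cm^3\n",
    x$relative_percent, x$absolute_suv, x$matched_volume_mm3 / 1000))
  cat(sprintf("  SUVmax %.4g, SUVbg %.4g\n", x$suvmax, x$suvbg))
  invisible(x)
}

#' Delineate a lesion at a given relative threshold
#'
#' Applies a relative threshold to a PET volume: SUVmax is taken within
#' a spherical region of interest, the absolute cutoff is computed from
#' the relative threshold and background, and the delineated target is
#' the 6-connected component of supra-threshold voxels containing the
#' ROI maximum. Restricting to one connected component keeps nearby
#' lesions or hot background out of the target.
#'
#' @param image an \code{image_volume}.
#' @param percent relative threshold in percent.
#' @param suvbg background SUV.
#' @param roi_center_mm length-3 physical center of the ROI in mm.
#' @param roi_radius_mm ROI radius in mm; must contain the lesion peak.
#' @return A list with \code{mask} (an \code{image_volume} of 0/1),
#'   \code{volume_mm3}, \code{absolute_suv} and \code{suvmax}.
#' @export
delineate <- function(image, percent, suvbg, roi_center_mm, roi_radius_mm) {
  stopifnot(inherits(image, "image_volume"))
  roi_center_mm <- rep_len(as.numeric(roi_center_mm), 3L)
  if (roi_radius_mm <= 0) stop("'roi_radius_mm' must be positive")
  d <- dim(image$values)
  ax <- lapply(1:3, function(a) axis_coords(image, a) - roi_center_mm[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  roi <- r2 <= roi_radius_mm^2
  if (!any(roi)) stop("ROI is empty or outside the image")
  vals <- image$values
  smax <- max(vals[roi])
  cutoff <- absolute_from_relative(percent, smax, suvbg)
  seed <- which(roi & vals == smax)[1]
  cand <- vals >= cutoff
  mask <- flood_fill6(cand, seed)
  out_mask <- image_volume(array(as.numeric(mask), dim = d),
                           image$spacing_mm, image$origin_mm, image$meta)
  list(mask = out_mask,
       volume_mm3 = sum(mask) * voxel_volume(image),
       absolute_suv = cutoff, suvmax = smax)
}

# 6-connected component of TRUE voxels in `cand` containing linear index
# `seed`, by breadth-first frontier expansion.
flood_fill6 <- function(cand, seed) {
  d <- dim(cand)
  lab <- array(FALSE, dim = d)
  if (!cand[seed]) return(lab)
  lab[seed] <- TRUE
  frontier <- arrayInd(seed, d)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0L) {
    nb <- do.call(rbind, lapply(seq_len(6), function(s)
      sweep(frontier, 2L, shifts[s, ], "+")))
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
      nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    keep <- cand[lin] & !lab[lin]
    lin <- unique(lin[keep])
    if (!length(lin)) break
    lab[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  lab
}
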