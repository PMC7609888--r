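#' 3-D image volume of SUV values
#'
#' Lightweight container for a 3-D scalar field of standardized uptake
#' values (SUV) on a regular, axis-aligned grid. The physical coordinate
#' of the center of voxel \code{(i, j, k)} (1-based R indices) is
#' \code{origin_mm + (c(i, j, k) - 0.5) * spacing_mm}, i.e. \code{origin_mm}
#' is the outer corner of the first voxel.
#'
#' @param values 3-D numeric array of SUV values; all finite.
#' @param spacing_mm voxel spacing in mm; scalar or length-3 vector.
#' @param origin_mm physical coordinate (mm) of the corner of the first
#'   voxel. Defaults to \code{-dim(values) * spacing_mm / 2}, which centers
#'   the grid on the physical origin.
#' @param meta named list of free-form metadata (e.g. the simulation
#'   parameters that produced the volume); carried along by operations.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!all(is.finite(values)))
    stop("image values must be finite")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("all voxel spacings must be positive and finite")
  if (is.null(origin_mm))
    origin_mm <- -dim(values) * spacing_mm / 2
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = origin_mm, meta = meta),
    class = "image_volume"
  )
}

#' Volume of a single voxel
#'
#' @param image an \code{image_volume}.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  prod(image$spacing_mm)
}

#' Maximum SUV of an image
#'
#' The maximum voxel value of the image (SUVmax). Note this is a property
#' of the blurred, pixelated image, not the true uptake of the object.
#'
#' @param image an \code{image_volume}.
#' @return Maximum voxel value.
#' @export
suv_max <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  max(image$values)
}

# Physical center coordinates of the voxels along one axis.
axis_coords <- function(image, axis) {
  n <- dim(image$values)[axis]
  image$origin_mm[axis] + (seq_len(n) - 0.5) * image$spacing_mm[axis]
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 6), collapse = " x ")))
  cat(sprintf("  value range [%.4g, %.4g] SUV\n",
              min(x$values), max(x$values)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, function(v)
      paste(signif(unlist(v), 5), collapse = ","))),
      sep = "=", collapse = ", "), "\n")
  invisible(x)
}
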