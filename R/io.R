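#' Write an image volume as NIfTI
#'
#' Values are stored as 32-bit float (or 8-bit unsigned integer for
#' binary masks), with the voxel spacing in the header and an
#' axis-aligned affine placing the center of the first voxel at
#' \code{origin_mm + spacing_mm / 2}.
#'
#' @param image an \code{image_volume}.
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @param mask write as uint8 (for binary masks) instead of float32.
#' @return The path, invisibly.
#' @export
write_volume <- function(image, path, mask = FALSE) {
  stopifnot(inherits(image, "image_volume"))
  nif <- RNifti::asNifti(image$values)
  aff <- diag(c(image$spacing_mm, 1))
  aff[1:3, 4] <- image$origin_mm + image$spacing_mm / 2
  RNifti::pixdim(nif) <- image$spacing_mm
  RNifti::sform(nif) <- structure(aff, code = 2L)
  RNifti::writeNifti(nif, path,
                     datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Read a NIfTI file as an image volume
#'
#' Only axis-aligned (non-oblique) volumes are supported: the rotation
#' part of the affine must be diagonal up to sign. The voxel spacing is
#' taken from the header; the origin from the affine translation.
#'
#' @param path path to a NIfTI-1 file.
#' @return An \code{image_volume}.
#' @export
read_volume <- function(path) {
  nif <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path))
  vals <- as.array(nif)
  if (length(dim(vals)) != 3L)
    stop("only 3-D volumes are supported")
  vals <- array(as.numeric(vals), dim = dim(vals))  # drop NIfTI attributes
  aff <- RNifti::xform(nif)
  rot <- aff[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4 * max(abs(diag(rot)))))
    stop("oblique affine: only axis-aligned volumes are supported")
  spacing <- abs(diag(rot))
  origin <- aff[1:3, 4] - spacing / 2
  image_volume(vals, spacing, origin)
}

#' Write / read a scene as JSON
#'
#' Round-trippable JSON serialization of a \code{sphere_scene}:
#' diameters, uptakes, centers, background and field of view.
#'
#' @param scene a \code{sphere_scene}.
#' @param path JSON file path.
#' @return \code{write_scene_json}: the path, invisibly;
#'   \code{read_scene_json}: a \code{sphere_scene}.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "sphere_scene"))
  obj <- list(
    spheres = lapply(scene$spheres, function(s)
      list(diameter_mm = s$diameter_mm, uptake_suv = s$uptake_suv,
           center_mm = s$center_mm)),
    background_suv = scene$background_suv,
    fov_mm = scene$fov_mm
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spheres <- lapply(seq_len(nrow(obj$spheres)), function(i)
    sphere_spec(obj$spheres$diameter_mm[i], obj$spheres$uptake_suv[i],
                unlist(obj$spheres$center_mm[i])))
  sphere_scene(spheres, background_suv = obj$background_suv,
               fov_mm = obj$fov_mm)
}

#' Shipped reference tables
#'
#' \code{reference_thresholds} returns the published reference curve of
#' simulated volume-matching thresholds versus D/FWHM;
#' \code{reference_phantom_validation} returns the published phantom
#' validation table (sphere diameters, true volumes, formula thresholds
#' and delineation results on a physical image-quality phantom). Both
#' are reference data for comparison, not correctness oracles for this
#' package's simulator.
#'
#' @return A data frame.
#' @export
reference_thresholds <- function() {
  utils::read.csv(system.file("extdata",
                              "reference_thresholds_simulated.csv",
                              package = "suvthresh", mustWork = TRUE))
}

#' @rdname reference_thresholds
#' @export
reference_phantom_validation <- function() {
  utils::read.csv(system.file("extdata",
                              "reference_phantom_validation.csv",
                              package = "suvthresh", mustWork = TRUE))
}

#' Generate the synthetic fixture set
#'
#' Writes, deterministically for a given seed: (a) the synthetic
#' image-quality phantom scene (four hot spheres, 8:1 contrast) as JSON
#' together with its simulated PET volume at FWHM 8 mm on a
#' 3.65 x 3.65 x 3.27 mm pixel grid and per-sphere ground-truth masks
#' (NIfTI); (b) a reduced simulation-grid CSV; (c) the shipped
#' reference tables as CSV; (d) a run-metadata JSON recording the seed
#' and parameters. The scene simulation is deterministic; the seed only
#' feeds downstream consumers that add noise (e.g. fit fixtures).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the metadata.
#' @param what subset of \code{c("tables", "scene", "grid", "volumes")}
#'   to generate.
#' @param grid_cfg \code{grid_config} for the reduced grid CSV.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(out_dir, seed = 1L,
                          what = c("tables", "scene", "grid", "volumes"),
                          grid_cfg = grid_config(
                            diameters_mm = c(6, 8, 12, 16),
                            fwhms_mm = 4,
                            ps_fractions = c(1 / 10, 1 / 2),
                            background_fractions = 0)) {
  what <- match.arg(what, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wrote <- function(f) files <<- c(files, f)

  if ("tables" %in% what) {
    for (fn in c("reference_thresholds_simulated.csv",
                 "reference_phantom_validation.csv")) {
      dest <- file.path(out_dir, fn)
      file.copy(system.file("extdata", fn, package = "suvthresh",
                            mustWork = TRUE), dest, overwrite = TRUE)
      wrote(dest)
    }
  }

  scene <- nema_iq_scene(contrast_ratio = 8, background_suv = 1)
  if ("scene" %in% what) {
    dest <- file.path(out_dir, "nema_iq_scene_synthetic.json")
    write_scene_json(scene, dest)
    wrote(dest)
    truth <- data.frame(
      diameter_mm = vapply(scene$spheres, `[[`, 0, "diameter_mm"),
      volume_cm3 = round(sphere_volume(
        vapply(scene$spheres, `[[`, 0, "diameter_mm")) / 1000, 4))
    dest <- file.path(out_dir, "nema_iq_truth_volumes.csv")
    utils::write.csv(truth, dest, row.names = FALSE, quote = FALSE)
    wrote(dest)
  }

  if ("grid" %in% what) {
    grid <- run_grid(grid_cfg, check_backgrounds = 0L)
    grid$threshold_percent <- round(grid$threshold_percent, 2)
    grid$suvmax <- round(grid$suvmax, 4)
    dest <- file.path(out_dir, "grid_thresholds_reduced.csv")
    utils::write.csv(
      grid[, c("d_mm", "fwhm_mm", "ps_mm", "bg_fraction",
               "threshold_percent", "suvmax")],
      dest, row.names = FALSE, quote = FALSE)
    wrote(dest)
  }

  if ("volumes" %in% what) {
    sys <- system_model(8, c(3.65, 3.65, 3.27))
    img <- simulate_pet(scene, sys)
    dest <- file.path(out_dir, "nema_iq_synthetic.nii.gz")
    write_volume(img, dest)
    wrote(dest)
    for (s in scene$spheres) {
      truth_mask <- voxelize_grid(
        sphere_scene(sphere_spec(s$diameter_mm, 1, s$center_mm),
                     background_suv = 0, fov_mm = scene$fov_mm),
        img$spacing_mm, dim(img$values), img$origin_mm)
      truth_mask$values <- array(as.numeric(truth_mask$values >= 0.5),
                                 dim = dim(truth_mask$values))
      dest <- file.path(out_dir,
                        sprintf("nema_iq_truth_mask_d%02d.nii.gz",
                                s$diameter_mm))
      write_volume(truth_mask, dest, mask = TRUE)
      wrote(dest)
    }
  }

  meta <- list(seed = seed, contrast_ratio = 8, background_suv = 1,
               fwhm_mm = 8, pixel_mm = c(3.65, 3.65, 3.27),
               package_version = as.character(
                 utils::packageVersion("suvthresh")))
  dest <- file.path(out_dir, "fixtures_metadata.json")
  jsonlite::write_json(meta, dest, auto_unbox = TRUE, pretty = TRUE)
  wrote(dest)
  invisible(files)
}
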