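#' Read a 3-D scalar volume from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` file into a [count_volume()]. The affine must be
#' axis-aligned (diagonal rotation part); the voxel spacing is taken from the
#' affine and the origin from its translation column, so that
#' `read_volume(write_volume(v))` reproduces `v` bit-exactly in values and
#' within 1e-6 mm in geometry.
#'
#' @param path file path to a NIfTI volume.
#' @param modality modality tag to attach, default `"SPECT"`.
#' @return A [count_volume()].
#' @export
read_volume <- function(path, modality = "SPECT") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3-D volume, got ", length(d), "-D input", call. = FALSE)
  }
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("missing or invalid voxel spacing metadata", call. = FALSE)
  }
  if (max(abs(rot - diag(spacing))) > 1e-4 * max(spacing)) {
    stop("only axis-aligned (RAS diagonal) volumes are supported", call. = FALSE)
  }
  grid <- voxel_grid(d, spacing, origin_mm = aff[1:3, 4])
  count_volume(array(as.vector(img), dim = d), grid, modality = modality)
}

#' Write a volume or mask to NIfTI
#'
#' @param volume a [count_volume()], [contour_mask()] or a bare 3-D array
#'   paired with `grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid required only when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, grid = NULL) {
  if (inherits(volume, "count_volume") || inherits(volume, "contour_mask") ||
      inherits(volume, "dose_map") || inherits(volume, "activity_map")) {
    grid <- volume$grid
    values <- volume$values
  } else {
    if (is.null(grid)) stop("`grid` is required for bare arrays", call. = FALSE)
    values <- as.array(volume)
  }
  storage.mode(values) <- "double"
  img <- RNifti::asNifti(values)
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @inheritParams read_volume
#' @param label region label to attach.
#' @return A [contour_mask()]. Values must be 0/1 on disk.
#' @export
read_mask <- function(path, label = "roi") {
  v <- read_volume(path)
  contour_mask(v$values != 0, v$grid, label = label)
}

#' Resample a mask onto another grid (nearest neighbour)
#'
#' Each target voxel centre is mapped to world coordinates and assigned the
#' value of the nearest source voxel; target voxels whose centre falls outside
#' the source extent are 0. Nearest-neighbour assignment keeps the mask binary;
#' resampling onto the mask's own grid is the identity.
#'
#' @param mask a [contour_mask()].
#' @param target_grid a [voxel_grid()] spatially overlapping the mask.
#' @return A [contour_mask()] on `target_grid`.
#' @export
resample_mask <- function(mask, target_grid) {
  stopifnot(inherits(mask, "contour_mask"), inherits(target_grid, "voxel_grid"))
  if (grids_aligned(mask$grid, target_grid)) {
    return(contour_mask(mask$values, target_grid, label = mask$label))
  }
  src <- mask$grid
  # nearest source index per target coordinate, per axis
  idx <- vector("list", 3L)
  inside <- vector("list", 3L)
  for (ax in 1:3) {
    w <- axis_coords(target_grid, ax)
    j <- round((w - src$origin_mm[ax]) / src$voxel_size_mm[ax]) + 1
    inside[[ax]] <- j >= 1 & j <= src$shape[ax]
    j[!inside[[ax]]] <- 1L
    idx[[ax]] <- as.integer(j)
  }
  if (!any(inside[[1]]) || !any(inside[[2]]) || !any(inside[[3]])) {
    stop("grids have disjoint physical extents", call. = FALSE)
  }
  out <- mask$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out[!inside[[1]], , ] <- FALSE
  out[, !inside[[2]], ] <- FALSE
  out[, , !inside[[3]]] <- FALSE
  contour_mask(out, target_grid, label = mask$label)
}
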