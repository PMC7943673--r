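#' Voxel grid geometry
#'
#' A `voxel_grid` describes the geometry shared by all volumes in a dosimetry
#' workflow: array shape, voxel spacing in mm, world origin (the centre of the
#' first voxel, in mm) and axis orientation codes. Voxel centres are at
#' `origin_mm + (index - 1) * voxel_size_mm` with 1-based indices along each
#' axis.
#'
#' @param shape integer vector of length 3, array dimensions (voxels).
#' @param voxel_size_mm positive numeric vector of length 3, spacing in mm.
#'   A scalar is recycled (cubic voxels).
#' @param origin_mm numeric vector of length 3, world position of the first
#'   voxel centre. Default centres the grid on the world origin.
#' @param orientation character axis codes, default `"RAS"`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(128, 128, 128), 4.42)
#' voxel_volume_ml(g)  # 0.0864 mL per voxel
#' @export
voxel_grid <- function(shape, voxel_size_mm, origin_mm = NULL,
                       orientation = "RAS") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive numbers", call. = FALSE)
  }
  if (is.null(origin_mm)) {
    # centre the physical extent on the world origin
    origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop("`origin_mm` must be three finite numbers", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         origin_mm = origin_mm, orientation = orientation),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm (", signif(voxel_volume_ml(x), 4), " mL/voxel)\n", sep = "")
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param grid a [voxel_grid()].
#' @return Scalar voxel volume in mL (`prod(voxel_size_mm) / 1000`).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$voxel_size_mm) / 1000
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff shape, spacing, origin and orientation all match,
#' geometric quantities within `tol` mm.
#'
#' @param a,b [voxel_grid()] objects.
#' @param tol alignment tolerance in mm (default 1e-6).
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol) &&
    identical(a$orientation, b$orientation)
}

# Abort unless two gridded objects share one grid; never broadcast silently.
assert_aligned <- function(a, b, what = "volumes") {
  ga <- if (inherits(a, "voxel_grid")) a else a$grid
  gb <- if (inherits(b, "voxel_grid")) b else b$grid
  if (!grids_aligned(ga, gb)) {
    stop("misaligned grids: ", what,
         " must share shape, spacing, origin and orientation", call. = FALSE)
  }
  invisible(TRUE)
}

# World coordinates (mm) of every voxel centre along one axis.
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}

#' Scintigraphic count volume
#'
#' Wraps a 3-D array of non-negative counts together with its [voxel_grid()]
#' and a modality tag (`"SPECT"`-like or `"PET"`-like).
#'
#' @param values 3-D numeric array of counts (finite, >= 0).
#' @param grid a [voxel_grid()] whose shape matches `dim(values)`.
#' @param modality `"SPECT"` or `"PET"` (free text allowed).
#' @return An object of class `count_volume`.
#' @export
count_volume <- function(values, grid, modality = "SPECT") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("count volume must be a 3-D array, got ",
         length(dim(values)), "-D", call. = FALSE)
  }
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("array dimensions do not match the grid shape", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  structure(list(values = values, grid = grid, modality = modality),
            class = "count_volume")
}

#' @export
print.count_volume <- function(x, ...) {
  cat("<count_volume> [", x$modality, "] total counts ",
      format(sum(x$values), big.mark = ","), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Binary contour mask
#'
#' A region of interest on a voxel grid: liver, tumor, normal liver, a
#' threshold-derived target, or the liver+lungs calibration region.
#'
#' @param values 3-D array coercible to logical (0/1).
#' @param grid a [voxel_grid()].
#' @param label free-text region label, e.g. `"liver"`, `"tumor"`.
#' @return An object of class `contour_mask`.
#' @export
contour_mask <- function(values, grid, label = "roi") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("mask must be a 3-D array", call. = FALSE)
  }
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("mask dimensions do not match the grid shape", call. = FALSE)
  }
  if (is.numeric(values) && !all(values %in% c(0, 1))) {
    stop("mask values must be binary (0/1)", call. = FALSE)
  }
  storage.mode(values) <- "logical"
  structure(list(values = values, grid = grid, label = label),
            class = "contour_mask")
}

#' @export
print.contour_mask <- function(x, ...) {
  cat("<contour_mask> '", x$label, "': ", sum(x$values), " voxels, ",
      signif(mask_volume_ml(x), 4), " mL\n", sep = "")
  invisible(x)
}

#' Mask volume in millilitres
#'
#' @param mask a [contour_mask()].
#' @return Volume in mL: number of set voxels times the voxel volume.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "contour_mask"))
  sum(mask$values) * voxel_volume_ml(mask$grid)
}
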