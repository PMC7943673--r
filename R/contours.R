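#' Percentage-of-maximum threshold contour
#'
#' Selects, within a volume of interest surrounding the liver, all voxels
#' whose uptake exceeds `fraction` of the maximum uptake in that VOI (strict
#' `>`; ties at exactly the threshold level are excluded). With the default
#' fraction of 0.10 this reproduces the 10%-threshold scintigraphic target
#' used to represent the arterially perfused liver area. The maximum is taken
#' within the VOI — not over the whole image — so extrahepatic hot spots
#' cannot distort the threshold; set `global_max = TRUE` for the image-wide
#' alternative. The result is invariant under any positive rescaling of the
#' counts.
#'
#' @param counts a [count_volume()].
#' @param voi a non-empty [contour_mask()] delimiting the search region.
#' @param fraction threshold as a fraction of the maximum, in (0, 1).
#' @param global_max take the maximum over the whole image instead of the VOI.
#' @return A [contour_mask()] labelled `"target_threshold"`. All-zero counts
#'   give an empty mask with a warning.
#' @export
threshold_contour <- function(counts, voi, fraction = 0.10,
                              global_max = FALSE) {
  stopifnot(inherits(counts, "count_volume"), inherits(voi, "contour_mask"))
  assert_aligned(counts, voi, "counts and VOI")
  if (!any(voi$values)) stop("VOI is empty", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  mx <- if (global_max) max(counts$values) else max(counts$values[voi$values])
  if (mx <= 0) {
    warning("all counts are zero in the VOI; returning an empty mask")
    return(contour_mask(array(FALSE, counts$grid$shape), counts$grid,
                        label = "target_threshold"))
  }
  contour_mask(voi$values & counts$values > fraction * mx, counts$grid,
               label = "target_threshold")
}

#' Healthy (normal) liver mask
#'
#' Set difference liver minus tumor. When the tumor lies inside the liver,
#' volumes satisfy V(liver) = V(tumor) + V(normal liver). Tumor voxels found
#' outside the liver are clipped with a warning by default, or rejected.
#'
#' @param liver,tumor [contour_mask()] objects on one grid.
#' @param outside one of `"clip"` (default) or `"error"`, the policy for
#'   tumor voxels outside the liver.
#' @return A [contour_mask()] labelled `"normal_liver"`.
#' @export
normal_liver <- function(liver, tumor, outside = c("clip", "error")) {
  stopifnot(inherits(liver, "contour_mask"), inherits(tumor, "contour_mask"))
  outside <- match.arg(outside)
  assert_aligned(liver, tumor, "liver and tumor masks")
  stray <- sum(tumor$values & !liver$values)
  if (stray > 0) {
    if (outside == "error") {
      stop(stray, " tumor voxels lie outside the liver", call. = FALSE)
    }
    warning(stray, " tumor voxels outside the liver were clipped")
  }
  contour_mask(liver$values & !tumor$values, liver$grid,
               label = "normal_liver")
}

#' Bundle the contours of one patient / timepoint
#'
#' Groups liver, tumor, normal-liver and (optionally) the threshold target
#' mask under a provenance tag (`"C_MRI"`, `"C_SPECT"` or `"C_PET"`), and
#' asserts the partition invariants: tumor inside liver, normal liver equal
#' to liver minus tumor, tumor and normal liver disjoint.
#'
#' @param liver,tumor [contour_mask()] objects on one grid.
#' @param target_threshold optional threshold-target [contour_mask()].
#' @param provenance `"C_MRI"`, `"C_SPECT"` or `"C_PET"`.
#' @return A list of class `contour_set` with elements `liver`, `tumor`,
#'   `normal_liver`, `target_threshold`, `provenance`.
#' @export
contour_set <- function(liver, tumor, target_threshold = NULL,
                        provenance = c("C_MRI", "C_SPECT", "C_PET")) {
  provenance <- match.arg(provenance)
  nl <- normal_liver(liver, tumor)
  if (any(tumor$values & nl$values)) {
    stop("tumor and normal liver overlap", call. = FALSE)  # unreachable guard
  }
  structure(list(liver = liver, tumor = tumor, normal_liver = nl,
                 target_threshold = target_threshold,
                 provenance = provenance),
            class = "contour_set")
}

#' Dice similarity index
#'
#' Overlap between two binary regions: \eqn{2|A \cap B| / (|A| + |B|)},
#' symmetric, in \[0, 1\].
#'
#' @param a,b [contour_mask()] objects on one grid.
#' @return Dice coefficient. Two empty masks are undefined and raise an error.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "contour_mask"), inherits(b, "contour_mask"))
  assert_aligned(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Registration quality gate on the Dice index
#'
#' Deformably registered anatomy contours are accepted only when the Dice
#' index between the transferred liver contour and the scintigraphic-CT liver
#' contour reaches the threshold (inclusive), default 0.85.
#'
#' @param dice_value Dice index in \[0, 1\] (vectorised).
#' @param threshold minimum accepted Dice, default 0.85.
#' @param patient_id optional ids used in the failure message.
#' @return Logical vector, `TRUE` = pass. Failures are reported via a warning
#'   naming the patient ids.
#' @export
registration_qa <- function(dice_value, threshold = 0.85, patient_id = NULL) {
  if (any(dice_value < 0 | dice_value > 1, na.rm = TRUE)) {
    stop("Dice values must lie in [0, 1]", call. = FALSE)
  }
  pass <- dice_value >= threshold
  if (any(!pass)) {
    ids <- if (is.null(patient_id)) which(!pass) else patient_id[!pass]
    warning("registration QA failed (Dice < ", threshold, ") for: ",
            paste(ids, collapse = ", "))
  }
  pass
}

#' Inter-operator variability as RMS of coefficients of variation
#'
#' For each structure delineated by two operators, the coefficient of
#' variation is the (n-1) sample standard deviation of the two volumes over
#' their mean — for two values \eqn{|v_A - v_B| / (\sqrt{2}\,\bar v)}. The
#' summary is the root mean square of the per-pair CVs, in percent.
#'
#' @param volume_pairs a two-column matrix/data frame of paired volumes (mL),
#'   one row per structure, or a list of length-2 numeric vectors.
#' @return RMS of the CVs, in percent.
#' @export
interoperator_rms_cv <- function(volume_pairs) {
  if (is.list(volume_pairs) && !is.data.frame(volume_pairs)) {
    volume_pairs <- do.call(rbind, volume_pairs)
  }
  volume_pairs <- as.matrix(volume_pairs)
  if (nrow(volume_pairs) < 1L || ncol(volume_pairs) != 2L) {
    stop("need at least one pair of volumes", call. = FALSE)
  }
  if (any(volume_pairs <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  cv <- apply(volume_pairs, 1L, function(v) stats::sd(v) / mean(v))
  sqrt(mean(cv^2)) * 100
}
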