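# ---------------------------------------------------------------------------
# Evaluation suite: signed symmetric volume change V, AAVC (plain and
# MAD-robust), inverse consistency error, MSE, mutual information, Dice and
# majority-vote label fusion.
# ---------------------------------------------------------------------------

#' Signed symmetric volume-change transform
#'
#' Because the Jacobian is not a linear function of volume change, squared
#' differences of Jacobians weight compression and expansion asymmetrically.
#' The V transform gives both the same importance:
#' V = 1 - 1/J for J in (0, 1) and V = J - 1 for J >= 1, so that
#' |V(J)| = |V(1/J)| and V(1) = 0.
#'
#' @param J A `jacobian_map` or numeric vector/array of strictly positive
#'   volume ratios.
#' @return Same shape as the input (a plain array for a `jacobian_map`).
#' @export
v_transform <- function(J) {
  v <- if (inherits(J, "jacobian_map")) J$values else J
  if (any(v <= 0))
    stop("V transform requires strictly positive Jacobian values",
         call. = FALSE)
  ifelse(v >= 1, v - 1, 1 - 1 / v)
}

roi_logical <- function(roi, shape) {
  m <- mask_logical(roi, shape)
  if (is.null(m)) m <- array(TRUE, shape)
  m
}

aavc_values <- function(field, roi) {
  J <- if (inherits(field, "jacobian_map")) field
       else jacobian_determinant(field)
  m <- roi_logical(roi, vol_shape(J))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  abs(v_transform(J$values[m]))
}

#' Average absolute volume change (AAVC)
#'
#' The ROI mean of |V| for one subject's mapping h:
#' AAVC(h) = (1/|Omega|) sum over ROI voxels of |V\[J\[h\]\](x)|.
#' Zero iff the mapping changes no volume anywhere on the ROI.
#'
#' @param field A `displacement_field` (or a precomputed `jacobian_map`).
#' @param roi ROI mask (`label_volume`, mask array, or `NULL` for the whole
#'   grid).
#' @return The scalar AAVC.
#' @export
aavc <- function(field, roi = NULL) {
  mean(aavc_values(field, roi))
}

#' MAD-robust AAVC
#'
#' AAVC restricted to ROI voxels whose |V| lies within `k` median absolute
#' deviations of the ROI median of |V|; voxels further away are excluded as
#' outliers. A zero MAD (degenerate distribution) excludes nothing; if every
#' voxel would be excluded the plain AAVC is returned with a warning.
#'
#' @inheritParams aavc
#' @param k Outlier multiplier (default 2.5).
#' @return The scalar robust AAVC.
#' @export
robust_aavc <- function(field, roi = NULL, k = 2.5) {
  v <- aavc_values(field, roi)
  if (length(v) < 2L) stop("ROI must contain at least 2 voxels", call. = FALSE)
  med <- median(v)
  dev <- mad(v, constant = 1)
  if (dev == 0) return(mean(v))
  keep <- abs(v - med) <= k * dev
  if (!any(keep)) {
    warning("all ROI voxels excluded as outliers; returning plain AAVC",
            call. = FALSE)
    return(mean(v))
  }
  mean(v[keep])
}

#' Average inverse consistency error (AICE)
#'
#' Mean displacement magnitude of the round trip through a forward transform
#' h and the reverse-direction transform h_I (obtained when the roles of
#' fixed and moving image are swapped):
#' AICE = (1/|Omega|) sum over ROI of ||(h_I o h)(x) - x|| in mm.
#'
#' @param h,h_inv_reg `displacement_field`s on the reference grid.
#' @param roi ROI mask or `NULL`.
#' @return The scalar AICE in mm.
#' @export
aice <- function(h, h_inv_reg, roi = NULL) {
  require_same_grid(h, h_inv_reg, "forward and reverse fields")
  comp <- compose_fields(h_inv_reg, h)
  m <- roi_logical(roi, vol_shape(comp))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  mag <- sqrt(comp$vectors[, , , 1]^2 + comp$vectors[, , , 2]^2 +
              comp$vectors[, , , 3]^2)
  mean(mag[m])
}

#' Mean squared error within an ROI
#'
#' @param ref,warped `image_volume`s on the same grid (the warped image is
#'   the moving image already resampled to reference space).
#' @param roi ROI mask or `NULL`.
#' @param channels Channels to use; default the shared channel names except
#'   `"mask"`.
#' @param per_channel If `TRUE` return a named per-channel vector instead of
#'   the channel average.
#' @return Scalar MSE (or named vector).
#' @export
mse <- function(ref, warped, roi = NULL, channels = NULL,
                per_channel = FALSE) {
  stopifnot(inherits(ref, "image_volume"), inherits(warped, "image_volume"))
  require_same_grid(ref, warped, "images")
  if (is.null(channels))
    channels <- setdiff(intersect(names(ref$channels),
                                  names(warped$channels)), "mask")
  if (length(channels) == 0L) stop("no channels to compare", call. = FALSE)
  m <- roi_logical(roi, vol_shape(ref))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  out <- vapply(channels, function(nm)
    mean((ref$channels[[nm]][m] - warped$channels[[nm]][m])^2), numeric(1))
  if (per_channel) out else mean(out)
}

mi_one <- function(x, y, bins) {
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0 || diff(ry) == 0) return(0)  # single occupied bin
  ix <- pmin.int(floor((x - rx[1]) / diff(rx) * bins) + 1L, bins)
  iy <- pmin.int(floor((y - ry[1]) / diff(ry) * bins) + 1L, bins)
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  n <- length(x)
  p <- joint / n
  pj <- matrix(p, bins, bins)
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

#' Mutual information within an ROI
#'
#' MI between the reference and the warped subject image, approximated from
#' a joint histogram over the ROI voxels (default 256 x 256 bins), with
#' marginals obtained as histogram sums and the natural-log convention.
#' Intensity ranges are the per-image min/max within the ROI; empty bins
#' contribute 0. A constant image occupies a single bin and yields MI = 0.
#'
#' @inheritParams mse
#' @param bins Histogram bins per image (default 256).
#' @return Scalar MI in nats (or named per-channel vector).
#' @export
mutual_information <- function(ref, warped, roi = NULL, bins = 256L,
                               channels = NULL, per_channel = FALSE) {
  stopifnot(inherits(ref, "image_volume"), inherits(warped, "image_volume"))
  require_same_grid(ref, warped, "images")
  if (is.null(channels))
    channels <- setdiff(intersect(names(ref$channels),
                                  names(warped$channels)), "mask")
  m <- roi_logical(roi, vol_shape(ref))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  out <- vapply(channels, function(nm)
    mi_one(ref$channels[[nm]][m], warped$channels[[nm]][m], bins),
    numeric(1))
  if (per_channel) out else mean(out)
}

#' Sorensen-Dice overlap coefficient
#'
#' 2|A intersect B| / (|A| + |B|) for the voxel sets carrying `label` in the
#' two volumes; defined as 1 when both sets are empty.
#'
#' @param a,b `label_volume`s on the same grid.
#' @param label The label value to compare.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b, label) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  require_same_grid(a, b, "label volumes")
  A <- a$labels == label
  B <- b$labels == label
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Majority-vote label fusion
#'
#' Per voxel, assigns the label that attains a strict majority (more than
#' n/2 of the n input volumes); where no label reaches a strict majority the
#' voxel is assigned background (0). With this rule a structure that is
#' inconsistently mapped across subjects can disappear entirely from the
#' fused labelling.
#'
#' @param warped_labels A list of `label_volume`s on a common grid.
#' @return A `label_volume`.
#' @export
majority_vote <- function(warped_labels) {
  if (inherits(warped_labels, "label_volume"))
    warped_labels <- list(warped_labels)
  if (!is.list(warped_labels) || length(warped_labels) == 0L)
    stop("need at least one label volume", call. = FALSE)
  ref <- warped_labels[[1L]]
  for (lv in warped_labels) {
    stopifnot(inherits(lv, "label_volume"))
    require_same_grid(ref, lv, "label volumes")
  }
  n <- length(warped_labels)
  shp <- vol_shape(ref)
  labs <- sort(unique(unlist(lapply(warped_labels,
                                    function(v) unique(as.vector(v$labels))))))
  labs <- setdiff(labs, 0L)
  out <- array(0L, shp)
  for (l in labs) {
    cnt <- Reduce(`+`, lapply(warped_labels, function(v) v$labels == l))
    out[cnt > n / 2] <- l          # at most one label can exceed n/2
  }
  label_volume(out, ref$spacing, ref$origin)
}

#' Per-subject metric report
#'
#' Computes the evaluation metrics for one subject's registration to a
#' reference: AAVC (plain and MAD-robust), MSE and MI between the reference
#' and the warped subject, and per-label Dice if segmentations are supplied.
#'
#' @param reference Reference `image_volume`.
#' @param subject Subject `image_volume` (in its own space).
#' @param field `displacement_field` registering the subject to the
#'   reference.
#' @param roi ROI mask or `NULL`.
#' @param labels_ref,labels_subject Optional `label_volume`s: a reference-
#'   space labelling and the subject's segmentation (warped here).
#' @param subject_id Identifier recorded in the output row.
#' @return A one-row data.frame with columns `subject_id`, `aavc`,
#'   `robust_aavc`, `mse`, `mi`, and `dice_<label>` columns when labels are
#'   given.
#' @export
evaluate_subject <- function(reference, subject, field, roi = NULL,
                             labels_ref = NULL, labels_subject = NULL,
                             subject_id = NA_character_) {
  warped <- warp(subject, field)
  row <- data.frame(subject_id = subject_id,
                    aavc = aavc(field, roi),
                    robust_aavc = robust_aavc(field, roi),
                    mse = mse(reference, warped, roi),
                    mi = mutual_information(reference, warped, roi),
                    stringsAsFactors = FALSE)
  if (!is.null(labels_ref) && !is.null(labels_subject)) {
    wl <- warp(labels_subject, field)
    labs <- setdiff(sort(unique(as.vector(labels_ref$labels))), 0L)
    for (l in labs)
      row[[paste0("dice_", l)]] <- dice(labels_ref, wl, l)
  }
  row
}
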