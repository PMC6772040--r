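# ---------------------------------------------------------------------------
# Interpolation core. All samplers take physical points (mm) and convert to
# continuous 0-based voxel coordinates through the grid metadata. Two border
# policies: "clamp" (nearest-border value, used for vector fields so no
# spurious folds appear at the support edge) and "fill" (constant fill value,
# used for intensities).
# ---------------------------------------------------------------------------

# Sample a single 3-D array at physical points.
# pts: n x 3 matrix (mm). Returns numeric vector of length n.
sample_array <- function(arr, pts, spacing, origin,
                         interp = c("linear", "nearest"),
                         border = c("clamp", "fill"), fill = 0) {
  interp <- match.arg(interp)
  border <- match.arg(border)
  n <- dim(arr)
  v1 <- (pts[, 1L] - origin[1L]) / spacing[1L]
  v2 <- (pts[, 2L] - origin[2L]) / spacing[2L]
  v3 <- (pts[, 3L] - origin[3L]) / spacing[3L]
  oob <- NULL
  if (border == "fill")
    oob <- v1 < 0 | v1 > n[1L] - 1L | v2 < 0 | v2 > n[2L] - 1L |
           v3 < 0 | v3 > n[3L] - 1L
  v1 <- pmin.int(pmax.int(v1, 0), n[1L] - 1L)
  v2 <- pmin.int(pmax.int(v2, 0), n[2L] - 1L)
  v3 <- pmin.int(pmax.int(v3, 0), n[3L] - 1L)
  if (interp == "nearest") {
    i1 <- round(v1); i2 <- round(v2); i3 <- round(v3)
    out <- arr[1L + i1 + n[1L] * (i2 + n[2L] * i3)]
  } else {
    # lower corner index, clamped so the upper corner stays in range;
    # degenerate axes (extent 1) sample the single plane with weight 1
    i1 <- if (n[1L] > 1L) pmin.int(floor(v1), n[1L] - 2L) else 0
    i2 <- if (n[2L] > 1L) pmin.int(floor(v2), n[2L] - 2L) else 0
    i3 <- if (n[3L] > 1L) pmin.int(floor(v3), n[3L] - 2L) else 0
    t1 <- v1 - i1; t2 <- v2 - i2; t3 <- v3 - i3
    s1 <- 1 - t1; s2 <- 1 - t2; s3 <- 1 - t3
    d1 <- if (n[1L] > 1L) 1L else 0L
    d2 <- if (n[2L] > 1L) n[1L] else 0L
    d3 <- if (n[3L] > 1L) n[1L] * n[2L] else 0L
    base <- 1L + i1 + n[1L] * (i2 + n[2L] * i3)
    out <- s1 * s2 * s3 * arr[base] +
           t1 * s2 * s3 * arr[base + d1] +
           s1 * t2 * s3 * arr[base + d2] +
           t1 * t2 * s3 * arr[base + d1 + d2] +
           s1 * s2 * t3 * arr[base + d3] +
           t1 * s2 * t3 * arr[base + d1 + d3] +
           s1 * t2 * t3 * arr[base + d2 + d3] +
           t1 * t2 * t3 * arr[base + d1 + d2 + d3]
  }
  if (!is.null(oob) && any(oob)) out[oob] <- fill
  out
}

# Sample several arrays sharing one grid at the same points: the corner
# indices and trilinear weights are computed once and reused (hot path of
# the registration sweeps).
sample_arrays <- function(arrays, pts, spacing, origin,
                          border = c("clamp", "fill"), fill = 0) {
  border <- match.arg(border)
  n <- dim(arrays[[1L]])
  v1 <- (pts[, 1L] - origin[1L]) / spacing[1L]
  v2 <- (pts[, 2L] - origin[2L]) / spacing[2L]
  v3 <- (pts[, 3L] - origin[3L]) / spacing[3L]
  oob <- NULL
  if (border == "fill")
    oob <- v1 < 0 | v1 > n[1L] - 1L | v2 < 0 | v2 > n[2L] - 1L |
           v3 < 0 | v3 > n[3L] - 1L
  v1 <- pmin.int(pmax.int(v1, 0), n[1L] - 1L)
  v2 <- pmin.int(pmax.int(v2, 0), n[2L] - 1L)
  v3 <- pmin.int(pmax.int(v3, 0), n[3L] - 1L)
  i1 <- if (n[1L] > 1L) pmin.int(floor(v1), n[1L] - 2L) else 0
  i2 <- if (n[2L] > 1L) pmin.int(floor(v2), n[2L] - 2L) else 0
  i3 <- if (n[3L] > 1L) pmin.int(floor(v3), n[3L] - 2L) else 0
  t1 <- v1 - i1; t2 <- v2 - i2; t3 <- v3 - i3
  s1 <- 1 - t1; s2 <- 1 - t2; s3 <- 1 - t3
  d1 <- if (n[1L] > 1L) 1L else 0L
  d2 <- if (n[2L] > 1L) n[1L] else 0L
  d3 <- if (n[3L] > 1L) n[1L] * n[2L] else 0L
  base <- 1L + i1 + n[1L] * (i2 + n[2L] * i3)
  w <- list(s1 * s2 * s3, t1 * s2 * s3, s1 * t2 * s3, t1 * t2 * s3,
            s1 * s2 * t3, t1 * s2 * t3, s1 * t2 * t3, t1 * t2 * t3)
  off <- c(0L, d1, d2, d1 + d2, d3, d1 + d3, d2 + d3, d1 + d2 + d3)
  lapply(arrays, function(a) {
    out <- w[[1L]] * a[base]
    for (q in 2:8) out <- out + w[[q]] * a[base + off[q]]
    if (!is.null(oob) && any(oob)) out[oob] <- fill
    out
  })
}

# k-th component of a field as a 3-D array (guards against dim dropping)
comp_array <- function(field, k) array(field$vectors[, , , k], vol_shape(field))

# Sample the three components of a displacement field at physical points.
# Border policy is always nearest-border clamp for vector fields.
sample_field_vectors <- function(field, pts) {
  out <- matrix(0, nrow = nrow(pts), ncol = 3L)
  for (k in 1:3)
    out[, k] <- sample_array(comp_array(field, k), pts,
                             field$spacing, field$origin,
                             interp = "linear", border = "clamp")
  out
}

#' Warp a volume through a displacement field
#'
#' Resamples the input so that `output(x) = input(x + u(x))`: samples are
#' taken in the moving volume's space from coordinates in the reference
#' space, leaving no holes. Intensity volumes use trilinear interpolation by
#' default; label volumes must use nearest-neighbour (which can invent no new
#' labels).
#'
#' @param x An `image_volume`, `label_volume` or `jacobian_map` to resample.
#' @param field A `displacement_field` on the output grid.
#' @param interp `"linear"` or `"nearest"`; `"linear"` is an error for label
#'   volumes.
#' @param fill Fill value for samples falling outside the input support
#'   (default 0).
#' @return An object of the same class as `x`, on the grid of `field`.
#' @export
warp <- function(x, field, interp = c("linear", "nearest"), fill = 0) {
  UseMethod("warp")
}

warp_points <- function(field) {
  shp <- vol_shape(field)
  pts <- grid_points_mm(shp, field$spacing, field$origin)
  pts[, 1L] <- pts[, 1L] + as.vector(field$vectors[, , , 1L])
  pts[, 2L] <- pts[, 2L] + as.vector(field$vectors[, , , 2L])
  pts[, 3L] <- pts[, 3L] + as.vector(field$vectors[, , , 3L])
  pts
}

#' @export
warp.image_volume <- function(x, field, interp = c("linear", "nearest"),
                              fill = 0) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "displacement_field"))
  pts <- warp_points(field)
  shp <- vol_shape(field)
  ch <- lapply(x$channels, function(a)
    array(sample_array(a, pts, x$spacing, x$origin, interp = interp,
                       border = "fill", fill = fill), shp))
  image_volume(ch, field$spacing, field$origin)
}

#' @export
warp.label_volume <- function(x, field, interp = c("nearest", "linear"),
                              fill = 0) {
  interp <- match.arg(interp)
  if (interp != "nearest")
    stop("label volumes must be warped with nearest-neighbour interpolation",
         call. = FALSE)
  stopifnot(inherits(field, "displacement_field"))
  pts <- warp_points(field)
  shp <- vol_shape(field)
  lab <- array(sample_array(x$labels, pts, x$spacing, x$origin,
                            interp = "nearest", border = "fill",
                            fill = fill), shp)
  label_volume(lab, field$spacing, field$origin)
}

#' @export
warp.jacobian_map <- function(x, field, interp = c("linear", "nearest"),
                              fill = 1) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "displacement_field"))
  pts <- warp_points(field)
  shp <- vol_shape(field)
  jacobian_map(array(sample_array(x$values, pts, x$spacing, x$origin,
                                  interp = interp, border = "fill",
                                  fill = fill), shp),
               field$spacing, field$origin)
}

#' Resample the initial reference by half a voxel
#'
#' Applies a constant translation of +0.5 voxel pitch along every axis with
#' linear interpolation. The anatomy is unchanged but the interpolation
#' smoothing that any later resampling step introduces is now present, so
#' image-similarity metrics compare like with like between an initial and a
#' synthetic (resampled) reference.
#'
#' @param image An `image_volume`.
#' @return The resampled `image_volume` on the same grid.
#' @export
halfvoxel_resample <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  shp <- vol_shape(image)
  pts <- grid_points_mm(shp, image$spacing, image$origin)
  pts[, 1L] <- pts[, 1L] + 0.5 * image$spacing[1L]
  pts[, 2L] <- pts[, 2L] + 0.5 * image$spacing[2L]
  pts[, 3L] <- pts[, 3L] + 0.5 * image$spacing[3L]
  ch <- lapply(image$channels, function(a)
    array(sample_array(a, pts, image$spacing, image$origin,
                       interp = "linear", border = "clamp"), shp))
  image_volume(ch, image$spacing, image$origin)
}

# Resample an image/label/field onto a new grid geometry (used by the
# registration pyramid). Border clamp keeps coarse grids well defined.
resample_to_grid <- function(x, shape, spacing, origin) {
  pts <- grid_points_mm(shape, spacing, origin)
  if (inherits(x, "image_volume")) {
    ch <- lapply(x$channels, function(a)
      array(sample_array(a, pts, x$spacing, x$origin,
                         interp = "linear", border = "clamp"), shape))
    image_volume(ch, spacing, origin)
  } else if (inherits(x, "displacement_field")) {
    v <- array(0, c(shape, 3L))
    for (k in 1:3)
      v[, , , k] <- sample_array(comp_array(x, k), pts, x$spacing,
                                 x$origin, interp = "linear",
                                 border = "clamp")
    displacement_field(v, spacing, origin)
  } else if (inherits(x, "label_volume")) {
    label_volume(array(sample_array(x$labels, pts, x$spacing, x$origin,
                                    interp = "nearest", border = "clamp"),
                       shape), spacing, origin)
  } else stop("cannot resample this type", call. = FALSE)
}
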