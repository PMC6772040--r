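# ---------------------------------------------------------------------------
# Grid-aligned volume types. All objects live on a node-centred orthogonal
# grid: voxel index i (0-based) maps to the physical point origin + i*spacing
# (mm). Every type carries shape/spacing/origin so that operations mixing
# volumes can check grid compatibility.
# ---------------------------------------------------------------------------

check_grid_meta <- function(shape, spacing, origin) {
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)", call. = FALSE)
  invisible(TRUE)
}

#' Multi-channel scalar image volume
#'
#' An `image_volume` holds one or more co-registered scalar channels (for
#' example absolute fat content, absolute water content, and a binary body
#' mask) on a shared orthogonal grid with physical spacing in mm.
#'
#' @param channels A named list of 3-D numeric arrays sharing a common shape,
#'   or a single 3-D array (stored as channel `"value"`).
#' @param spacing Voxel size in mm per axis (length 3, strictly positive).
#' @param origin Physical coordinate (mm) of voxel (0, 0, 0). Default c(0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(channels, spacing, origin = c(0, 0, 0)) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- list(value = channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("channels must be a non-empty named list of 3-D arrays", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named", call. = FALSE)
  shp <- dim(channels[[1L]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("channel '", nm, "' is not a 3-D array", call. = FALSE)
    if (!identical(dim(ch), shp))
      stop("channel '", nm, "' does not share the common shape", call. = FALSE)
    if (any(!is.finite(ch)))
      stop("channel '", nm, "' contains non-finite intensities", call. = FALSE)
  }
  check_grid_meta(shp, spacing, origin)
  structure(list(channels = channels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Integer label volume
#'
#' Organ-segmentation grid; 0 denotes background.
#'
#' @param labels 3-D array of non-negative integers.
#' @param spacing,origin Grid metadata as in [image_volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3-D array", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  check_grid_meta(dim(labels), spacing, origin)
  structure(list(labels = array(as.integer(round(labels)), dim(labels)),
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' Dense displacement field
#'
#' Stores the displacement u of a deformation f(x) = x + u(x) as a 4-D array
#' `[nx, ny, nz, 3]` in physical units (mm), on the reference grid. The i-th
#' vector component displaces along physical axis i.
#'
#' @param vectors 4-D numeric array with trailing dimension 3 (mm).
#' @param spacing,origin Grid metadata as in [image_volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing, origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (!is.array(vectors) || length(d) != 4L || d[4L] != 3L)
    stop("vectors must be a 4-D array with trailing dimension 3", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field contains non-finite values", call. = FALSE)
  check_grid_meta(d[1:3], spacing, origin)
  structure(list(vectors = vectors,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' Zero displacement field on a given grid
#'
#' @param shape Voxels per axis (length 3).
#' @param spacing,origin Grid metadata.
#' @export
zero_field <- function(shape, spacing, origin = c(0, 0, 0)) {
  displacement_field(array(0, c(shape, 3L)), spacing, origin)
}

#' Jacobian determinant map
#'
#' Scalar volume of local volume-change ratios det(∂f/∂x): 1 means no volume
#' change, values above 1 expansion, in (0, 1) contraction, and values at or
#' below 0 a locally non-invertible (folding) mapping.
#'
#' @param values 3-D numeric array (dimensionless).
#' @param spacing,origin Grid metadata.
#' @return An object of class `jacobian_map`.
#' @export
jacobian_map <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("Jacobian map contains non-finite values", call. = FALSE)
  check_grid_meta(dim(values), spacing, origin)
  structure(list(values = values,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "jacobian_map")
}

# --- shared accessors -------------------------------------------------------

#' Grid shape, spacing and origin of a volume object
#'
#' @param x An `image_volume`, `label_volume`, `displacement_field` or
#'   `jacobian_map`.
#' @return Integer (shape) or numeric (spacing, origin) vector of length 3.
#' @export
vol_shape <- function(x) {
  if (inherits(x, "image_volume")) dim(x$channels[[1L]])
  else if (inherits(x, "label_volume")) dim(x$labels)
  else if (inherits(x, "displacement_field")) dim(x$vectors)[1:3]
  else if (inherits(x, "jacobian_map")) dim(x$values)
  else stop("not a grid volume object", call. = FALSE)
}

#' @rdname vol_shape
#' @export
vol_spacing <- function(x) x$spacing

#' @rdname vol_shape
#' @export
vol_origin <- function(x) x$origin

#' Extract a channel from an image volume
#'
#' @param img An `image_volume`.
#' @param name Channel name; defaults to the first channel.
#' @return A 3-D array.
#' @export
channel <- function(img, name = NULL) {
  stopifnot(inherits(img, "image_volume"))
  if (is.null(name)) return(img$channels[[1L]])
  if (!name %in% names(img$channels))
    stop("no channel named '", name, "'", call. = FALSE)
  img$channels[[name]]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(as.integer(vol_shape(a)), as.integer(vol_shape(b))) &&
    max(abs(vol_spacing(a) - vol_spacing(b))) < tol &&
    max(abs(vol_origin(a) - vol_origin(b))) < tol
}

require_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not defined on the same grid", call. = FALSE)
  invisible(TRUE)
}

# Physical coordinates of all grid nodes, as an n x 3 matrix in array
# (column-major) order: first index fastest.
grid_points_mm <- function(shape, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + spacing[a] * (seq_len(shape[a]) - 1))
  n <- shape
  cbind(rep(ax[[1L]], times = n[2L] * n[3L]),
        rep(rep(ax[[2L]], each = n[1L]), times = n[3L]),
        rep(ax[[3L]], each = n[1L] * n[2L]))
}

# logical array marking the one-voxel boundary shell of a grid
boundary_shell <- function(shape) {
  b <- array(FALSE, shape)
  b[c(1L, shape[1L]), , ] <- TRUE
  b[, c(1L, shape[2L]), ] <- TRUE
  b[, , c(1L, shape[3L])] <- TRUE
  b
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(vol_shape(x), collapse = " x "),
      " voxels, channels: ", paste(names(x$channels), collapse = ", "),
      "\n  spacing (mm): ", paste(signif(x$spacing, 4), collapse = " x "),
      ", origin (mm): ", paste(signif(x$origin, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat("<label_volume> ", paste(vol_shape(x), collapse = " x "),
      " voxels, labels: ", paste(labs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1L]^2 + x$vectors[, , , 2L]^2 +
              x$vectors[, , , 3L]^2)
  cat("<displacement_field> ", paste(vol_shape(x), collapse = " x "),
      " voxels, max |u| = ", signif(max(mag), 4), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.jacobian_map <- function(x, ...) {
  cat("<jacobian_map> ", paste(vol_shape(x), collapse = " x "),
      " voxels, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}
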