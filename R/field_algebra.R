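# ---------------------------------------------------------------------------
# Displacement-field algebra: Jacobian determinants, composition, inversion.
# Derivatives are taken in physical units (divided by the per-axis spacing in
# mm), which matters on anisotropic grids such as whole-body MR protocols
# with 2.07 x 2.07 x 8.00 mm voxels.
# ---------------------------------------------------------------------------

# Finite difference of a 3-D array along one axis, spacing-normalized:
# central differences at interior nodes, one-sided at the two boundary
# planes, so the output has the same shape as the input.
fd_axis <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n < 2L)
    stop("cannot differentiate along an axis with fewer than 2 voxels",
         call. = FALSE)
  ip <- c(2:n, n)
  im <- c(1L, 1:(n - 1L))
  args_p <- list(a, quote(expr = ), quote(expr = ), quote(expr = ))
  args_m <- args_p
  args_p[[axis + 1L]] <- ip
  args_m[[axis + 1L]] <- im
  ap <- do.call(`[`, c(args_p, list(drop = FALSE)))
  am <- do.call(`[`, c(args_m, list(drop = FALSE)))
  den <- (ip - im) * h              # 1h at the ends, 2h in the interior
  sweep(ap - am, axis, den, "/")
}

#' Jacobian determinant of a deformation
#'
#' Computes the per-voxel determinant of the Jacobian matrix of the
#' deformation f(x) = x + u(x), i.e. det(I + Du) with spatial derivatives of
#' u taken by spacing-normalized finite differences (central at interior
#' voxels, one-sided at the boundary). The value is the local volume-change
#' ratio of the mapping.
#'
#' @param field A `displacement_field`.
#' @return A `jacobian_map` on the same grid.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  shp <- vol_shape(field)
  if (any(shp < 2L))
    stop("Jacobian requires at least 2 voxels per axis", call. = FALSE)
  sp <- field$spacing
  A <- vector("list", 9L)            # A[[3*(j-1)+i]] = dfi/dxj
  for (i in 1:3) {
    ui <- comp_array(field, i)
    for (j in 1:3) {
      d <- fd_axis(ui, j, sp[j])
      if (i == j) d <- d + 1
      A[[3L * (j - 1L) + i]] <- d
    }
  }
  a11 <- A[[1L]]; a21 <- A[[2L]]; a31 <- A[[3L]]
  a12 <- A[[4L]]; a22 <- A[[5L]]; a32 <- A[[6L]]
  a13 <- A[[7L]]; a23 <- A[[8L]]; a33 <- A[[9L]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  jacobian_map(det, field$spacing, field$origin)
}

#' Compose two deformations
#'
#' Returns the displacement of `f_outer` composed with `f_inner` (first apply
#' inner, then outer), i.e. the field of `(f_outer o f_inner) - id` on the
#' grid of `inner`. The outer displacement is sampled at the inner-mapped
#' points by trilinear interpolation of the vector components; points mapped
#' outside the outer support take the nearest-border vector value.
#'
#' @param outer,inner `displacement_field` objects.
#' @return A `displacement_field` on the grid of `inner`.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "displacement_field"),
            inherits(inner, "displacement_field"))
  shp <- vol_shape(inner)
  pts <- warp_points(inner)          # x + u_inner(x)
  uo <- sample_field_vectors(outer, pts)
  v <- array(0, c(shp, 3L))
  for (k in 1:3)
    v[, , , k] <- comp_array(inner, k) + array(uo[, k], shp)
  displacement_field(v, inner$spacing, inner$origin)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse deformation: with f = id + u, the
#' inverse displacement v satisfies v(x) = -u(x + v(x)); the scheme iterates
#' v_{k+1}(x) = -u(x + v_k(x)) from v_0 = -u and stops when the maximum
#' update falls below `tol` (mm) or `max_iter` is reached. Requires an
#' approximately invertible field (min Jacobian > 0 recommended).
#'
#' @param field A `displacement_field`.
#' @param tol Convergence threshold on the maximum update, mm (default 0.1).
#' @param max_iter Iteration cap (default 50).
#' @return A `displacement_field` with an attribute `"report"`: a list with
#'   `iterations`, `max_update` (mm) and `converged`. A warning is issued on
#'   non-convergence; the best iterate is still returned.
#' @export
invert_field <- function(field, tol = 0.1, max_iter = 50L) {
  stopifnot(inherits(field, "displacement_field"))
  shp <- vol_shape(field)
  pts0 <- grid_points_mm(shp, field$spacing, field$origin)
  v <- -field$vectors
  it <- 0L
  upd <- Inf
  while (it < max_iter) {
    it <- it + 1L
    pts <- pts0
    pts[, 1L] <- pts[, 1L] + as.vector(v[, , , 1L])
    pts[, 2L] <- pts[, 2L] + as.vector(v[, , , 2L])
    pts[, 3L] <- pts[, 3L] + as.vector(v[, , , 3L])
    u_at <- sample_field_vectors(field, pts)
    vnew <- array(0, c(shp, 3L))
    for (k in 1:3) vnew[, , , k] <- array(-u_at[, k], shp)
    upd <- max(abs(vnew - v))
    v <- vnew
    if (upd < tol) break
  }
  converged <- upd < tol
  if (!converged)
    warning(sprintf(
      "field inversion did not converge in %d iterations (last update %.3g mm)",
      max_iter, upd), call. = FALSE)
  out <- displacement_field(v, field$spacing, field$origin)
  attr(out, "report") <- list(iterations = it, max_update = upd,
                              converged = converged)
  out
}
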