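# ---------------------------------------------------------------------------
# Cohort mean Jacobian and prescribed-Jacobian displacement synthesis.
# ---------------------------------------------------------------------------

#' Synthesis configuration
#'
#' Parameters of the prescribed-Jacobian displacement synthesis.
#'
#' @param epsilon Lower clamp applied to Jacobian values before taking
#'   logarithms (dimensionless, default 0.01). Removes singularities caused
#'   by local folds from imperfect registrations.
#' @param tol Convergence threshold: maximum absolute Jacobian mismatch over
#'   the enforced voxels (default 0.01).
#' @param max_iter Iteration cap (default 500).
#' @param step0 Initial update step for the line search (default 1).
#' @param mask Optional body mask restricting where matching is enforced: a
#'   `label_volume`, an `image_volume` mask channel, or a logical/numeric 3-D
#'   array. `NULL` enforces on all interior voxels.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(epsilon = 0.01, tol = 0.01, max_iter = 500L,
                             step0 = 1, mask = NULL) {
  stopifnot(epsilon > 0, tol > 0, max_iter >= 1, step0 > 0)
  structure(list(epsilon = epsilon, tol = tol,
                 max_iter = as.integer(max_iter), step0 = step0,
                 mask = mask),
            class = "synthesis_config")
}

mask_logical <- function(mask, shape) {
  if (is.null(mask)) return(NULL)
  m <- if (inherits(mask, "label_volume")) mask$labels > 0
       else if (inherits(mask, "image_volume")) channel(mask, "mask") > 0.5
       else if (inherits(mask, "jacobian_map")) mask$values > 0
       else mask > 0
  if (!identical(as.integer(dim(m)), as.integer(shape)))
    stop("mask shape does not match the target grid", call. = FALSE)
  array(as.logical(m), shape)
}

#' Clamped log-domain mean Jacobian of a cohort
#'
#' Voxel-wise geometric mean of the Jacobian maps, computed under logarithm
#' for numerical stability with a lower threshold `epsilon` imposed on each
#' input to remove singularities from local folds:
#' J-bar = exp( (1/n) sum_i ln(max(epsilon, J_i)) ). The output is strictly
#' >= epsilon everywhere.
#'
#' @param jacobians A list of `jacobian_map` objects on a common grid (or a
#'   single map).
#' @param epsilon Lower clamp, > 0 (default 0.01).
#' @return A `jacobian_map`.
#' @export
mean_jacobian <- function(jacobians, epsilon = 0.01) {
  if (inherits(jacobians, "jacobian_map")) jacobians <- list(jacobians)
  if (!is.list(jacobians) || length(jacobians) == 0L)
    stop("need at least one Jacobian map", call. = FALSE)
  stopifnot(epsilon > 0)
  ref <- jacobians[[1L]]
  acc <- array(0, vol_shape(ref))
  for (J in jacobians) {
    if (!inherits(J, "jacobian_map"))
      stop("all inputs must be jacobian_map objects", call. = FALSE)
    require_same_grid(ref, J, "Jacobian maps")
    acc <- acc + log(pmax(J$values, epsilon))
  }
  jacobian_map(exp(acc / length(jacobians)), ref$spacing, ref$origin)
}

# --- spectral Poisson solver (homogeneous Dirichlet) -----------------------
# DST-I along each axis diagonalizes the standard 7-point Laplacian with
# zero Dirichlet conditions one node outside the grid. Grids here are small
# (<= 64 per axis), so the transform is applied as a dense matrix product.

dst_matrix <- function(n) {
  k <- seq_len(n)
  sqrt(2 / (n + 1)) * sin(pi * outer(k, k) / (n + 1))  # symmetric, orthonormal
}

apply_axis <- function(a, M, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(a, perm)
  d <- dim(p)
  out <- array(M %*% matrix(p, nrow = d[1L]), d)
  aperm(out, order(perm))
}

poisson_dirichlet <- function(rhs, spacing) {
  n <- dim(rhs)
  S <- lapply(1:3, function(a) dst_matrix(n[a]))
  lam <- lapply(1:3, function(a) {
    k <- seq_len(n[a])
    (2 * cos(pi * k / (n[a] + 1)) - 2) / spacing[a]^2
  })
  w <- rhs
  for (a in 1:3) w <- apply_axis(w, S[[a]], a)
  den <- outer(outer(lam[[1L]], lam[[2L]], "+"), lam[[3L]], "+")
  w <- w / den
  for (a in 1:3) w <- apply_axis(w, S[[a]], a)
  w
}

zero_boundary <- function(v) {
  n <- dim(v)[1:3]
  v[c(1L, n[1L]), , , ] <- 0
  v[, c(1L, n[2L]), , ] <- 0
  v[, , c(1L, n[3L]), ] <- 0
  v
}

#' Synthesize a displacement field with a prescribed Jacobian
#'
#' Searches for a displacement u, zero on the grid boundary, whose
#' deformation id + u has a Jacobian determinant matching the `target` map.
#' Because u vanishes on the boundary the deformation is volume preserving
#' globally, so the target must have grid-wide mean 1; the target is first
#' made feasible by uniformly rescaling values outside the body mask
#' (background), leaving values inside the mask untouched (with no mask the
#' whole target is rescaled multiplicatively).
#'
#' Each iteration applies a gradient-type correction u <- u + s * grad(phi),
#' where phi solves the Poisson problem lap(phi) = target - J\[id + u\] with
#' zero Dirichlet conditions, and the step s is halved until the mismatch
#' objective sum((J - target)^2) decreases, making the objective trace
#' monotone non-increasing. Iteration stops when the maximum absolute
#' mismatch over the enforced voxels (mask intersected with the grid
#' interior) is at most `config$tol`, or at `config$max_iter`. Deterministic
#' given (target, config).
#'
#' @param target A strictly positive `jacobian_map`.
#' @param config A [synthesis_config()].
#' @return A `displacement_field` with attribute `"report"`: a list with
#'   `iterations`, `converged`, `max_mismatch` (over enforced voxels),
#'   `objective_trace` and `target_adjusted` (the feasible target actually
#'   matched).
#' @export
displacement_from_jacobian <- function(target, config = synthesis_config()) {
  stopifnot(inherits(target, "jacobian_map"),
            inherits(config, "synthesis_config"))
  shp <- vol_shape(target)
  if (any(shp < 4L))
    stop("synthesis requires at least 4 voxels per axis", call. = FALSE)
  Tv <- target$values
  if (any(Tv <= 0))
    stop("target Jacobian must be strictly positive", call. = FALSE)
  m <- mask_logical(config$mask, shp)
  N <- length(Tv)
  if (!is.null(m)) {
    bg <- !m
    if (!any(bg) || sum(Tv[bg]) <= 0) {
      Tv <- Tv / mean(Tv)
    } else {
      scale_bg <- (N - sum(Tv[m])) / sum(Tv[bg])
      if (!is.finite(scale_bg) || scale_bg <= 0)
        stop("target cannot be made feasible by background rescaling",
             call. = FALSE)
      Tv[bg] <- Tv[bg] * scale_bg
    }
  } else {
    Tv <- Tv / mean(Tv)
  }
  if (abs(mean(Tv) - 1) > 1e-6)
    stop("adjusted target mean differs from 1; infeasible with zero-boundary displacement",
         call. = FALSE)

  interior <- !boundary_shell(shp)
  enforced <- if (is.null(m)) interior else (m & interior)
  if (!any(enforced))
    stop("no enforced voxels (mask does not intersect the grid interior)",
         call. = FALSE)

  sp <- target$spacing
  u <- array(0, c(shp, 3L))
  field <- displacement_field(u, sp, target$origin)
  J <- jacobian_determinant(field)$values
  # mismatch objective over the enforced voxels; outside them the Jacobian
  # floats freely (it absorbs the global volume-preservation constraint)
  obj_of <- function(J) sum((J - Tv)[enforced]^2)
  obj <- obj_of(J)
  trace <- obj
  s <- config$step0
  it <- 0L
  converged <- max(abs(J - Tv)[enforced]) <= config$tol
  while (!converged && it < config$max_iter) {
    it <- it + 1L
    r <- array(0, shp)
    r[enforced] <- (Tv - J)[enforced]
    phi <- poisson_dirichlet(r, sp)
    g <- array(0, c(shp, 3L))
    for (k in 1:3) g[, , , k] <- fd_axis(phi, k, sp[k])
    g <- zero_boundary(g)
    accepted <- FALSE
    for (h in 1:25) {
      u2 <- u + s * g
      f2 <- displacement_field(u2, sp, target$origin)
      J2 <- jacobian_determinant(f2)$values
      obj2 <- obj_of(J2)
      if (obj2 < obj) {
        u <- u2; J <- J2; obj <- obj2
        s <- min(config$step0, s * 1.5)
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    trace <- c(trace, obj)
    if (!accepted) break
    converged <- max(abs(J - Tv)[enforced]) <= config$tol
  }
  out <- displacement_field(u, sp, target$origin)
  report <- list(iterations = it, converged = converged,
                 max_mismatch = max(abs(J - Tv)[enforced]),
                 objective_trace = trace,
                 target_adjusted = jacobian_map(Tv, sp, target$origin))
  if (!converged)
    warning(sprintf(
      "displacement synthesis stopped at iteration %d with max mismatch %.4g",
      it, report$max_mismatch), call. = FALSE)
  attr(out, "report") <- report
  out
}
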