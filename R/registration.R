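# ---------------------------------------------------------------------------
# Pairwise multi-channel deformable registration. The energy is a per-channel
# weighted sum of squared intensity differences plus a diffusion regularizer
# over 6-connected neighbour pairs. The minimizer is a monotone line-searched
# gradient descent over a coarse-to-fine pyramid; any minimizer of this
# energy is admissible, the downstream reference construction consumes only
# the resulting displacement fields.
# ---------------------------------------------------------------------------

#' Registration configuration
#'
#' @param channel_weights Named non-negative weights per channel; `NULL`
#'   weights all shared channels equally with 1.
#' @param smoothness_weight Multiplier on the diffusion regularizer
#'   (dimensionless, default 1).
#' @param pyramid_levels Number of resolution levels (default 3, x2
#'   downsampling per level).
#' @param step_mm Magnitude of the first displacement update proposed at each
#'   level, mm (default 2); subsequent steps adapt by the line search.
#' @param max_sweeps Maximum descent sweeps per level (default 40).
#' @param rel_tol Relative energy-improvement threshold terminating a level
#'   (default 1e-4).
#' @param seed Integer recorded for provenance; the minimizer itself is
#'   deterministic.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(channel_weights = NULL, smoothness_weight = 1,
                                pyramid_levels = 3L, step_mm = 2,
                                max_sweeps = 40L, rel_tol = 1e-4, seed = 0L) {
  stopifnot(pyramid_levels >= 1, step_mm > 0, max_sweeps >= 1,
            smoothness_weight >= 0)
  if (!is.null(channel_weights)) {
    if (is.null(names(channel_weights)) || any(channel_weights < 0))
      stop("channel_weights must be named and non-negative", call. = FALSE)
    if (all(channel_weights == 0))
      stop("at least one channel weight must be positive", call. = FALSE)
  }
  structure(list(channel_weights = channel_weights,
                 smoothness_weight = smoothness_weight,
                 pyramid_levels = as.integer(pyramid_levels),
                 step_mm = step_mm, max_sweeps = as.integer(max_sweeps),
                 rel_tol = rel_tol, seed = as.integer(seed)),
            class = "registration_config")
}

reg_weights <- function(fixed, moving, config) {
  chf <- names(fixed$channels); chm <- names(moving$channels)
  if (!setequal(chf, chm))
    stop("fixed and moving images do not share channel names", call. = FALSE)
  w <- config$channel_weights
  if (is.null(w)) return(setNames(rep(1, length(chf)), chf))
  if (!all(names(w) %in% chf))
    stop("channel_weights name channels absent from the images", call. = FALSE)
  out <- setNames(rep(0, length(chf)), chf)
  out[names(w)] <- w
  out
}

# squared-difference data term, moving sampled at p + u(p)
reg_data_energy <- function(fixed, moving, pts, w) {
  e <- 0
  for (nm in names(w)) {
    if (w[[nm]] == 0) next
    mv <- sample_array(moving$channels[[nm]], pts, moving$spacing,
                       moving$origin, interp = "linear", border = "fill",
                       fill = 0)
    e <- e + w[[nm]] * sum((as.vector(fixed$channels[[nm]]) - mv)^2)
  }
  e
}

# diffusion regularizer: each unordered 6-neighbour pair counted once
reg_smooth_energy <- function(u) {
  n <- dim(u)[1:3]
  e <- 0
  for (k in 1:3) {
    v <- u[, , , k]
    if (n[1L] > 1L) e <- e + sum((v[-1, , , drop = FALSE] -
                                  v[-n[1L], , , drop = FALSE])^2)
    if (n[2L] > 1L) e <- e + sum((v[, -1, , drop = FALSE] -
                                  v[, -n[2L], , drop = FALSE])^2)
    if (n[3L] > 1L) e <- e + sum((v[, , -1, drop = FALSE] -
                                  v[, , -n[3L], drop = FALSE])^2)
  }
  e
}

#' Registration energy
#'
#' The pairwise registration objective: a weighted sum of squared intensity
#' differences over the image channels, with the moving image sampled by
#' linear interpolation at the displaced positions, plus a diffusion
#' regularizer penalizing first-order variation of the displacement over the
#' set of 6-connected neighbouring voxel pairs (each unordered pair counted
#' once):
#' `E = sum_c w_c sum_p (I_fix(p) - I_mov(p + u(p)))^2 +
#'  lambda sum_(p,q) ||u(p) - u(q)||^2`.
#'
#' @param fixed,moving `image_volume`s sharing channel names.
#' @param u A `displacement_field` on the fixed grid.
#' @param config A [registration_config()].
#' @return The scalar energy.
#' @export
energy <- function(fixed, moving, u, config = registration_config()) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"),
            inherits(u, "displacement_field"))
  require_same_grid(fixed, u, "fixed image and displacement")
  w <- reg_weights(fixed, moving, config)
  pts <- warp_points(u)
  reg_data_energy(fixed, moving, pts, w) +
    config$smoothness_weight * reg_smooth_energy(u$vectors)
}

# graph Laplacian of each component (replicate-edge shifts make missing
# neighbour contributions vanish)
shift_axis <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin.int(pmax.int(seq_len(n) + by, 1L), n)
  args <- list(a, quote(expr = ), quote(expr = ), quote(expr = ))
  args[[axis + 1L]] <- idx
  do.call(`[`, c(args, list(drop = FALSE)))
}

laplacian_term <- function(v) {
  out <- 0 * v
  for (ax in 1:3)
    out <- out + (2 * v - shift_axis(v, ax, 1L) - shift_axis(v, ax, -1L))
  out
}

level_grid <- function(shape, spacing, level) {
  f <- 2^(level - 1L)
  list(shape = pmax(4L, as.integer(ceiling(shape / f))), spacing = spacing * f)
}

#' Pairwise deformable registration
#'
#' Minimizes [energy()] by monotone gradient descent with a backtracking line
#' search, over a coarse-to-fine resolution pyramid. An optional initial
#' field warm-starts the optimization (composed fields from a previous
#' reference-construction round make good initializations and the method
#' takes advantage of them). The returned field never has higher full-
#' resolution energy than the initialization (or the zero field if none is
#' given).
#'
#' @param fixed,moving `image_volume`s sharing channel names.
#' @param config A [registration_config()].
#' @param init Optional `displacement_field` on the fixed grid.
#' @return A `displacement_field` on the fixed grid, with attribute
#'   `"report"`: a list with per-level sweep counts and the energy trace.
#' @export
register <- function(fixed, moving, config = registration_config(),
                     init = NULL) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  w <- reg_weights(fixed, moving, config)
  shp <- vol_shape(fixed)
  if (is.null(init)) init <- zero_field(shp, fixed$spacing, fixed$origin)
  require_same_grid(fixed, init, "fixed image and init field")
  e_init <- energy(fixed, moving, init, config)
  lambda <- config$smoothness_weight

  u_cur <- init
  trace <- list()
  for (lev in seq(config$pyramid_levels, 1L)) {
    lg <- level_grid(shp, fixed$spacing, lev)
    fix_l <- if (lev == 1L) fixed else
      resample_to_grid(fixed, lg$shape, lg$spacing, fixed$origin)
    mov_l <- if (lev == 1L) moving else
      resample_to_grid(moving, lg$shape, lg$spacing, moving$origin)
    u_l <- if (identical(as.integer(vol_shape(u_cur)), as.integer(lg$shape)))
      u_cur else resample_to_grid(u_cur, lg$shape, lg$spacing, fixed$origin)
    # at the finest level, never start from something worse than the init
    if (lev == 1L) {
      if (energy(fixed, moving, u_l, config) > e_init) u_l <- init
    }
    # per-level caches: grid points, fixed-channel vectors, moving gradients
    pts0 <- grid_points_mm(lg$shape, lg$spacing, fixed$origin)
    act <- names(w)[w > 0]
    fixv <- lapply(act, function(nm) as.vector(fix_l$channels[[nm]]))
    names(fixv) <- act
    grads <- lapply(act, function(nm) {
      a <- mov_l$channels[[nm]]
      lapply(1:3, function(k) fd_axis(a, k, lg$spacing[k]))
    })
    names(grads) <- act
    mapped <- function(uvec) {
      p <- pts0
      p[, 1L] <- p[, 1L] + as.vector(uvec[, , , 1L])
      p[, 2L] <- p[, 2L] + as.vector(uvec[, , , 2L])
      p[, 3L] <- p[, 3L] + as.vector(uvec[, , , 3L])
      p
    }
    data_energy <- function(pts) {
      vals <- sample_arrays(lapply(act, function(nm) mov_l$channels[[nm]]),
                            pts, mov_l$spacing, mov_l$origin,
                            border = "fill", fill = 0)
      e <- 0
      for (q in seq_along(act))
        e <- e + w[[act[q]]] * sum((fixv[[q]] - vals[[q]])^2)
      e
    }
    level_energy <- function(uvec, pts = mapped(uvec))
      data_energy(pts) + lambda * reg_smooth_energy(uvec)
    level_gradient <- function(uvec, pts) {
      g <- array(0, c(lg$shape, 3L))
      for (nm in act) {
        sm <- sample_arrays(c(list(mov_l$channels[[nm]]), grads[[nm]]),
                            pts, mov_l$spacing, mov_l$origin,
                            border = "fill", fill = 0)
        resid <- sm[[1L]] - fixv[[nm]]
        for (k in 1:3)
          g[, , , k] <- g[, , , k] +
            array(2 * w[[nm]] * resid * sm[[k + 1L]], lg$shape)
      }
      for (k in 1:3)
        g[, , , k] <- g[, , , k] +
          2 * lambda * laplacian_term(array(uvec[, , , k], lg$shape))
      g
    }

    uv <- u_l$vectors
    pts_cur <- mapped(uv)
    e_cur <- level_energy(uv, pts_cur)
    etrace <- e_cur
    s <- NULL
    for (sw in seq_len(config$max_sweeps)) {
      g <- level_gradient(uv, pts_cur)
      gmax <- max(abs(g))
      if (gmax == 0) break
      if (is.null(s)) s <- config$step_mm / gmax
      accepted <- FALSE
      for (h in 1:12) {
        u_try <- uv - s * g
        pts_try <- mapped(u_try)
        e_try <- level_energy(u_try, pts_try)
        if (e_try < e_cur) {
          rel <- (e_cur - e_try) / max(e_cur, .Machine$double.eps)
          uv <- u_try; e_cur <- e_try; pts_cur <- pts_try
          s <- s * 1.5
          accepted <- TRUE
          etrace <- c(etrace, e_cur)
          if (rel < config$rel_tol) accepted <- NA  # converged at this level
          break
        }
        s <- s / 2
      }
      if (!isTRUE(accepted)) break
    }
    u_l <- displacement_field(uv, lg$spacing, fixed$origin)
    trace[[length(trace) + 1L]] <- list(level = lev, shape = lg$shape,
                                        energy = etrace)
    u_cur <- u_l
  }
  e_final <- energy(fixed, moving, u_cur, config)
  if (e_final > e_init) {        # contract: never degrade the initialization
    u_cur <- init
    e_final <- e_init
  }
  attr(u_cur, "report") <- list(levels = trace, energy_init = e_init,
                                energy_final = e_final)
  u_cur
}
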