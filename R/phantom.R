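# ---------------------------------------------------------------------------
# Seeded synthetic phantoms: body-like multi-channel volumes, organ labels
# and random diffeomorphisms with known properties. Anatomy is deliberately
# schematic (ellipsoids and shells): what downstream code exercises is field
# algebra and volume-change bookkeeping on anisotropic grids, not anatomical
# realism.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom specification
#'
#' @param shape Voxels per axis (default 48^3; at least 16 per axis for
#'   meaningful geometry).
#' @param spacing Voxel size in mm (default the anisotropic 2.07 x 2.07 x
#'   8.00 mm of whole-body MR protocols, so spacing-aware Jacobians are
#'   exercised).
#' @param n_organs Number of ellipsoidal organs (default 3).
#' @param fat_fraction_range Interval for the fraction of the body occupied
#'   by the subcutaneous fat shell (default c(0.2, 0.4)).
#' @param seed Integer fixing all randomness.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L),
                         spacing = c(2.07, 2.07, 8.0),
                         n_organs = 3L,
                         fat_fraction_range = c(0.2, 0.4),
                         seed = 0L) {
  stopifnot(length(shape) == 3L, all(shape >= 16L), all(spacing > 0),
            n_organs >= 0L,
            length(fat_fraction_range) == 2L,
            all(fat_fraction_range > 0), all(fat_fraction_range < 1))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_organs = as.integer(n_organs),
                 fat_fraction_range = fat_fraction_range,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a body-like multi-channel phantom
#'
#' Builds an ellipsoidal "body" with a subcutaneous fat shell, an interior
#' water compartment with smooth intensity gradients plus seeded noise, a
#' binary body-mask channel, and `n_organs` ellipsoidal labelled organs of
#' distinct intensity placed fully inside the water compartment. Outside the
#' body every channel is 0; inside, fat + water > 0.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (an `image_volume` with channels `fat`,
#'   `water`, `mask`) and `labels` (a `label_volume`, organs labelled 1..n).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape; sp <- spec$spacing
  ext <- (shp - 1) * sp
  ctr <- ext / 2
  semi <- 0.42 * ext                       # body semi-axes, mm
  pts <- grid_points_mm(shp, sp, c(0, 0, 0))
  r2 <- ((pts[, 1] - ctr[1]) / semi[1])^2 +
        ((pts[, 2] - ctr[2]) / semi[2])^2 +
        ((pts[, 3] - ctr[3]) / semi[3])^2
  body <- r2 <= 1
  with_seed(spec$seed, {
    ff <- runif(1, spec$fat_fraction_range[1], spec$fat_fraction_range[2])
    rho <- (1 - ff)^(1 / 3)                # inner radius of the fat shell
    core <- r2 <= rho^2
    shell <- body & !core
    # channels emulate absolute fat/water content on a 0-100 scale; smooth
    # large-scale gradients give the registration something to match
    gx <- 15 * (pts[, 1] - ctr[1]) / max(ext)
    gz <- 20 * (pts[, 3] - ctr[3]) / max(ext)
    fat <- ifelse(shell, 80 + gx, ifelse(core, 10, 0))
    water <- ifelse(core, 70 + gz, ifelse(shell, 15, 0))
    labels <- integer(length(r2))
    if (spec$n_organs > 0) {
      o_semi <- pmin(0.16 * ext, rho * semi * 0.35)  # organ semi-axes
      ang <- 2 * pi * (seq_len(spec$n_organs) - 1) / spec$n_organs +
        runif(spec$n_organs, -0.2, 0.2)
      rad <- 0.45 * rho                    # normalized placement radius
      for (k in seq_len(spec$n_organs)) {
        oc <- ctr + c(rad * semi[1] * cos(ang[k]),
                      rad * semi[2] * sin(ang[k]),
                      runif(1, -0.15, 0.15) * semi[3])
        # the organ must fit inside the water core
        rr <- sqrt(sum(((oc - ctr) / (rho * semi))^2))
        margin <- max(o_semi / (rho * semi))
        if (rr + margin >= 1)
          stop("cannot place ", spec$n_organs,
               " organs inside the body at this size", call. = FALSE)
        d2 <- ((pts[, 1] - oc[1]) / o_semi[1])^2 +
              ((pts[, 2] - oc[2]) / o_semi[2])^2 +
              ((pts[, 3] - oc[3]) / o_semi[3])^2
        inside <- d2 <= 1
        labels[inside] <- k
        water[inside] <- 40 + 15 * k       # distinct organ intensity
      }
    }
    # band-limit the piecewise anatomy (finite acquisition PSF) and give the
    # tissue a smooth texture: correlated fluctuations survive subvoxel
    # resampling, unlike white noise, and anchor the match in flat regions
    fat <- as.vector(gauss_smooth(array(fat, shp), c(1.2, 1.2, 1.2)))
    water <- as.vector(gauss_smooth(array(water, shp), c(1.2, 1.2, 1.2)))
    tex <- function() {
      a <- gauss_smooth(array(rnorm(prod(shp)), shp), c(1.5, 1.5, 1.5))
      as.vector(a) * (2 / stats::sd(a))
    }
    fat[body] <- pmax(fat[body] + tex()[body], 2)
    water[body] <- pmax(water[body] + tex()[body], 2)
    fat[!body] <- 0
    water[!body] <- 0
  })
  img <- image_volume(list(fat = array(fat, shp),
                           water = array(water, shp),
                           mask = array(as.numeric(body), shp)), sp)
  list(image = img,
       labels = label_volume(array(labels, shp), sp))
}

# separable Gaussian convolution along each axis (zero padding)
gauss_smooth <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(a)[ax]
    r <- max(1L, ceiling(3 * s))
    i <- seq_len(n)
    M <- exp(-(outer(i, i, "-")^2) / (2 * s^2))
    M[abs(outer(i, i, "-")) > r] <- 0
    M <- M / rowSums(M)
    a <- apply_axis(a, M, ax)
  }
  a
}

# smoothstep taper from 0 at the faces to 1 beyond `margin` voxels
boundary_taper <- function(shape, margin = 3) {
  w <- lapply(1:3, function(ax) {
    i <- seq_len(shape[ax]) - 1
    d <- pmin(i, shape[ax] - 1 - i) / margin
    t <- pmin(pmax(d, 0), 1)
    3 * t^2 - 2 * t^3
  })
  outer(outer(w[[1]], w[[2]]), w[[3]])
}

#' Generate a seeded random diffeomorphism
#'
#' Draws white noise per vector component, smooths it with a separable
#' Gaussian of physical width `smoothness_mm`, tapers it to zero on the grid
#' boundary, scales it to `magnitude_mm` maximum displacement, and finally
#' shrinks the amplitude by bisection until the minimum Jacobian determinant
#' is at least `min_jacobian` (so the field is guaranteed free of folds).
#'
#' @param shape,spacing Grid geometry.
#' @param smoothness_mm Gaussian width of the field, mm (default 15).
#' @param magnitude_mm Maximum displacement before the Jacobian constraint,
#'   mm (default 8).
#' @param min_jacobian Lower bound imposed on the Jacobian, in (0, 1)
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A `displacement_field` (zero on the boundary). If no positive
#'   amplitude satisfies the constraint a zero field is returned with a
#'   warning.
#' @export
make_diffeomorphism <- function(shape, spacing, smoothness_mm = 15,
                                magnitude_mm = 8, min_jacobian = 0.3,
                                seed = 0L) {
  stopifnot(min_jacobian > 0, min_jacobian < 1, magnitude_mm >= 0)
  shape <- as.integer(shape)
  if (magnitude_mm == 0)
    return(zero_field(shape, spacing))
  v <- with_seed(seed, array(rnorm(prod(shape) * 3L), c(shape, 3L)))
  sig <- smoothness_mm / spacing
  taper <- boundary_taper(shape)
  for (k in 1:3) v[, , , k] <- gauss_smooth(v[, , , k], sig) * taper
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  v <- v * (magnitude_mm / max(mag))
  minJ_at <- function(scale) {
    f <- displacement_field(v * scale, spacing)
    min(jacobian_determinant(f)$values)
  }
  if (minJ_at(1) >= min_jacobian) {
    out <- displacement_field(v, spacing)
  } else {
    lo <- 0; hi <- 1
    for (b in 1:30) {
      mid <- (lo + hi) / 2
      if (minJ_at(mid) >= min_jacobian) lo <- mid else hi <- mid
    }
    if (lo == 0) {
      warning("could not satisfy the Jacobian bound at any amplitude; ",
              "returning a zero field", call. = FALSE)
      return(zero_field(shape, spacing))
    }
    out <- displacement_field(v * lo, spacing)
  }
  out
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  3 * t^2 - 2 * t^3
}

#' Analytic test fields with closed-form Jacobians
#'
#' Constructs displacement fields whose Jacobian determinant is known in
#' closed form, for convergence and oracle testing.
#'
#' `radial_bump`: u(x) = a exp(-r^2 / 2 sigma^2) (x - c), a radially
#' symmetric expansion. With g(r) the Gaussian profile, the Jacobian is
#' (1 + g)^2 (1 + g + r g'(r)); invertibility requires a < e^{3/2}/2.
#'
#' `axis_scale`: a stretch by factor `s` along one axis confined to a padded
#' interior via smoothstep blending b of the axis coordinate, u = (s - 1)
#' times the antiderivative of b, so the Jacobian is exactly 1 + (s - 1)
#' b(x_axis): equal to `s` on the interior plateau and 1 near the faces.
#'
#' @param kind `"radial_bump"` or `"axis_scale"`.
#' @param shape,spacing Grid geometry.
#' @param params For `radial_bump`: list with `amplitude` (default 0.2),
#'   `sigma_mm` (default 1/6 of the smallest extent), `center` (mm, default
#'   the grid center). For `axis_scale`: list with `s` (default 1.2), `axis`
#'   (default 1), `margin_frac` (default 0.25).
#' @return A list with `field` (a `displacement_field`) and `jacobian` (the
#'   closed-form `jacobian_map`).
#' @export
make_analytic_field <- function(kind = c("radial_bump", "axis_scale"),
                                shape, spacing, params = list()) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  ext <- (shape - 1) * spacing
  pts <- grid_points_mm(shape, spacing, c(0, 0, 0))
  if (kind == "radial_bump") {
    a <- params$amplitude %||% 0.2
    sigma <- params$sigma_mm %||% (min(ext) / 6)
    ctr <- params$center %||% (ext / 2)
    if (a >= exp(1.5) / 2 || a <= -0.5)
      stop("radial bump amplitude outside the invertibility bound",
           call. = FALSE)
    dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]; dz <- pts[, 3] - ctr[3]
    r2 <- dx^2 + dy^2 + dz^2
    g <- a * exp(-r2 / (2 * sigma^2))
    v <- array(0, c(shape, 3L))
    v[, , , 1] <- array(g * dx, shape)
    v[, , , 2] <- array(g * dy, shape)
    v[, , , 3] <- array(g * dz, shape)
    # radial stretch 1 + g + r g', tangential (1 + g)^2; r g' = -(r^2/sigma^2) g
    Jv <- (1 + g)^2 * (1 + g - (r2 / sigma^2) * g)
    if (min(Jv) <= 0)
      stop("radial bump parameters imply a non-positive Jacobian",
           call. = FALSE)
    list(field = displacement_field(v, spacing),
         jacobian = jacobian_map(array(Jv, shape), spacing))
  } else {
    s <- params$s %||% 1.2
    axis <- params$axis %||% 1L
    mf <- params$margin_frac %||% 0.25
    if (s <= 0)
      stop("axis scale factor must be positive", call. = FALSE)
    m <- mf * ext[axis]
    x <- pts[, axis]
    lo <- m; hi <- ext[axis] - m
    # blend b: smoothstep up over [0, m], plateau 1, smoothstep down over
    # [hi, ext]; antiderivative B with B(0) = 0
    bstep <- function(t) t^3 - t^4 / 2                # antiderivative of 3t^2-2t^3
    b <- smoothstep(x / m) * (x < lo) + (x >= lo & x <= hi) +
      smoothstep((ext[axis] - x) / m) * (x > hi)
    B <- ifelse(x < lo, m * bstep(pmin(x / m, 1)),
         ifelse(x <= hi, m * bstep(1) + (x - lo),
                m * bstep(1) + (hi - lo) +
                  m * (bstep(1) - bstep(pmax((ext[axis] - x) / m, 0)))))
    v <- array(0, c(shape, 3L))
    v[, , , axis] <- array((s - 1) * B, shape)
    Jv <- 1 + (s - 1) * b
    if (min(Jv) <= 0)
      stop("axis scale parameters imply a non-positive Jacobian",
           call. = FALSE)
    list(field = displacement_field(v, spacing),
         jacobian = jacobian_map(array(Jv, shape), spacing))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort with known ground-truth deformations
#'
#' Warps one template phantom by `n_subjects` independent seeded
#' diffeomorphisms. Subject images are resampled through the inverse of each
#' ground-truth field, so the field that registers subject j back to the
#' template is exactly the returned `field_true`. Synthetic fat-mass and
#' height covariates are drawn per subject for reference-selection code.
#'
#' @param spec A [phantom_spec()] for the template.
#' @param n_subjects Number of subjects (>= 2).
#' @param deform_params List with `smoothness_mm`, `magnitude_mm`,
#'   `min_jacobian` forwarded to [make_diffeomorphism()].
#' @param seed Base seed; subject j uses `seed + j - 1`.
#' @return A list with `template` (the [make_phantom()] output), `subjects`
#'   (a list with `image`, `labels`, `field_true` per subject) and
#'   `covariates` (a data.frame with `subject_id`, `fat_mass`, `height`).
#' @export
make_cohort <- function(spec = phantom_spec(), n_subjects = 5L,
                        deform_params = list(), seed = 0L) {
  stopifnot(n_subjects >= 2L)
  dp <- modifyList(list(smoothness_mm = 15, magnitude_mm = 8,
                        min_jacobian = 0.3), deform_params)
  template <- make_phantom(spec)
  subjects <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    g <- make_diffeomorphism(spec$shape, spec$spacing,
                             smoothness_mm = dp$smoothness_mm,
                             magnitude_mm = dp$magnitude_mm,
                             min_jacobian = dp$min_jacobian,
                             seed = seed + j - 1L)
    ginv <- suppressWarnings(invert_field(g))
    subjects[[j]] <- list(
      image = warp(template$image, ginv),
      labels = warp(template$labels, ginv),
      field_true = g)
  }
  cov <- with_seed(seed + 1000L, data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    fat_mass = round(rnorm(n_subjects, 25, 5), 1),
    height = round(rnorm(n_subjects, 168, 7), 1),
    stringsAsFactors = FALSE))
  list(template = template, subjects = subjects, covariates = cov)
}
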