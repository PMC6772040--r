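# Displacement-field algebra: Jacobians, composition, inversion, warping.

test_that("Jacobian of translations is exactly 1 and of affine maps det(A)", {
  shp <- c(16, 16, 16)
  # pure translation: no volume change anywhere, including the boundary
  f <- constant_field(shp, c(5, -3, 2))
  expect_equal(jacobian_determinant(f)$values,
               array(1, shp), tolerance = 0)

  # linear map f(x) = (2 x1, x2, x3): diagonal Jacobian, det 2 everywhere
  pts <- avref:::grid_points_mm(shp, test_spacing, c(0, 0, 0))
  f2 <- zero_field(shp, test_spacing)
  f2$vectors[, , , 1] <- array(pts[, 1], shp)
  expect_equal(max(abs(jacobian_determinant(f2)$values - 2)), 0,
               tolerance = 1e-12)

  # general affine f(x) = A x + b: interior Jacobian equals det(A)
  A <- matrix(c(1.2, 0.1, -0.05,
                0.02, 0.9, 0.2,
                -0.1, 0.03, 1.1), 3, 3, byrow = TRUE)
  fa <- zero_field(shp, test_spacing)
  mapped <- pts %*% t(A)
  for (k in 1:3) fa$vectors[, , , k] <- array(mapped[, k] - pts[, k], shp)
  J <- jacobian_determinant(fa)$values
  expect_equal(max(abs(J[interior_mask(shp)] - det(A))), 0,
               tolerance = 1e-10)
})

test_that("Jacobian matches a per-voxel determinant-expansion oracle", {
  shp <- c(12, 12, 12)
  f <- random_smooth_field(shp, seed = 11)
  J <- jacobian_determinant(f)$values

  # independent oracle: loop voxels, build the 3x3 matrix entry by entry
  # from finite differences, expand the determinant by hand
  sp <- test_spacing
  u <- f$vectors
  oracle <- array(NA_real_, shp)
  for (i in 1:shp[1]) for (j in 1:shp[2]) for (k in 1:shp[3]) {
    idx <- c(i, j, k)
    M <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      hi <- idx; lo <- idx
      hi[b] <- min(idx[b] + 1, shp[b]); lo[b] <- max(idx[b] - 1, 1)
      num <- u[hi[1], hi[2], hi[3], a] - u[lo[1], lo[2], lo[3], a]
      M[a, b] <- num / ((hi[b] - lo[b]) * sp[b]) + (a == b)
    }
    oracle[i, j, k] <-
      M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
      M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
      M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  }
  expect_equal(max(abs(J - oracle)), 0, tolerance = 1e-12)
})

test_that("Jacobian rejects degenerate grids", {
  v <- array(0, c(1, 8, 8, 3))
  f <- displacement_field(v, c(1, 1, 1))
  expect_error(jacobian_determinant(f), "at least 2 voxels")
})

test_that("composition adds translations, is identity-neutral and associative", {
  shp <- c(12, 12, 12)
  t1 <- c(1.5, -2, 4); t2 <- c(-0.5, 1, 2.5)
  f1 <- constant_field(shp, t1)
  f2 <- constant_field(shp, t2)
  z <- zero_field(shp, test_spacing)

  cc <- compose_fields(f1, f2)
  for (k in 1:3)
    expect_equal(max(abs(cc$vectors[, , , k] - (t1[k] + t2[k]))), 0,
                 tolerance = 1e-12)

  f <- random_smooth_field(shp, seed = 3)
  expect_equal(compose_fields(f, z)$vectors, f$vectors, tolerance = 1e-12)

  # associativity, exact on translations
  t3 <- c(2, 2, -8)
  f3 <- constant_field(shp, t3)
  left <- compose_fields(compose_fields(f1, f2), f3)
  right <- compose_fields(f1, compose_fields(f2, f3))
  expect_equal(left$vectors, right$vectors, tolerance = 1e-12)
})

test_that("inversion: trivial cases and composition residual bound", {
  shp <- c(16, 16, 16)
  z <- zero_field(shp, test_spacing)
  expect_equal(invert_field(z)$vectors, z$vectors)

  t <- c(3, -1, 6)
  f <- constant_field(shp, t)
  fi <- invert_field(f)
  for (k in 1:3)
    expect_equal(max(abs(fi$vectors[, , , k] + t[k])), 0, tolerance = 1e-9)

  # smooth fold-free field: || f o f^-1 - id || < 0.5 mm on the interior
  g <- make_diffeomorphism(shp, test_spacing, smoothness_mm = 15,
                           magnitude_mm = 6, min_jacobian = 0.55, seed = 5)
  expect_gte(min(jacobian_determinant(g)$values), 0.55)
  gi <- invert_field(g, tol = 0.05, max_iter = 100)
  resid <- compose_fields(g, gi)   # (f o f^-1) - id
  expect_lt(max(field_magnitude(resid)[interior_mask(shp, 2)]), 0.5)
  # in voxel units: within a tenth of the smallest pitch
  expect_lt(max(field_magnitude(resid)[interior_mask(shp, 2)]) /
              min(test_spacing), 0.1)

  # round-trip residual decreases monotonically with the tolerance
  resids <- vapply(c(0.5, 0.1, 0.02), function(tl) {
    gi <- invert_field(g, tol = tl, max_iter = 200)
    max(field_magnitude(compose_fields(g, gi))[interior_mask(shp, 2)])
  }, numeric(1))
  expect_true(all(diff(resids) <= 1e-12))
})

test_that("warping: identity, impulse shift, label semantics", {
  shp <- c(12, 12, 12)
  set.seed(42)
  img <- image_volume(list(value = array(runif(prod(shp)), shp)),
                      test_spacing)
  z <- zero_field(shp, test_spacing)
  expect_equal(warp(img, z)$channels$value, img$channels$value,
               tolerance = 1e-12)

  # impulse shifted by exactly one voxel pitch along axis 2:
  # output(x) = input(x + t) moves the bright voxel one step down-index
  imp <- array(0, shp); imp[6, 6, 6] <- 1
  t <- c(0, test_spacing[2], 0)
  w <- warp(image_volume(list(v = imp), test_spacing),
            constant_field(shp, t))
  expect_equal(w$channels$v[6, 5, 6], 1)
  expect_equal(sum(w$channels$v), 1)

  # labels: nearest neighbour invents no labels, linear is refused
  set.seed(7)
  lab <- label_volume(array(sample(0:3, prod(shp), TRUE), shp), test_spacing)
  g <- make_diffeomorphism(shp, test_spacing, magnitude_mm = 4,
                           min_jacobian = 0.4, seed = 2)
  wl <- warp(lab, g)
  expect_true(all(unique(as.vector(wl$labels)) %in%
                  unique(as.vector(lab$labels))))
  expect_error(warp(lab, g, interp = "linear"), "nearest")

  # zero field preserves the total count of every label exactly
  wl0 <- warp(lab, z)
  expect_identical(table(wl0$labels), table(lab$labels))
})

test_that("half-voxel resampling smooths without moving anatomy", {
  shp <- c(12, 12, 12)
  const <- image_volume(list(v = array(3.7, shp)), test_spacing)
  h <- halfvoxel_resample(const)
  expect_equal(h$channels$v, const$channels$v, tolerance = 1e-12)

  # binary step edge: linear interpolation puts 0.5 at the midpoint
  step <- array(0, shp); step[7:12, , ] <- 1
  hs <- halfvoxel_resample(image_volume(list(v = step), test_spacing))
  expect_true(any(abs(hs$channels$v - 0.5) < 1e-12))

  # two half-voxel shifts differ from one full-voxel shift only by
  # interpolation smoothing, bounded by the local intensity range
  set.seed(9)
  img <- image_volume(list(v = array(runif(prod(shp)), shp)), test_spacing)
  twice <- halfvoxel_resample(halfvoxel_resample(img))
  full <- warp(img, constant_field(shp, test_spacing), fill = 0)
  interior <- interior_mask(shp, 2)
  dmax <- max(abs(twice$channels$v - full$channels$v)[interior])
  expect_lte(dmax, diff(range(img$channels$v)))
})
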