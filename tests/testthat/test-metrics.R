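# Evaluation metrics: V transform, AAVC, AICE, MSE, MI, Dice, majority vote.

test_that("V transform weights compression and expansion symmetrically", {
  expect_equal(v_transform(1), 0)
  expect_equal(v_transform(2), 1)
  expect_equal(v_transform(0.5), -1)
  expect_equal(v_transform(0.25), -3)
  expect_error(v_transform(c(1, 0)), "positive")

  set.seed(3)
  J <- runif(200, 0.05, 20)
  expect_equal(abs(v_transform(J)), abs(v_transform(1 / J)),
               tolerance = 1e-12)
})

test_that("AAVC is the ROI mean of |V| and vanishes only at identity", {
  shp <- c(10, 10, 10)
  z <- zero_field(shp, test_spacing)
  expect_equal(aavc(z), 0)

  # jacobian_map input: uniform doubling gives AAVC 1
  J2 <- jacobian_map(array(2, shp), test_spacing)
  expect_equal(aavc(J2), 1)

  # mixed expansion/compression {2, 0.5}: mean of |1| and |-1| is 1
  roi <- array(FALSE, shp); roi[1, 1, 1] <- roi[2, 1, 1] <- TRUE
  Jm <- array(1, shp); Jm[1, 1, 1] <- 2; Jm[2, 1, 1] <- 0.5
  expect_equal(aavc(jacobian_map(Jm, test_spacing), roi), 1)

  expect_error(aavc(z, array(FALSE, shp)), "empty ROI")
  g <- make_diffeomorphism(shp, test_spacing, magnitude_mm = 4,
                           min_jacobian = 0.4, seed = 1)
  expect_gt(aavc(g), 0)
})

test_that("robust AAVC excludes MAD outliers and degrades gracefully", {
  # 99 voxels with |V| tightly spread around 0.1 plus one gross outlier
  # (J = 51): the outlier sits far beyond 2.5 MAD and is excluded
  J <- array(1, c(10, 10, 2))
  J[1:99] <- 1 + seq(0.095, 0.105, length.out = 99)
  J[100] <- 51
  roi <- array(c(rep(TRUE, 100), rep(FALSE, 100)), c(10, 10, 2))
  jm <- jacobian_map(J, c(1, 1, 1))
  expect_equal(robust_aavc(jm, roi, k = 2.5), 0.1, tolerance = 1e-3)
  expect_gt(aavc(jm, roi), 0.5)

  # uniform |V|: MAD = 0, nothing excluded
  Ju <- jacobian_map(array(1.3, c(10, 10, 2)), c(1, 1, 1))
  expect_equal(robust_aavc(Ju, roi), aavc(Ju, roi))

  # k -> infinity recovers the plain AAVC
  expect_equal(robust_aavc(jm, roi, k = Inf), aavc(jm, roi))
})

test_that("AICE of translations and of exact numerical inverses", {
  shp <- c(12, 12, 12)
  t <- c(2, -1, 4)
  f <- constant_field(shp, t)
  # same transform both ways: round trip is 2t
  expect_equal(aice(f, f), 2 * sqrt(sum(t^2)), tolerance = 1e-9)
  # true inverse: zero
  expect_equal(aice(f, constant_field(shp, -t)), 0, tolerance = 1e-9)

  # numerically exact inverse pair: the fixed-point inversion controls
  # || f o f^-1 - id ||, i.e. AICE with the inverse as the forward transform
  g <- make_diffeomorphism(shp, test_spacing, magnitude_mm = 5,
                           min_jacobian = 0.5, seed = 8)
  gi <- invert_field(g, tol = 0.05, max_iter = 100)
  expect_lte(aice(gi, g, interior_mask(shp, 2)), 0.05)
  # the other round trip carries interpolation error on top; still far
  # below the displacement scale
  expect_lte(aice(g, gi, interior_mask(shp, 2)), 0.5)
})

test_that("MSE matches an elementwise oracle", {
  shp <- c(8, 8, 8)
  set.seed(21)
  a <- array(runif(prod(shp)), shp)
  b <- array(runif(prod(shp)), shp)
  ia <- image_volume(list(v = a), test_spacing)
  ib <- image_volume(list(v = b), test_spacing)
  expect_equal(mse(ia, ia), 0)
  expect_equal(mse(ia, image_volume(list(v = a + 3), test_spacing)), 9,
               tolerance = 1e-12)

  roi <- array(FALSE, shp); roi[2:6, 3:5, 1:8] <- TRUE
  oracle <- 0; n <- 0
  for (i in 1:shp[1]) for (j in 1:shp[2]) for (k in 1:shp[3])
    if (roi[i, j, k]) {
      oracle <- oracle + (a[i, j, k] - b[i, j, k])^2
      n <- n + 1
    }
  expect_equal(mse(ia, ib, roi), oracle / n, tolerance = 1e-12)
})

test_that("mutual information: self-information, independence, bijection invariance", {
  shp <- c(48, 48, 48)   # ~1e5 ROI samples
  set.seed(31)
  x <- array(runif(prod(shp)), shp)
  y <- array(runif(prod(shp)), shp)
  ix <- image_volume(list(v = x), test_spacing)
  iy <- image_volume(list(v = y), test_spacing)

  # MI(X, X) equals the marginal histogram entropy
  mi_self <- mutual_information(ix, ix, bins = 64)
  h <- tabulate(pmin.int(floor((x - min(x)) / diff(range(x)) * 64) + 1L, 64L),
                nbins = 64L)
  p <- h / sum(h)
  expect_equal(mi_self, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-9)

  # independent noise: MI near zero once the finite-sample histogram bias
  # (about (bins - 1)^2 / 2n nats) is controlled by the bin count
  expect_lt(mutual_information(ix, iy, bins = 32), 0.05)

  # bin-aligned bijective remap (intensity inversion) preserves MI
  inv <- image_volume(list(v = max(x) + min(x) - x), test_spacing)
  expect_equal(mutual_information(ix, inv, bins = 64), mi_self,
               tolerance = 1e-9)

  # constant image: single occupied bin, MI defined as 0
  ic <- image_volume(list(v = array(1, shp)), test_spacing)
  expect_equal(mutual_information(ix, ic), 0)
})

test_that("Dice coefficient handles identity, disjoint and partial overlap", {
  shp <- c(10, 10, 10)
  a <- array(0L, shp); a[1:5, , 1] <- 1L
  la <- label_volume(a, test_spacing)
  expect_equal(dice(la, la, 1), 1)

  b <- array(0L, shp); b[6:10, , 1] <- 1L
  expect_equal(dice(la, label_volume(b, test_spacing), 1), 0)

  # |A| = |B| = 100, overlap 50
  a2 <- array(0L, shp); a2[1:10, 1:10, 1] <- 1L
  b2 <- array(0L, shp); b2[1:10, 1:10, 2] <- 1L
  b2[1:5, 1:10, 1] <- 1L; b2[1:5, 1:10, 2] <- 0L
  la2 <- label_volume(a2, test_spacing)
  lb2 <- label_volume(b2, test_spacing)
  expect_equal(sum(b2 == 1), 100)
  expect_equal(dice(la2, lb2, 1), 0.5)
  expect_equal(dice(la2, lb2, 1), dice(lb2, la2, 1))

  # both empty: defined as 1
  expect_equal(dice(la, la, 7), 1)
})

test_that("majority vote requires a strict majority, else background", {
  shp <- c(4, 4, 4)
  mk <- function(v) label_volume(array(v, shp), test_spacing)
  v1 <- array(0L, shp); v1[1, 1, 1] <- 5L; v1[2, 1, 1] <- 5L
  v2 <- array(0L, shp); v2[1, 1, 1] <- 5L; v2[2, 1, 1] <- 3L
  v3 <- array(0L, shp); v3[1, 1, 1] <- 3L
  # votes {5, 5, 3}: strict majority for 5
  out <- majority_vote(list(mk(v1), mk(v2), mk(v3)))
  expect_equal(out$labels[1, 1, 1], 5L)
  # votes {5, 3, 0}: no strict majority -> background
  expect_equal(out$labels[2, 1, 1], 0L)
  # elsewhere all-background stays background
  expect_equal(out$labels[4, 4, 4], 0L)

  # single input is returned unchanged
  single <- majority_vote(list(mk(v2)))
  expect_identical(single$labels, mk(v2)$labels)

  # permutation invariance
  out2 <- majority_vote(list(mk(v3), mk(v1), mk(v2)))
  expect_identical(out2$labels, out$labels)
})

test_that("per-subject evaluation assembles the metric row", {
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 5)
  ph <- make_phantom(spec)
  g <- make_diffeomorphism(spec$shape, spec$spacing, magnitude_mm = 4,
                           min_jacobian = 0.4, seed = 6)
  subj <- warp(ph$image, invert_field(g))
  roi <- channel(ph$image, "mask") > 0.5
  row <- evaluate_subject(ph$image, subj, g, roi = roi,
                          labels_ref = ph$labels,
                          labels_subject = warp(ph$labels, invert_field(g)),
                          subject_id = "A")
  expect_equal(row$subject_id, "A")
  expect_gt(row$aavc, 0)
  expect_true(is.finite(row$mse) && row$mse >= 0)
  expect_gt(row$mi, 0)
  expect_true(all(vapply(grep("^dice_", names(row)),
                         function(i) row[[i]] >= 0 && row[[i]] <= 1,
                         logical(1))))
})
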