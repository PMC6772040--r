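# Initial-reference selection, reference correction, iterated refinement.

test_that("initial reference selection: medians, exclusions, brute force", {
  cohort <- data.frame(subject_id = c("A", "B", "C"),
                       fat_mass = c(20, 25, 30),
                       height = c(160, 165, 170),
                       stringsAsFactors = FALSE)
  expect_equal(select_initial_reference(cohort), "B")
  # the exact-median subject is excluded: the next best wins
  expect_true(select_initial_reference(cohort, exclusions = "B") %in%
              c("A", "C"))
  expect_error(select_initial_reference(cohort,
                                        exclusions = c("A", "B", "C")),
               "eligible")

  # seeded random records against an exhaustive scoring loop
  set.seed(77)
  big <- data.frame(subject_id = sprintf("S%02d", 1:7),
                    fat_mass = round(runif(7, 15, 45), 1),
                    height = round(runif(7, 150, 190), 1),
                    stringsAsFactors = FALSE)
  mad1 <- function(x) {
    s <- median(abs(x - median(x)))
    if (s == 0) 1 else s
  }
  best <- NULL; best_score <- Inf
  for (i in seq_len(nrow(big))) {
    sc <- abs(big$fat_mass[i] - median(big$fat_mass)) / mad1(big$fat_mass) +
          abs(big$height[i] - median(big$height)) / mad1(big$height)
    if (sc < best_score) { best_score <- sc; best <- big$subject_id[i] }
  }
  expect_equal(select_initial_reference(big), best)
  # deterministic given the table
  expect_equal(select_initial_reference(big), select_initial_reference(big))
})

test_that("all-zero fields require no correction", {
  spec <- phantom_spec(shape = c(20, 20, 20), seed = 4)
  ph <- make_phantom(spec)
  zf <- lapply(1:3, function(i) zero_field(spec$shape, spec$spacing))
  cfg <- synthesis_config(mask = channel(ph$image, "mask") > 0.5)
  res <- build_reference(ph$image, zf, cfg)
  expect_lt(max(abs(res$d$vectors)), 1e-8)
  expect_equal(res$reference$channels$fat, ph$image$channels$fat,
               tolerance = 1e-6)
  for (f in res$composed_fields) expect_lt(max(abs(f$vectors)), 1e-6)
  expect_equal(mean(res$report$aavc_after), 0, tolerance = 1e-6)
})

test_that("single-subject correction absorbs the whole deformation", {
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 4)
  ph <- make_phantom(spec)
  mask <- channel(ph$image, "mask") > 0.5
  f <- make_diffeomorphism(spec$shape, spec$spacing, magnitude_mm = 5,
                           min_jacobian = 0.3, seed = 9)
  cfg <- synthesis_config(mask = mask)
  res <- suppressWarnings(build_reference(ph$image, list(f), cfg))
  # J[d] realizes the (clamped) Jacobian of the single field on the mask
  Jd <- jacobian_determinant(res$d)$values
  Jf <- pmax(jacobian_determinant(f)$values, cfg$epsilon)
  enf <- mask & !avref:::boundary_shell(spec$shape)
  expect_lt(max(abs(Jd - Jf)[enf]), 0.05)
  # the composed field's Jacobian is close to 1 there
  Jc <- jacobian_determinant(res$composed_fields[[1]])$values
  roi <- res$report$roi_after
  expect_lt(mean(abs(Jc - 1)[roi]), 0.05)
})

test_that("composed fields differ from the originals only through d", {
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 4)
  ph <- make_phantom(spec)
  fields <- lapply(1:3, function(s)
    make_diffeomorphism(spec$shape, spec$spacing, magnitude_mm = 5,
                        min_jacobian = 0.3, seed = s))
  cfg <- synthesis_config(mask = channel(ph$image, "mask") > 0.5)
  res <- build_reference(ph$image, fields, cfg)
  # compose(composed_j, d) recovers f_j up to interpolation + inversion error
  interior <- interior_mask(spec$shape, 2)
  for (j in seq_along(fields)) {
    back <- compose_fields(res$composed_fields[[j]], res$d)
    err <- sqrt((back$vectors[, , , 1] - fields[[j]]$vectors[, , , 1])^2 +
                (back$vectors[, , , 2] - fields[[j]]$vectors[, , , 2])^2 +
                (back$vectors[, , , 3] - fields[[j]]$vectors[, , , 3])^2)
    expect_lt(mean(err[interior]), 0.5)
  }
})

test_that("cohort round trip: geometric mean of composed Jacobians is 1", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 0)
  ph <- make_phantom(spec)
  mask <- channel(ph$image, "mask") > 0.5
  fields <- lapply(1:4, function(s)
    make_diffeomorphism(spec$shape, spec$spacing, magnitude_mm = 6,
                        min_jacobian = 0.25, seed = s))
  cfg <- synthesis_config(mask = mask)
  res <- build_reference(ph$image, fields, cfg)
  Js <- lapply(res$composed_fields,
               function(f) jacobian_determinant(f)$values)
  gm <- exp(Reduce(`+`, lapply(Js, function(j) log(pmax(j, 1e-6)))) /
            length(Js))
  roi <- res$report$roi_after
  expect_lt(max(abs(gm[roi] - 1)), 0.05)
  # equivalently: the mean log-Jacobian vanishes voxel-wise on the ROI
  expect_lt(max(abs(log(gm[roi]))), 0.06)
})

test_that("a single refinement iteration equals register-all plus build", {
  spec <- phantom_spec(shape = c(20, 20, 20), seed = 6)
  co <- make_cohort(spec, n_subjects = 2,
                    deform_params = list(magnitude_mm = 3,
                                         min_jacobian = 0.4), seed = 3)
  initial <- co$template$image
  images <- lapply(co$subjects, `[[`, "image")
  mask <- channel(initial, "mask") > 0.5
  rcfg <- registration_config(max_sweeps = 10)
  scfg <- synthesis_config(mask = mask, max_iter = 50)

  its <- suppressWarnings(
    iterate_reference(initial, images, rcfg, scfg, n_iters = 1))
  expect_length(its, 1)
  expect_length(attr(its, "aavc_trace"), 2)

  ref0 <- halfvoxel_resample(initial)
  fields <- lapply(images, function(im) register(ref0, im, rcfg))
  manual <- suppressWarnings(build_reference(ref0, fields, scfg))
  expect_equal(its[[1]]$d$vectors, manual$d$vectors, tolerance = 1e-10)
  expect_equal(its[[1]]$reference$channels$fat,
               manual$reference$channels$fat, tolerance = 1e-10)
})

test_that("iterated refinement resamples once from the initial reference", {
  spec <- phantom_spec(shape = c(20, 20, 20), seed = 6)
  co <- make_cohort(spec, n_subjects = 2,
                    deform_params = list(magnitude_mm = 3,
                                         min_jacobian = 0.4), seed = 3)
  initial <- co$template$image
  images <- lapply(co$subjects, `[[`, "image")
  rcfg <- registration_config(max_sweeps = 8)
  scfg <- synthesis_config(mask = channel(initial, "mask") > 0.5,
                           max_iter = 40)
  its <- suppressWarnings(
    iterate_reference(initial, images, rcfg, scfg, n_iters = 2))
  expect_length(attr(its, "aavc_trace"), 3)
  # structural check: the stored reference equals one single warp of the
  # half-voxel-resampled initial image through the accumulated deformation,
  # not a chain of warps of intermediate references
  ref0 <- halfvoxel_resample(initial)
  direct <- warp(ref0, its[[2]]$d_inv_accumulated)
  expect_equal(its[[2]]$reference$channels$fat, direct$channels$fat)
  chained <- warp(warp(ref0, its[[1]]$d_inv), its[[2]]$d_inv)
  expect_false(isTRUE(all.equal(chained$channels$fat,
                                direct$channels$fat, tolerance = 1e-12)))
})
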