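# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; physical spacing is anisotropic by default so spacing-normalized
# derivatives are actually exercised.

test_spacing <- c(2.07, 2.07, 8.0)

# seeded Gaussian-smoothed random displacement field (not necessarily
# fold-free; use make_diffeomorphism when a Jacobian bound is needed)
random_smooth_field <- function(shape, spacing = test_spacing,
                                amplitude = 2, sigma_vox = 2, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(shape) * 3), c(shape, 3))
  for (k in 1:3)
    v[, , , k] <- avref:::gauss_smooth(v[, , , k], rep(sigma_vox, 3))
  v <- v * (amplitude / max(abs(v)))
  displacement_field(v, spacing)
}

constant_field <- function(shape, t, spacing = test_spacing) {
  v <- array(0, c(shape, 3))
  for (k in 1:3) v[, , , k] <- t[k]
  displacement_field(v, spacing)
}

field_magnitude <- function(f) {
  sqrt(f$vectors[, , , 1]^2 + f$vectors[, , , 2]^2 + f$vectors[, , , 3]^2)
}

interior_mask <- function(shape, depth = 1) {
  m <- array(FALSE, shape)
  i <- lapply(shape, function(n) (1 + depth):(n - depth))
  m[i[[1]], i[[2]], i[[3]]] <- TRUE
  m
}

mean_field_error <- function(u, g, roi = NULL) {
  e <- sqrt((u$vectors[, , , 1] - g$vectors[, , , 1])^2 +
            (u$vectors[, , , 2] - g$vectors[, , , 2])^2 +
            (u$vectors[, , , 3] - g$vectors[, , , 3])^2)
  if (is.null(roi)) mean(e) else mean(e[roi])
}
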