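# Shared fixtures: a reference Gabor parameter set, quick synthesis configs,
# and a lazy cache for expensive population quantities reused across files.

ref_params <- function() {
  gabor_params(sigma = 6, theta = 0.7, wavelength = 10, phase = 1.2)
}

quick_config <- function(seed = 1, ...) {
  synthesis_config(seed = seed, mei_iters = 400, vei_iters = 600,
                   lambda_grid = c(1e-4, 2e-3, 5e-2), ...)
}

.acc_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- compute()
  .acc_cache[[key]]
}

# phase of the best-fitting grating for an image, by regression on a
# quadrature carrier pair
fitted_gabor_phase <- function(img, params, shape = default_shape(),
                               deg_per_pixel = 2) {
  p0 <- params; p0$phase <- 0
  p1 <- params; p1$phase <- pi / 2
  a <- sum(img * gabor_image(p0, shape, deg_per_pixel))
  b <- sum(img * gabor_image(p1, shape, deg_per_pixel))
  atan2(-b, a) %% (2 * pi)
}
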