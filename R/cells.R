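# Analytic model neurons: Gabor simple cells (rectified linear) and energy-
# model complex cells (quadrature pair), plus the generic differentiable
# neuron contract used by all synthesis code.

#' Gabor parameters
#'
#' @param mu_x,mu_y center in degrees (grid center is 0,0)
#' @param sigma Gaussian envelope s.d. in degrees
#' @param theta grating orientation in radians
#' @param wavelength grating period in degrees/cycle
#' @param phase grating phase in radians
#' @return object of class `gabor_params`
#' @export
gabor_params <- function(mu_x = 0, mu_y = 0, sigma, theta, wavelength, phase) {
  p <- list(mu_x = mu_x, mu_y = mu_y, sigma = sigma, theta = theta,
            wavelength = wavelength, phase = phase)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1))))
    stop("all Gabor parameters must be finite scalars")
  if (sigma <= 0 || wavelength <= 0) stop("sigma and wavelength must be positive")
  structure(p, class = "gabor_params")
}

#' Evaluate a Gabor image on the pixel grid
#'
#' Gaussian-windowed cosine grating: an isotropic Gaussian envelope centered
#' at (mu_x, mu_y) multiplying cos(2 pi (x cos theta + y sin theta) /
#' wavelength + phase), evaluated at pixel centers in degrees relative to the
#' grid center.
#'
#' @param params a [gabor_params()] object
#' @param shape c(rows, cols)
#' @param deg_per_pixel degrees per pixel
#' @return numeric matrix
#' @export
gabor_image <- function(params, shape = default_shape(), deg_per_pixel = 2) {
  stopifnot(inherits(params, "gabor_params"), deg_per_pixel > 0)
  g <- grid_coords_deg(shape, deg_per_pixel)
  env <- exp(-((g$x - params$mu_x)^2 + (g$y - params$mu_y)^2) /
               (2 * params$sigma^2))
  carrier <- cos(2 * pi * (g$x * cos(params$theta) + g$y * sin(params$theta)) /
                   params$wavelength + params$phase)
  env * carrier
}

#' Differentiable model-neuron contract
#'
#' Wraps a deterministic nonnegative response function and its gradient with
#' respect to image pixels. `eval_batch` takes an (npx x n) matrix of
#' vectorized images and returns `list(r = responses, G = gradients)`; a
#' default is derived from `respond`/`grad` when not supplied.
#'
#' @param respond function(image matrix) -> nonnegative scalar
#' @param grad function(image matrix) -> gradient matrix
#' @param shape grid c(rows, cols) the neuron operates on
#' @param rf_center c(row, col) receptive-field center in pixels
#' @param label free-text description
#' @param eval_batch optional vectorized evaluator (see above)
#' @return object of class `model_neuron`
#' @export
model_neuron <- function(respond, grad, shape = default_shape(),
                         rf_center = (shape + 1) / 2, label = "",
                         eval_batch = NULL) {
  stopifnot(is.function(respond), is.function(grad))
  if (is.null(eval_batch)) {
    eval_batch <- function(X) {
      n <- ncol(X)
      r <- numeric(n)
      G <- matrix(0, nrow(X), n)
      for (i in seq_len(n)) {
        img <- matrix(X[, i], shape[1], shape[2])
        r[i] <- respond(img)
        G[, i] <- as.vector(grad(img))
      }
      list(r = r, G = G)
    }
  }
  structure(list(respond = respond, grad = grad, shape = shape,
                 rf_center = rf_center, label = label,
                 eval_batch = eval_batch),
            class = "model_neuron")
}

#' @export
print.model_neuron <- function(x, ...) {
  cat("<model_neuron>", x$label, "\n")
  cat("  grid:", x$shape[1], "x", x$shape[2],
      " rf center: (", x$rf_center[1], ",", x$rf_center[2], ")\n")
  invisible(x)
}

# responses + gradients for a batch, any neuron
neuron_eval_batch <- function(model, X) model$eval_batch(X)

#' Responses of a neuron to a batch of images
#'
#' @param model a `model_neuron`
#' @param images list of matrices or an (npx x n) matrix
#' @return numeric vector of responses
#' @export
neuron_respond <- function(model, images) {
  X <- as_image_batch(images)
  model$eval_batch(X)$r
}

as_image_batch <- function(images) {
  if (is.list(images)) {
    X <- vapply(images, as.vector, numeric(length(images[[1]])))
    if (is.null(dim(X))) X <- matrix(X, ncol = length(images))
    X
  } else if (is.matrix(images)) {
    images
  } else stop("images must be a list of matrices or an (npx x n) matrix")
}

#' Rectified-linear Gabor simple cell
#'
#' Response is max(0, <image, G>) for a Gabor filter G; the subgradient is G
#' where the projection is positive and 0 elsewhere.
#'
#' @inheritParams gabor_image
#' @return a `model_neuron`
#' @export
simple_cell <- function(params, shape = default_shape(), deg_per_pixel = 2) {
  Fv <- as.vector(gabor_image(params, shape, deg_per_pixel))
  npx <- length(Fv)
  ctr <- rf_center_pixels(params, shape, deg_per_pixel)
  eval_batch <- function(X) {
    if (nrow(X) != npx) stop("image/filter shape mismatch")
    z <- as.vector(crossprod(Fv, X))
    pos <- z > 0
    r <- ifelse(pos, z, 0)
    G <- Fv %*% t(as.numeric(pos))
    list(r = r, G = G)
  }
  neuron <- model_neuron(
    respond = function(img) max(0, sum(img * Fv)),
    grad = function(img) matrix(Fv * as.numeric(sum(img * Fv) > 0),
                                shape[1], shape[2]),
    shape = shape, rf_center = ctr,
    label = sprintf("simple cell (sigma=%.2f, lambda=%.2f, theta=%.2f)",
                    params$sigma, params$wavelength, params$theta),
    eval_batch = eval_batch)
  neuron$params <- params
  neuron$deg_per_pixel <- deg_per_pixel
  neuron$kind <- "simple"
  neuron$eval_batch_r <- function(X) {
    z <- as.vector(crossprod(Fv, X))
    ifelse(z > 0, z, 0)
  }
  neuron
}

#' Energy-model complex cell
#'
#' Response is sqrt(a^2 + b^2) where a and b are the image's inner products
#' with a quadrature pair of Gabor filters (phase and phase + pi/2); the
#' gradient is (a G1 + b G2) / response.
#'
#' @inheritParams gabor_image
#' @return a `model_neuron`
#' @export
complex_cell <- function(params, shape = default_shape(), deg_per_pixel = 2) {
  p2 <- params; p2$phase <- params$phase + pi / 2
  F1 <- as.vector(gabor_image(params, shape, deg_per_pixel))
  F2 <- as.vector(gabor_image(p2, shape, deg_per_pixel))
  Fq <- cbind(F1, F2)
  npx <- length(F1)
  ctr <- rf_center_pixels(params, shape, deg_per_pixel)
  eval_batch <- function(X) {
    if (nrow(X) != npx) stop("image/filter shape mismatch")
    AB <- crossprod(Fq, X)                     # 2 x n
    r <- sqrt(colSums(AB^2))
    w <- sweep(AB, 2, pmax(r, 1e-12), `/`)
    list(r = r, G = Fq %*% w)
  }
  neuron <- model_neuron(
    respond = function(img) {
      v <- as.vector(img)
      sqrt(sum(v * F1)^2 + sum(v * F2)^2)
    },
    grad = function(img) {
      v <- as.vector(img)
      a <- sum(v * F1); b <- sum(v * F2)
      r <- max(sqrt(a^2 + b^2), 1e-12)
      matrix((a * F1 + b * F2) / r, shape[1], shape[2])
    },
    shape = shape, rf_center = ctr,
    label = sprintf("complex cell (sigma=%.2f, lambda=%.2f, theta=%.2f)",
                    params$sigma, params$wavelength, params$theta),
    eval_batch = eval_batch)
  neuron$params <- params
  neuron$deg_per_pixel <- deg_per_pixel
  neuron$kind <- "complex"
  neuron$eval_batch_r <- function(X) sqrt(colSums(crossprod(Fq, X)^2))
  neuron
}

rf_center_pixels <- function(params, shape, deg_per_pixel) {
  c(params$mu_y / deg_per_pixel + (shape[1] + 1) / 2,
    params$mu_x / deg_per_pixel + (shape[2] + 1) / 2)
}

#' Sample a population of Gabor cell parameters
#'
#' Orientation and phase are uniform; the envelope s.d. is uniform on
#' `sigma_range` (degrees); the wavelength is uniform on `[sigma, 2 sigma]`,
#' which respects the constraint that the period be at most twice the
#' envelope s.d. Centers are at the grid center.
#'
#' @param n number of cells
#' @param sigma_range envelope s.d. range in degrees
#' @param seed RNG seed (mandatory)
#' @return list of `gabor_params`
#' @export
sample_gabor_population <- function(n, sigma_range = c(4.4, 10.9), seed) {
  stopifnot(n >= 1)
  withr_seed(seed)
  lapply(seq_len(n), function(i) {
    sigma <- stats::runif(1, sigma_range[1], sigma_range[2])
    gabor_params(sigma = sigma,
                 theta = stats::runif(1, 0, pi),
                 wavelength = stats::runif(1, sigma, 2 * sigma),
                 phase = stats::runif(1, 0, 2 * pi))
  })
}

# local seed helper: sets the seed without clobbering the caller's RNG stream
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Poisson response sampling
#'
#' Draws spike-count-like responses with mean `gain * respond(image)` for
#' each image and repeat; reproducible under `seed`.
#'
#' @param model a `model_neuron`
#' @param images list of matrices or (npx x n) matrix
#' @param gain positive rate multiplier
#' @param seed RNG seed (mandatory)
#' @param n_repeats repeats per image (columns of the result)
#' @return integer matrix, n_images x n_repeats
#' @export
sample_poisson_responses <- function(model, images, gain = 10, seed,
                                     n_repeats = 1) {
  stopifnot(gain > 0, n_repeats >= 1)
  mu <- gain * neuron_respond(model, images)
  withr_seed(seed)
  matrix(stats::rpois(length(mu) * n_repeats, rep(mu, n_repeats)),
         nrow = length(mu), ncol = n_repeats)
}
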