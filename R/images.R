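# Grid convention used everywhere: images are numeric matrices, row 1 at the
# top, default 36 rows x 64 columns; `deg_per_pixel` converts pixel spacing to
# degrees of visual angle (default 2). Coordinates are measured in degrees
# relative to the grid center.

#' Default stimulus grid
#' @return integer vector c(rows, cols)
#' @export
default_shape <- function() c(36L, 64L)

#' Pixel-center coordinates in degrees
#'
#' @param shape c(rows, cols)
#' @param deg_per_pixel degrees of visual angle per pixel
#' @return list with matrices `x` and `y` (degrees, zero at the grid center)
#' @export
grid_coords_deg <- function(shape = default_shape(), deg_per_pixel = 2) {
  stopifnot(length(shape) == 2, all(shape >= 1), deg_per_pixel > 0)
  rows <- shape[1]; cols <- shape[2]
  xs <- (seq_len(cols) - (cols + 1) / 2) * deg_per_pixel
  ys <- (seq_len(rows) - (rows + 1) / 2) * deg_per_pixel
  list(x = matrix(xs, rows, cols, byrow = TRUE),
       y = matrix(ys, rows, cols))
}

#' Standardize an image to a fixed mean and RMS contrast
#'
#' Centers and rescales so that, before clipping, the image has the target
#' mean and root-mean-square contrast (population RMS about the mean).
#' Clipping, when requested, is applied last.
#'
#' @param image numeric matrix (or vector)
#' @param mean_target target mean (default 0)
#' @param rms_target target RMS contrast (default 0.25)
#' @param clip NULL for no clipping, else c(lo, hi)
#' @return standardized image, same shape
#' @export
standardize <- function(image, mean_target = 0, rms_target = 0.25, clip = NULL) {
  if (!all(is.finite(image))) stop("image must be finite")
  mu <- mean(image)
  rms <- sqrt(mean((image - mu)^2))
  if (rms < .Machine$double.eps * 1e3)
    stop("zero-variance input: RMS contrast target unreachable")
  out <- (image - mu) * (rms_target / rms) + mean_target
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2, clip[1] < clip[2])
    out[out < clip[1]] <- clip[1]
    out[out > clip[2]] <- clip[2]
  }
  out
}

# Row-normalized banded Gaussian smoothing operator of size n.  Applying it on
# the left smooths columns; edge rows renormalize the truncated kernel, which
# avoids darkening at borders.
blur_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- k[ok]
  }
  B / rowSums(B)
}

# cache of blur operators keyed by "n:sigma"
.blur_cache <- new.env(parent = emptyenv())

blur_op_cached <- function(n, sigma) {
  key <- paste0(n, ":", signif(sigma, 8))
  op <- .blur_cache[[key]]
  if (is.null(op)) {
    op <- blur_operator(n, sigma)
    .blur_cache[[key]] <- op
  }
  op
}

#' Gaussian-blur an image
#'
#' Separable Gaussian smoothing with a truncated (3 sigma), edge-renormalized
#' kernel, used to smooth synthesis gradients and mask edges.
#'
#' @param image numeric matrix
#' @param sigma kernel standard deviation in pixels; 0 returns the input
#' @return blurred matrix
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  Br <- blur_op_cached(nrow(image), sigma)
  Bc <- blur_op_cached(ncol(image), sigma)
  Br %*% image %*% t(Bc)
}

# Blur a batch stored as an (npx x n) matrix of vectorized column-major
# images. Separable passes as dense matmuls: the whole batch viewed as
# images side by side for the row pass, then one small matmul per image for
# the column pass.
blur_batch <- function(X, shape, sigma) {
  if (sigma <= 0) return(X)
  rows <- shape[1]; cols <- shape[2]; n <- ncol(X)
  Br <- blur_op_cached(rows, sigma)
  tBc <- t(blur_op_cached(cols, sigma))
  M <- Br %*% matrix(X, rows, cols * n)
  for (k in seq_len(n)) {
    idx <- ((k - 1) * cols + 1):(k * cols)
    M[, idx] <- M[, idx] %*% tBc
  }
  dim(M) <- c(rows * cols, n)
  M
}

# Standardize each column of an (npx x n) batch; clip last.
standardize_batch <- function(X, mean_target = 0, rms_target = 0.25, clip = NULL) {
  npx <- nrow(X); n <- ncol(X)
  mu <- .colMeans(X, npx, n)
  msq <- .colSums(X * X, npx, n) / npx
  rms <- sqrt(pmax(msq - mu^2, 0))
  rms[rms < 1e-150] <- 1
  f <- rms_target / rms
  X2 <- X * rep(f, each = npx) + rep(mean_target - mu * f, each = npx)
  if (!is.null(clip)) X2 <- pmin(pmax(X2, clip[1]), clip[2])
  X2
}

#' Masked Euclidean distance between two images
#'
#' Pixel-space Euclidean distance restricted to a receptive-field mask: the
#' pixelwise difference is weighted by the mask values before taking the
#' 2-norm. With a binary mask this is the distance within the mask support.
#'
#' @param a,b numeric matrices on the same grid
#' @param mask weighted mask in `[0, 1]` (NULL for the full field)
#' @return nonnegative scalar
#' @export
masked_distance <- function(a, b, mask = NULL) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(a))
    d <- d * mask
  }
  sqrt(sum(d^2))
}

#' Radial power spectrum of an image
#'
#' Computes the 2D power spectrum (DC removed) and averages it into
#' `n_bins` equally spaced radial frequency bins up to the Nyquist frequency.
#'
#' @param image numeric matrix
#' @param deg_per_pixel degrees per pixel
#' @param n_bins number of radial bins (default 10)
#' @return list with `freq` (bin centers, cycles/degree) and `power`
#' @export
radial_power_spectrum <- function(image, deg_per_pixel = 2, n_bins = 10) {
  if (all(image == 0)) stop("all-zero image: power spectrum undefined")
  rows <- nrow(image); cols <- ncol(image)
  P <- Mod(stats::fft(image - mean(image)))^2
  fr <- ifelse(seq_len(rows) - 1 <= rows / 2, seq_len(rows) - 1,
               seq_len(rows) - 1 - rows) / (rows * deg_per_pixel)
  fc <- ifelse(seq_len(cols) - 1 <= cols / 2, seq_len(cols) - 1,
               seq_len(cols) - 1 - cols) / (cols * deg_per_pixel)
  FR <- matrix(fr, rows, cols)
  FC <- matrix(fc, rows, cols, byrow = TRUE)
  f <- sqrt(FR^2 + FC^2)
  nyq <- 1 / (2 * deg_per_pixel)
  edges <- seq(0, nyq, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(f, edges, rightmost.closed = TRUE), 1L), n_bins)
  keep <- f > 0 & f <= nyq
  pow <- vapply(seq_len(n_bins), function(b) {
    v <- P[keep & bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  list(freq = (edges[-1] + edges[-(n_bins + 1)]) / 2, power = pow)
}

#' Median frequency of a radial power spectrum
#'
#' Linear interpolation of the cumulative binned power at half the total.
#'
#' @param spec list as returned by [radial_power_spectrum()]
#' @return median frequency in cycles/degree
#' @export
median_frequency <- function(spec) {
  p <- spec$power
  if (sum(p) <= 0) stop("zero total power")
  cs <- cumsum(p) / sum(p)
  f <- spec$freq
  i <- which(cs >= 0.5)[1]
  if (i == 1) {
    lo_f <- 0; lo_c <- 0
  } else {
    lo_f <- f[i - 1]; lo_c <- cs[i - 1]
  }
  lo_f + (0.5 - lo_c) / (cs[i] - lo_c) * (f[i] - lo_f)
}
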