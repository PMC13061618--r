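# Gradient-based stimulus synthesis: most exciting inputs (MEIs), varied
# exciting inputs (VEIs) under the activation-floor / max-min-diversity loss,
# distance-matched synthesized controls, and the receptive-field mask
# extracted from an MEI.

#' Synthesis configuration
#'
#' Defaults follow the reference synthesis protocol: 1,000 MEI ascent steps at
#' learning rate 1.0 with sigma = 1.0 gradient blurring; 3,000 VEI steps at
#' learning rate 1,000 decayed to 100 for the final third; activation floor
#' c = 0.85; diversity weights log-spaced on [1e-4, 5e-2]; images standardized
#' to mean 0 / RMS contrast 0.25 after every step, then clipped.
#'
#' @param c activation floor as a fraction of the MEI response
#' @param lambda_grid strictly increasing diversity-regularizer weights
#' @param mei_iters,mei_lr MEI ascent steps and learning rate
#' @param vei_iters VEI descent steps
#' @param vei_lr c(early, late) learning rates; the late rate applies to the
#'   final third of the steps
#' @param grad_blur_sigma Gaussian sigma (pixels) for gradient smoothing
#' @param std_mean,std_rms standardization targets
#' @param clip c(lo, hi) clip bounds applied after standardization; the
#'   default (+/- 8 RMS units) clips under 1% of pixels on standardized 1/f
#'   imagery and leaves Gabor-like optima essentially unsaturated
#' @param n_veis number of VEIs per set
#' @param init_noise_sd s.d. of the Gaussian noise added to the MEI when
#'   initializing VEIs (standardized units)
#' @param floor_margin safety margin above `c` at which the activation term
#'   engages during optimization (selection still requires only `c`);
#'   keeps the optimization steady state at the floor instead of a hair
#'   below it
#' @param seed RNG seed (mandatory for synthesis calls)
#' @return list of class `synthesis_config`
#' @export
synthesis_config <- function(c = 0.85,
                             lambda_grid = 10^seq(log10(1e-4), log10(5e-2),
                                                  length.out = 8),
                             mei_iters = 1000, mei_lr = 1.0,
                             vei_iters = 3000, vei_lr = c(1000, 100),
                             grad_blur_sigma = 1.0,
                             std_mean = 0, std_rms = 0.25,
                             clip = c(-2, 2),
                             n_veis = 20, init_noise_sd = 0.05,
                             floor_margin = 0.02,
                             seed = NULL) {
  stopifnot(c > 0, c < 1, all(diff(lambda_grid) > 0), n_veis >= 2,
            mei_iters >= 1, vei_iters >= 1)
  structure(list(c = c, lambda_grid = lambda_grid, mei_iters = mei_iters,
                 mei_lr = mei_lr, vei_iters = vei_iters, vei_lr = vei_lr,
                 grad_blur_sigma = grad_blur_sigma, std_mean = std_mean,
                 std_rms = std_rms, clip = clip, n_veis = n_veis,
                 floor_margin = floor_margin,
                 init_noise_sd = init_noise_sd, seed = seed),
            class = "synthesis_config")
}

#' Synthesize the most exciting input (MEI) of a model neuron
#'
#' Gradient ascent from Gaussian white noise: at every step the response
#' gradient is Gaussian-blurred, added with the configured learning rate, and
#' the image re-standardized (then clipped). If the gradient vanishes at
#' initialization (e.g. a rectified cell below threshold), the start is
#' redrawn.
#'
#' @param model a `model_neuron`
#' @param config a [synthesis_config()]; `config$seed` must be set
#' @param n_starts independent restarts; the highest-activation result is
#'   kept (useful for models with rugged response landscapes)
#' @return object of class `mei`: image, activation, weighted mask
#' @export
synthesize_mei <- function(model, config = synthesis_config(seed = 1),
                           n_starts = 1) {
  if (is.null(config$seed)) stop("config$seed is required")
  shape <- model$shape
  npx <- prod(shape)
  withr_seed(config$seed)
  best_img <- NULL
  best_act <- -Inf
  for (start in seq_len(n_starts)) {
    x <- NULL
    for (try in 1:20) {
      x0 <- standardize(matrix(stats::rnorm(npx), shape[1], shape[2]),
                        config$std_mean, config$std_rms, config$clip)
      g0 <- model$eval_batch(matrix(as.vector(x0)))$G
      if (any(g0 != 0)) { x <- as.vector(x0); break }
    }
    if (is.null(x)) stop("gradient vanished at every initialization")
    X <- matrix(x, ncol = 1)
    for (it in seq_len(config$mei_iters)) {
      ev <- model$eval_batch(X)
      if (!all(is.finite(ev$G))) stop("non-finite gradient during MEI synthesis")
      X <- X + config$mei_lr * blur_batch(ev$G, shape, config$grad_blur_sigma)
      X <- standardize_batch(X, config$std_mean, config$std_rms, config$clip)
    }
    act <- model$eval_batch(X)$r[1]
    if (act > best_act) {
      best_act <- act
      best_img <- matrix(X[, 1], shape[1], shape[2])
    }
  }
  structure(list(image = best_img, activation = best_act,
                 mask = extract_mei_mask(best_img),
                 label = model$label, config = config),
            class = "mei")
}

#' @export
print.mei <- function(x, ...) {
  cat("<mei>", x$label, "\n  activation:", signif(x$activation, 4),
      " mask area:", sum(x$mask > 0.3), "px (>0.3)\n")
  invisible(x)
}

#' @export
plot.mei <- function(x, ...) {
  graphics::image(t(x$image)[, nrow(x$image):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(x$image) / ncol(x$image), ...)
  invisible(x)
}

#' Weighted receptive-field mask of an MEI
#'
#' Pipeline: pixel-wise z-score, threshold `|z| > z_threshold`, binary
#' closing, largest connected component, filled convex hull, Gaussian
#' smoothing (sigma = 1.5). Output values lie in `[0, 1]`.
#'
#' @param mei_image MEI image matrix
#' @param z_threshold z-score threshold (default 1.5)
#' @param smooth_sigma smoothing sigma in pixels (default 1.5)
#' @return weighted mask matrix in `[0, 1]`
#' @export
extract_mei_mask <- function(mei_image, z_threshold = 1.5, smooth_sigma = 1.5) {
  z <- (mei_image - mean(mei_image)) / stats::sd(mei_image)
  B <- abs(z) > z_threshold
  if (!any(B)) stop("no RF found: no pixel exceeds the z-score threshold")
  Bc <- EBImage::closing(EBImage::Image(B * 1), EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(Bc)
  labm <- as.matrix(EBImage::imageData(lab))
  if (max(labm) < 1) labm <- B * 1
  counts <- tabulate(labm[labm > 0])
  keep <- which(labm == which.max(counts), arr.ind = TRUE)
  hull_mask <- fill_convex_hull(keep, dim(mei_image))
  gaussian_blur(hull_mask, smooth_sigma)
}

# Fill the convex hull of pixel coordinates (row, col) on a grid; returns a
# 0/1 matrix. Degenerate hulls (< 3 points) fall back to the points alone.
fill_convex_hull <- function(coords, shape) {
  out <- matrix(0, shape[1], shape[2])
  if (nrow(coords) < 3) {
    out[coords] <- 1
    return(out)
  }
  h <- grDevices::chull(coords[, 2], coords[, 1])     # x = col, y = row
  hx <- coords[h, 2]; hy <- coords[h, 1]
  if (length(h) < 3) { out[coords] <- 1; return(out) }
  px <- rep(seq_len(shape[2]), each = shape[1])
  py <- rep(seq_len(shape[1]), times = shape[2])
  n <- length(hx)
  # orientation-safe half-plane test: signed area fixes the winding
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  s <- if (area2 > 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (s * cross >= -1e-9)
  }
  out[cbind(py[inside], px[inside])] <- 1
  out
}

# Pairwise masked Euclidean distances for a batch (npx x n); returns the
# n x n distance matrix.
pairwise_masked_distances <- function(X, mask = NULL) {
  Y <- if (is.null(mask)) X else X * as.vector(mask)
  G <- crossprod(Y)
  sq <- diag(G)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# One VEI optimization run at a fixed lambda. X is modified in place style.
vei_run <- function(model, mei, lambda, config) {
  shape <- model$shape
  npx <- prod(shape)
  n <- config$n_veis
  r_mei <- mei$activation
  maskv <- as.vector(mei$mask)
  X <- as.vector(mei$image) + matrix(stats::rnorm(npx * n, sd = config$init_noise_sd),
                                     npx, n)
  X <- standardize_batch(X, config$std_mean, config$std_rms, config$clip)
  switch_at <- floor(2 / 3 * config$vei_iters)
  # the one-sided hinge equilibrates just below the floor under a constant
  # diversity push; engaging it within a small safety margin above the floor
  # moves the steady state to the floor itself (selection still uses c)
  margin <- if (is.null(config$floor_margin)) 0.02 else config$floor_margin
  for (it in seq_len(config$vei_iters)) {
    lr <- if (it <= switch_at) config$vei_lr[1] else config$vei_lr[2]
    ev <- model$eval_batch(X)
    ratio <- ev$r / r_mei
    # activation-floor term
    act <- ratio < config$c + margin
    Gtot <- ev$G * rep(-as.numeric(act) / (n * r_mei), each = npx)
    # max-min diversity term: gradient flows through the closest pair only
    Y <- X * maskv
    D <- pairwise_masked_distances_from_masked(Y)
    diag(D) <- Inf
    ij <- arrayInd(which.min(D), dim(D))
    i <- ij[1]; j <- ij[2]
    dmin <- max(D[i, j], 1e-9)
    gpair <- maskv^2 * (X[, i] - X[, j]) / dmin
    Gtot[, i] <- Gtot[, i] - lambda * gpair
    Gtot[, j] <- Gtot[, j] + lambda * gpair
    X <- X - lr * blur_batch(Gtot, shape, config$grad_blur_sigma)
    X <- standardize_batch(X, config$std_mean, config$std_rms, config$clip)
  }
  ev <- model$eval_batch(X)
  D <- pairwise_masked_distances(X, maskv)
  ut <- D[upper.tri(D)]
  list(images = X, activations = ev$r, ratios = ev$r / r_mei,
       min_d = min(ut), mean_d = mean(ut))
}

pairwise_masked_distances_from_masked <- function(Y) {
  G <- crossprod(Y)
  sq <- diag(G)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

#' Synthesize varied exciting inputs (VEIs)
#'
#' Starting from noisy copies of the MEI, jointly minimizes the mean
#' activation-floor hinge `max(c - r_i / r_MEI, 0)` minus `lambda` times the
#' minimum pairwise masked distance, with blurred gradients, a decayed
#' learning rate and per-step standardization. The set returned is the one
#' optimized with the largest `lambda` whose minimum activation ratio still
#' meets the floor; if no `lambda` qualifies, the smallest-`lambda` set is
#' returned with `violated = TRUE`.
#'
#' @param model a `model_neuron`
#' @param mei an `mei` for the same neuron
#' @param config a [synthesis_config()] with `seed`
#' @param sweep "descend" stops at the first (largest) qualifying lambda;
#'   "full" optimizes every lambda and also returns the whole trade-off table
#' @return object of class `vei_set`
#' @export
synthesize_veis <- function(model, mei, config = synthesis_config(seed = 1),
                            sweep = c("descend", "full")) {
  sweep <- match.arg(sweep)
  if (is.null(config$seed)) stop("config$seed is required")
  lambdas <- sort(config$lambda_grid, decreasing = TRUE)
  runs <- list()
  selected <- NULL
  for (k in seq_along(lambdas)) {
    withr_seed(config$seed + 1000 * k)
    run <- vei_run(model, mei, lambdas[k], config)
    run$lambda <- lambdas[k]
    runs[[k]] <- run
    if (is.null(selected) && min(run$ratios) >= config$c) selected <- k
    if (sweep == "descend" && !is.null(selected)) break
  }
  violated <- is.null(selected)
  if (violated) selected <- length(runs)   # smallest lambda attempted
  sel <- runs[[selected]]
  trade <- data.frame(
    lambda = vapply(runs, `[[`, numeric(1), "lambda"),
    min_ratio = vapply(runs, function(r) min(r$ratios), numeric(1)),
    mean_distance = vapply(runs, `[[`, numeric(1), "mean_d"),
    min_distance = vapply(runs, `[[`, numeric(1), "min_d"))
  structure(list(images = sel$images, shape = model$shape,
                 activations = sel$activations, ratios = sel$ratios,
                 lambda_used = sel$lambda,
                 min_pairwise_distance = sel$min_d,
                 mean_pairwise_distance = sel$mean_d,
                 activation_floor = config$c, violated = violated,
                 mask = mei$mask, trade_off = trade),
            class = "vei_set")
}

#' @export
print.vei_set <- function(x, ...) {
  cat("<vei_set>", ncol(x$images), "images, lambda =", signif(x$lambda_used, 3),
      "\n  min activation ratio:", signif(min(x$ratios), 3),
      if (x$violated) "(floor violated)" else "",
      "\n  pairwise masked distance: min", signif(x$min_pairwise_distance, 4),
      "mean", signif(x$mean_pairwise_distance, 4), "\n")
  invisible(x)
}

#' Distance-matched synthesized controls
#'
#' Optimizes `n` images whose masked distance to the MEI matches the distance
#' budget `d_target` (the minimum VEI-to-MEI distance) while maximizing their
#' mutual minimum distance; a final radial projection enforces that every
#' control lies at most `d_target` from the MEI.
#'
#' @param model a `model_neuron`
#' @param mei an `mei`
#' @param veis the neuron's `vei_set`
#' @param config a [synthesis_config()] with `seed`
#' @param lambda diversity weight (default the VEI set's selected lambda)
#' @return list: images (npx x n), distances to MEI, d_target, activations
#' @export
synthesize_distance_controls <- function(model, mei, veis,
                                         config = synthesis_config(seed = 1),
                                         lambda = veis$lambda_used) {
  if (is.null(config$seed)) stop("config$seed is required")
  shape <- model$shape
  npx <- prod(shape)
  n <- config$n_veis
  maskv <- as.vector(mei$mask)
  meiv <- as.vector(mei$image)
  d_target <- min(apply(veis$images, 2, function(v)
    masked_distance(v, meiv, maskv)))
  if (d_target < 1e-6) stop("degenerate VEIs: zero distance budget")
  withr_seed(config$seed)
  X <- meiv + matrix(stats::rnorm(npx * n, sd = config$init_noise_sd), npx, n)
  X <- standardize_batch(X, config$std_mean, config$std_rms, config$clip)
  switch_at <- floor(2 / 3 * config$vei_iters)
  for (it in seq_len(config$vei_iters)) {
    lr <- if (it <= switch_at) config$vei_lr[1] else config$vei_lr[2]
    dif <- (X - meiv) * maskv
    d <- sqrt(colSums(dif^2))
    # distance-matching term |d_target - d|: subgradient w.r.t. X
    sgn <- sign(d_target - d)
    Gtot <- dif * maskv * rep(-sgn / (n * pmax(d, 1e-9)), each = npx)
    Y <- X * maskv
    D <- pairwise_masked_distances_from_masked(Y)
    diag(D) <- Inf
    ij <- arrayInd(which.min(D), dim(D))
    i <- ij[1]; j <- ij[2]
    dmin <- max(D[i, j], 1e-9)
    gpair <- maskv^2 * (X[, i] - X[, j]) / dmin
    Gtot[, i] <- Gtot[, i] - lambda * gpair
    Gtot[, j] <- Gtot[, j] + lambda * gpair
    X <- X - lr * blur_batch(Gtot, shape, config$grad_blur_sigma)
    X <- standardize_batch(X, config$std_mean, config$std_rms, config$clip)
  }
  # final projection: pull any control outside the budget radially toward MEI
  dif <- (X - meiv)
  dmask <- sqrt(colSums((dif * maskv)^2))
  over <- dmask > d_target
  if (any(over)) {
    scl <- d_target / dmask[over]
    X[, over] <- meiv + sweep(dif[, over, drop = FALSE], 2, scl, `*`)
  }
  d_final <- apply(X, 2, function(v) masked_distance(v, meiv, maskv))
  list(images = X, distances = d_final, d_target = d_target,
       activations = model$eval_batch(X)$r)
}

#' Natural-image controls matched to the VEI distance budget
#'
#' @param crop_pool list of image matrices or (npx x n) matrix, already
#'   standardized to the MEI statistics
#' @param mei an `mei`
#' @param d_target distance budget (minimum VEI-to-MEI masked distance)
#' @param frac_range admissible band as fractions of `d_target`
#' @param k maximum number of controls returned
#' @return list: images (npx x m, m <= k), distances, indices into the pool
#' @export
sample_natural_controls <- function(crop_pool, mei, d_target,
                                    frac_range = c(0.8, 1.0), k = 20) {
  X <- as_image_batch(crop_pool)
  maskv <- as.vector(mei$mask)
  meiv <- as.vector(mei$image)
  d <- sqrt(colSums(((X - meiv) * maskv)^2))
  ok <- which(d >= frac_range[1] * d_target & d <= frac_range[2] * d_target)
  if (!length(ok))
    warning("no crops within the distance band")
  take <- utils::head(ok, k)
  list(images = X[, take, drop = FALSE], distances = d[take], indices = take)
}

#' Distance between images in neuronal representational space
#'
#' Negative Pearson correlation between the model-predicted population
#' response vectors to the two images, after translating each image so the
#' target RF center lands on every neuron's RF center.
#'
#' @param population list of >= 3 `model_neuron`s
#' @param img_a,img_b image matrices
#' @param target_center c(row, col) reference RF center; defaults to the
#'   first neuron's center (alignment is the identity for co-centered cells)
#' @return scalar in `[-1, 1]`; `-1` for identical images
#' @export
neuronal_space_distance <- function(population, img_a, img_b,
                                    target_center = population[[1]]$rf_center) {
  stopifnot(length(population) >= 3)
  resp <- function(img) {
    vapply(population, function(nr) {
      sh <- round(nr$rf_center - target_center)
      nr$respond(shift_image(img, sh[1], sh[2]))
    }, numeric(1))
  }
  ra <- resp(img_a); rb <- resp(img_b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("zero-variance population response vector")
  -stats::cor(ra, rb)
}

#' Shift an image by whole pixels (zero padding)
#'
#' @param img matrix
#' @param dr,dc row/column shift (positive moves content down/right)
#' @return shifted matrix
#' @export
shift_image <- function(img, dr, dc) {
  out <- matrix(0, nrow(img), ncol(img))
  r_src <- seq_len(nrow(img)) - dr
  c_src <- seq_len(ncol(img)) - dc
  rok <- r_src >= 1 & r_src <= nrow(img)
  cok <- c_src >= 1 & c_src <= ncol(img)
  out[rok, cok] <- img[r_src[rok], c_src[cok]]
  out
}
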