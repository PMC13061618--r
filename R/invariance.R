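# Diversity-index calibration and computation, representational similarity,
# and greedy natural-VEI selection.

#' Mean pairwise masked distance of a set of images
#'
#' @param images list of matrices or (npx x n) matrix, n >= 2
#' @param mask optional weighted mask
#' @return mean over unordered pairs of the masked Euclidean distance
#' @export
mean_pairwise_distance <- function(images, mask = NULL) {
  X <- as_image_batch(images)
  stopifnot(ncol(X) >= 2)
  D <- pairwise_masked_distances(X, if (is.null(mask)) NULL else as.vector(mask))
  mean(D[upper.tri(D)])
}

#' Greedy max-min subset selection
#'
#' Starting from `start`, repeatedly adds the candidate whose minimum masked
#' distance to the already-selected set is largest. Deterministic given the
#' start; ties resolved by lowest index.
#'
#' @param X (npx x n) candidate matrix
#' @param k subset size
#' @param mask optional weighted mask
#' @param start index of the seed element
#' @return integer vector of k selected column indices
#' @export
greedy_max_min_select <- function(X, k, mask = NULL, start = 1L) {
  n <- ncol(X)
  stopifnot(k >= 1, k <= n)
  Y <- if (is.null(mask)) X else X * as.vector(mask)
  chosen <- integer(k)
  chosen[1] <- start
  mind <- sqrt(colSums((Y - Y[, start])^2))
  mind[start] <- -Inf
  if (k > 1) for (s in 2:k) {
    nxt <- which.max(mind)
    chosen[s] <- nxt
    d_new <- sqrt(colSums((Y - Y[, nxt])^2))
    mind <- pmin(mind, d_new)
    mind[chosen[1:s]] <- -Inf
  }
  chosen
}

# Dense Gabor candidate bank centered on a cell's own parameters: full sweeps
# of orientation and phase, wavelengths and positions bracketing the optimum
# (scaled by sigma so the search is parameter-relative). Returns an
# (npx x n_candidates) matrix of standardized Gabor images.
gabor_candidate_bank <- function(params, shape, deg_per_pixel,
                                 n_theta = 16, n_phase = 16,
                                 n_wavelength = 5, n_position = 5,
                                 std_rms = 0.25) {
  g <- grid_coords_deg(shape, deg_per_pixel)
  xv <- as.vector(g$x); yv <- as.vector(g$y)
  thetas <- (params$theta + seq(0, pi, length.out = n_theta + 1)[-(n_theta + 1)]) %% pi
  phases <- (params$phase + seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)]) %% (2 * pi)
  wl <- params$wavelength * seq(0.75, 1.5, length.out = n_wavelength)
  wl <- pmin(wl, 2 * params$sigma)
  wl[which.min(abs(wl - params$wavelength))] <- params$wavelength
  wl <- unique(wl)
  off <- params$sigma / 3
  pos <- rbind(c(0, 0), c(off, 0), c(-off, 0), c(0, off), c(0, -off))
  pos <- pos[seq_len(min(n_position, nrow(pos))), , drop = FALSE]
  envs <- apply(pos, 1, function(p)
    exp(-((xv - params$mu_x - p[1])^2 + (yv - params$mu_y - p[2])^2) /
          (2 * params$sigma^2)))
  cols <- vector("list", length(thetas) * length(wl) * length(phases) * nrow(pos))
  idx <- 1L
  for (th in thetas) {
    proj <- xv * cos(th) + yv * sin(th)
    for (w in wl) {
      ph_base <- 2 * pi * proj / w
      for (ps in phases) {
        carrier <- cos(ph_base + ps)
        for (pi_ in seq_len(nrow(pos))) {
          cols[[idx]] <- envs[, pi_] * carrier
          idx <- idx + 1L
        }
      }
    }
  }
  X <- do.call(cbind, cols)
  standardize_batch(X, 0, std_rms)
}

# responses only (no gradients) for a batch, avoiding eval_batch's gradient
# allocation for large candidate banks
respond_batch_only <- function(model, X) {
  if (identical(model$kind, "simple") || identical(model$kind, "complex")) {
    return(model$eval_batch_r(X))
  }
  r <- numeric(ncol(X))
  step <- 256L
  for (s in seq(1, ncol(X), by = step)) {
    e <- min(s + step - 1L, ncol(X))
    r[s:e] <- model$eval_batch(X[, s:e, drop = FALSE])$r
  }
  r
}

# Exhaustive-search VEIs of one analytic cell: admissible standardized Gabors
# (response >= floor * max) greedily selected for max-min masked distance.
ideal_cell_veis <- function(model, params, shape, deg_per_pixel,
                            n_veis = 20, floor = 0.85, grid = list(),
                            max_admissible = 800L, mask = NULL) {
  gr <- utils::modifyList(list(n_theta = 16, n_phase = 16,
                               n_wavelength = 5, n_position = 5), grid)
  X <- gabor_candidate_bank(params, shape, deg_per_pixel,
                            gr$n_theta, gr$n_phase, gr$n_wavelength,
                            gr$n_position)
  r <- respond_batch_only(model, X)
  rmax <- max(r)
  adm <- which(r >= floor * rmax)
  if (length(adm) < n_veis)
    stop("Gabor grid too coarse: only ", length(adm),
         " admissible candidates; refine the grid")
  if (length(adm) > max_admissible)
    adm <- adm[order(r[adm], decreasing = TRUE)[seq_len(max_admissible)]]
  best <- adm[which.max(r[adm])]
  if (is.null(mask))
    mask <- extract_mei_mask(matrix(X[, best], shape[1], shape[2]))
  Xa <- X[, adm, drop = FALSE]
  sel <- greedy_max_min_select(Xa, n_veis, mask,
                               start = which.max(r[adm]))
  imgs <- Xa[, sel, drop = FALSE]
  list(images = imgs, mask = mask,
       mean_distance = mean_pairwise_distance(imgs, mask),
       activations = r[adm][sel], max_response = rmax)
}

#' Exhaustive-search VEIs of an analytic Gabor cell
#'
#' The ideal-cell analogue of VEI synthesis: candidate standardized Gabors
#' are enumerated on a dense parameter bank centered on the cell's own
#' parameters, those responding above `floor` of the maximum are admissible,
#' and `n_veis` of them are greedily selected to maximize the minimum
#' pairwise masked distance. For a simple cell the admissible set is a tight
#' phase/position jitter around the optimum; for a complex cell it includes
#' the full phase circle.
#'
#' @param model a `simple_cell()` or `complex_cell()` neuron
#' @param n_veis number of VEIs (default 20)
#' @param floor admissibility floor as a fraction of the maximum (0.85)
#' @param grid list overriding the bank resolution (n_theta, n_phase,
#'   n_wavelength, n_position)
#' @param mask optional weighted mask for distances; defaults to the mask of
#'   the best candidate
#' @return list: images (npx x n_veis), mask, mean_distance, activations,
#'   max_response
#' @export
exhaustive_gabor_veis <- function(model, n_veis = 20, floor = 0.85,
                                  grid = list(), mask = NULL) {
  stopifnot(inherits(model, "model_neuron"),
            model$kind %in% c("simple", "complex"))
  ideal_cell_veis(model, model$params, model$shape, model$deg_per_pixel,
                  n_veis = n_veis, floor = floor, grid = grid,
                  mask = mask)
}

#' Calibrate diversity-index bounds from noiseless ideal cells
#'
#' Samples `n_cells` simple and `n_cells` complex Gabor cells, finds each
#' cell's VEIs by exhaustive search over a dense Gabor bank (admissible above
#' 85% of the maximal response, greedy max-min selection of `n_veis`), and
#' sets `d_lower` / `d_upper` to the simple- and complex-population medians
#' of the mean pairwise masked distance.
#'
#' @param n_cells cells per population (default 60)
#' @param shape grid c(rows, cols)
#' @param deg_per_pixel degrees per pixel
#' @param seed RNG seed (mandatory)
#' @param n_veis VEIs per cell (default 20)
#' @param floor admissibility floor as a fraction of the maximum (0.85)
#' @param grid list overriding the candidate-bank resolution
#' @return object of class `diversity_calibration`: d_lower, d_upper and the
#'   per-cell distances of both populations
#' @export
calibrate_diversity_bounds <- function(n_cells = 60, shape = default_shape(),
                                       deg_per_pixel = 2, seed,
                                       n_veis = 20, floor = 0.85,
                                       grid = list()) {
  stopifnot(n_cells >= 2)
  pops <- list(
    simple = sample_gabor_population(n_cells, seed = seed),
    complex = sample_gabor_population(n_cells, seed = seed + 1))
  dist_of <- function(params, kind) {
    model <- if (kind == "simple") simple_cell(params, shape, deg_per_pixel)
             else complex_cell(params, shape, deg_per_pixel)
    ideal_cell_veis(model, params, shape, deg_per_pixel,
                    n_veis = n_veis, floor = floor, grid = grid)$mean_distance
  }
  ds <- vapply(pops$simple, dist_of, numeric(1), kind = "simple")
  dc <- vapply(pops$complex, dist_of, numeric(1), kind = "complex")
  d_lower <- stats::median(ds)
  d_upper <- stats::median(dc)
  if (d_upper <= d_lower) stop("calibration failed: d_upper <= d_lower")
  structure(list(d_lower = d_lower, d_upper = d_upper,
                 simple_distances = ds, complex_distances = dc,
                 seed = seed, n_cells = n_cells, n_veis = n_veis,
                 floor = floor),
            class = "diversity_calibration")
}

#' @export
print.diversity_calibration <- function(x, ...) {
  cat("<diversity_calibration> d_lower =", signif(x$d_lower, 4),
      " d_upper =", signif(x$d_upper, 4),
      " (", x$n_cells, "cells/population )\n")
  invisible(x)
}

#' Diversity index
#'
#' Affine normalization of a mean pairwise VEI distance between the
#' noiseless simple-cell (0) and complex-cell (1) calibration bounds. Values
#' outside `[0, 1]` are possible for real neurons.
#'
#' @param d mean pairwise masked distance (scalar or vector)
#' @param calib a [calibrate_diversity_bounds()] result
#' @return diversity index, same length as `d`
#' @export
diversity_index <- function(d, calib) {
  stopifnot(inherits(calib, "diversity_calibration"))
  if (calib$d_upper == calib$d_lower) stop("degenerate calibration bounds")
  (d - calib$d_lower) / (calib$d_upper - calib$d_lower)
}

population_response_matrix <- function(population, images) {
  X <- as_image_batch(images)
  R <- vapply(population, function(m) {
    if (inherits(m, "ensemble_twin")) stats::predict(m, X)
    else if (inherits(m, "model_neuron")) respond_batch_only(m, X)
    else stop("population members must be model_neuron or ensemble_twin")
  }, numeric(ncol(X)))
  if (is.null(dim(R))) R <- matrix(R, nrow = ncol(X))
  R                                  # n_images x n_neurons
}

#' Build a latent basis of population responses
#'
#' Predicts the population's responses to a standardized image library,
#' performs PCA, and retains the smallest number of components explaining at
#' least `var_threshold` of the response variance.
#'
#' @param population list of `model_neuron`s or `ensemble_twin`s
#' @param mei_library standardized images (list or npx x n matrix), n >= 2
#' @param var_threshold variance-explained cutoff (default 0.95)
#' @return object of class `latent_basis`
#' @export
build_latent_basis <- function(population, mei_library, var_threshold = 0.95) {
  X <- as_image_batch(mei_library)
  if (ncol(X) < 2) stop("need at least 2 library images")
  R <- population_response_matrix(population, X)
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ve) >= var_threshold - 1e-12)[1]
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, var_explained = ve, k = k,
                 population = population),
            class = "latent_basis")
}

#' @export
print.latent_basis <- function(x, ...) {
  cat("<latent_basis>", x$k, "components,",
      sprintf("%.1f%%", 100 * sum(x$var_explained[seq_len(x$k)])),
      "variance explained\n")
  invisible(x)
}

latent_project <- function(basis, images) {
  R <- population_response_matrix(basis$population, images)
  sweep(R, 2, basis$center) %*% basis$rotation   # n_images x k
}

#' Representational similarity between two image sets
#'
#' Mean over all (a, b) pairs of the cosine similarity between latent
#' projections of the population responses. Pairs with a zero-norm latent
#' vector are skipped (and counted in the `skipped` attribute).
#'
#' @param basis a [build_latent_basis()] result
#' @param images_a,images_b image sets (list or npx x n matrix)
#' @return scalar mean cosine similarity
#' @export
representational_similarity <- function(basis, images_a, images_b) {
  A <- latent_project(basis, images_a)
  B <- latent_project(basis, images_b)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  S <- (A %*% t(B)) / (na %*% t(nb))
  bad <- !is.finite(S)
  out <- mean(S[!bad])
  attr(out, "skipped") <- sum(bad)
  out
}

# Shrink a weighted mask by eroding its binarized support until the masked
# MEI's activation drops below `keep` of the original, returning the last
# mask above that level.
refine_mei_mask <- function(model, mei, keep = 0.95, support_threshold = 0.05) {
  m <- mei$mask
  r0 <- mei$activation
  sup <- m > support_threshold
  best <- m * sup
  kern <- EBImage::makeBrush(3, "box")
  repeat {
    sup_new <- as.matrix(EBImage::imageData(
      EBImage::erode(EBImage::Image(sup * 1), kern))) > 0.5
    if (!any(sup_new)) break
    cand <- m * sup_new
    act <- model$respond(mei$image * cand)
    if (act < keep * r0) break
    sup <- sup_new
    best <- cand
  }
  best
}

#' Select natural VEIs from a crop pool
#'
#' Crops are masked with the refined MEI mask (shrunk until the masked MEI's
#' activation falls below 95% of the original), matched in mean and RMS
#' contrast to the masked MEI, screened at `threshold` of the MEI response,
#' and greedily selected for maximum minimum pairwise distance starting from
#' the most-activating crop.
#'
#' @param crop_pool list of matrices or (npx x n) matrix
#' @param model the neuron's `model_neuron`
#' @param mei the neuron's `mei`
#' @param threshold activation floor as a fraction of the MEI response (0.85)
#' @param k number of natural VEIs requested (20)
#' @return list: images (npx x m), indices, activations, `flagged` (TRUE when
#'   fewer than `k` crops were admissible)
#' @export
select_natural_veis <- function(crop_pool, model, mei, threshold = 0.85,
                                k = 20) {
  X <- as_image_batch(crop_pool)
  rmask <- refine_mei_mask(model, mei)
  rv <- as.vector(rmask)
  sup <- rv > 0.05
  meiv <- as.vector(mei$image)
  mu_t <- mean(meiv[sup]); sd_t <- stats::sd(meiv[sup])
  M <- X * rv
  Xm <- apply(M, 2, function(v) {
    s <- stats::sd(v[sup])
    if (s < 1e-12) return(v)
    out <- v
    out[sup] <- (v[sup] - mean(v[sup])) / s * sd_t + mu_t
    out
  })
  r <- respond_batch_only(model, Xm)
  adm <- which(r >= threshold * mei$activation)
  flagged <- length(adm) < k
  if (!length(adm))
    return(list(images = Xm[, 0, drop = FALSE], indices = integer(0),
                activations = numeric(0), flagged = TRUE))
  kk <- min(k, length(adm))
  Xa <- Xm[, adm, drop = FALSE]
  sel <- greedy_max_min_select(Xa, kk, mei$mask, start = which.max(r[adm]))
  list(images = Xa[, sel, drop = FALSE], indices = adm[sel],
       activations = r[adm][sel], flagged = flagged,
       admissible = Xa, admissible_indices = adm)
}
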