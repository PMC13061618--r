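# Texture-generative (bipartite) parameterization of VEIs: variable/fixed
# subfield mask series, texture-canvas optimization, texture-VEI rendering,
# harmonic-mean model selection, the bipartite invariance index (BII), the
# two control parameterizations, subfield manipulations and the subfield
# median-frequency comparison.

#' Variable-subfield mask series from VEI variance
#'
#' Computes the pixel-wise variance across the VEIs within the MEI mask
#' support and grows the variable subfield pixel by pixel in descending
#' variance order until each target fraction of the total variance is
#' enclosed. The fixed subfield is the in-mask complement. Both subfield
#' masks inherit the MEI mask's weights, so `m_v + m_f = m_mei` on the
#' support.
#'
#' @param veis a `vei_set` (or npx x n image matrix)
#' @param m_mei weighted MEI mask matrix
#' @param fractions target variance fractions (default 0.20 to 0.60 by 0.05)
#' @param support_threshold binarization threshold for the mask support (0.3)
#' @return list of `subfield_masks`: m_mei, m_v, m_f, indicator_v,
#'   variance_fraction (achieved), target_fraction, size (area ratio)
#' @export
variable_mask_series <- function(veis, m_mei,
                                 fractions = seq(0.20, 0.60, by = 0.05),
                                 support_threshold = 0.3) {
  X <- if (inherits(veis, "vei_set")) veis$images else as_image_batch(veis)
  stopifnot(ncol(X) >= 2)
  v <- apply(X, 1, stats::var)
  sup <- as.vector(m_mei) > support_threshold
  vs <- v * sup
  tot <- sum(vs)
  if (tot <= 0 || stats::sd(vs[sup]) < 1e-14 * mean(vs[sup]))
    warning("uniform variance map: degenerate subfield series")
  ord <- order(vs, decreasing = TRUE)
  ord <- ord[sup[ord]]
  cum <- cumsum(vs[ord]) / tot
  shape <- dim(m_mei)
  lapply(fractions, function(f) {
    k <- which(cum >= f)[1]
    if (is.na(k)) k <- length(ord)
    ind <- rep(FALSE, length(v))
    ind[ord[seq_len(k)]] <- TRUE
    ind_m <- matrix(ind, shape[1], shape[2])
    structure(list(m_mei = m_mei,
                   m_v = m_mei * ind_m,
                   m_f = m_mei * (sup & !ind) * 1,
                   indicator_v = ind_m,
                   variance_fraction = cum[k],
                   target_fraction = f,
                   size = k / sum(sup)),
              class = "subfield_masks")
  })
}

# bounding box (r0, c0, nr, nc) of a logical matrix
mask_bbox <- function(ind) {
  w <- which(ind, arr.ind = TRUE)
  r <- range(w[, 1]); c <- range(w[, 2])
  c(r[1], c[1], r[2] - r[1] + 1L, c[2] - c[1] + 1L)
}

# Composite K crops of a canvas into full-field images:
# image_k = fixed_part + vm * crop_k, where crop_k is the canvas window of
# the m_v bounding-box size at offset_k placed at the bbox location.
# Fully vectorized: linear canvas indices for all crops at once.
compose_crops <- function(canvas, offsets, bbox, vm, fixed_part, shape) {
  npx <- prod(shape)
  K <- nrow(offsets)
  X <- matrix(rep(as.vector(fixed_part), K), npx, K)
  bb_rows <- bbox[3]; bb_cols <- bbox[4]
  idx_in_img <- as.vector(outer(bbox[1]:(bbox[1] + bb_rows - 1),
                                (bbox[2]:(bbox[2] + bb_cols - 1) - 1) * shape[1],
                                `+`))
  vmw <- as.vector(vm)[idx_in_img]
  cr <- nrow(canvas)
  base <- as.vector(outer(seq_len(bb_rows),
                          (seq_len(bb_cols) - 1L) * cr, `+`))
  canvas_idx <- outer(base, (offsets[, 1] - 1L) + (offsets[, 2] - 1L) * cr,
                      `+`)                       # bbpx x K
  crops <- matrix(canvas[canvas_idx], length(base), K)
  X[idx_in_img, ] <- X[idx_in_img, , drop = FALSE] + vmw * crops
  list(X = X, idx_in_img = idx_in_img, vmw = vmw, canvas_idx = canvas_idx)
}

#' Optimize a texture canvas for a variable subfield
#'
#' Gradient-ascends a canvas (the variable-subfield bounding box dilated by
#' 50% per side) so that the mean model response over `K` random crops --
#' each composited as `m_v * crop + fixed_part` and standardized -- is
#' maximized. Gradients are Gaussian-blurred; the canvas is re-standardized
#' each step.
#'
#' @param model a `model_neuron`
#' @param masks a `subfield_masks` element
#' @param fixed_part full-field fixed content (matrix, e.g. `m_f * MEI`);
#'   use a zero matrix for purely texture-driven models
#' @param config a [synthesis_config()] with `seed`
#' @param iters ascent steps (default 1000)
#' @param K crops per step (default 16)
#' @param lr learning rate (default 1.0)
#' @param init_sd s.d. of the canvas initialization; sensibly the RMS of the
#'   MEI content inside the variable subfield, so crops start at a
#'   competitive contrast
#' @return object of class `texture_canvas`
#' @export
optimize_texture <- function(model, masks, fixed_part,
                             config = synthesis_config(seed = 1),
                             iters = 1000, K = 16, lr = 1.0,
                             init_sd = config$std_rms) {
  if (is.null(config$seed)) stop("config$seed is required")
  shape <- model$shape
  bbox <- mask_bbox(masks$indicator_v)
  bb_rows <- bbox[3]; bb_cols <- bbox[4]
  cr <- max(bb_rows + 2L, ceiling(2 * bb_rows))
  cc <- max(bb_cols + 2L, ceiling(2 * bb_cols))
  max_or <- cr - bb_rows + 1L
  max_oc <- cc - bb_cols + 1L
  withr_seed(config$seed)
  # the canvas is unconstrained: only composites are standardized, and the
  # gradient is propagated through standardization and clipping, so the
  # crop amplitude self-balances against the fixed content
  canvas <- matrix(stats::rnorm(cr * cc, sd = init_sd), cr, cc)
  fixedv <- as.vector(fixed_part)
  vm <- masks$m_v
  npx <- prod(shape)
  for (it in seq_len(iters)) {
    offsets <- cbind(sample.int(max_or, K, replace = TRUE),
                     sample.int(max_oc, K, replace = TRUE))
    cm <- compose_crops(canvas, offsets, bbox, vm, fixedv, shape)
    C <- cm$X
    mu <- .colMeans(C, npx, K)
    Cc <- C - rep(mu, each = npx)
    rms <- sqrt(.colMeans(Cc * Cc, npx, K))
    rms <- pmax(rms, 1e-12)
    a <- config$std_rms / rms
    Xs <- Cc * rep(a, each = npx) + config$std_mean
    clipped <- Xs < config$clip[1] | Xs > config$clip[2]
    X <- pmin(pmax(Xs, config$clip[1]), config$clip[2])
    ev <- model$eval_batch(X)
    g <- ev$G
    g[clipped] <- 0
    # backprop through X = a * (C - mean(C)) + mean_target
    gdot <- .colSums(g * Cc, npx, K) / (npx * rms^2)
    gc <- (g - rep(.colMeans(g, npx, K), each = npx) -
             Cc * rep(gdot, each = npx)) * rep(a, each = npx)
    gcrop <- gc[cm$idx_in_img, , drop = FALSE] * cm$vmw
    acc <- rowsum(as.vector(gcrop), as.vector(cm$canvas_idx))
    gcanvas <- matrix(0, cr, cc)
    gcanvas[as.integer(rownames(acc))] <- acc
    gcanvas <- gaussian_blur(gcanvas / K, config$grad_blur_sigma)
    canvas <- canvas + lr * gcanvas
  }
  structure(list(texture = canvas, bbox = bbox,
                 offset_range = c(max_or, max_oc), masks = masks),
            class = "texture_canvas")
}

#' Render texture-based VEIs from an optimized canvas
#'
#' Draws `n` uniformly random crop offsets, composites each crop with the
#' fixed content and standardizes. With `m_v = m_mei` this realizes the
#' full-texture VEIs.
#'
#' @param canvas a `texture_canvas`
#' @param masks the `subfield_masks` used for the canvas
#' @param fixed_part full-field fixed content matrix
#' @param n number of images (default 20)
#' @param seed RNG seed (mandatory)
#' @param config a [synthesis_config()] for standardization targets
#' @return list: images (npx x n), offsets
#' @export
render_texture_veis <- function(canvas, masks, fixed_part, n = 20, seed,
                                config = synthesis_config(seed = seed)) {
  withr_seed(seed)
  offsets <- cbind(sample.int(canvas$offset_range[1], n, replace = TRUE),
                   sample.int(canvas$offset_range[2], n, replace = TRUE))
  shape <- dim(masks$m_mei)
  cm <- compose_crops(canvas$texture, offsets, canvas$bbox, masks$m_v,
                      as.vector(fixed_part), shape)
  X <- standardize_batch(cm$X, config$std_mean, config$std_rms, config$clip)
  list(images = X, offsets = offsets)
}

#' Harmonic-mean model selection over a subfield series
#'
#' Normalizes mean activation and mean pairwise distance each by their
#' maximum over the series and returns the index maximizing the harmonic
#' mean H = 2 r d / (r + d).
#'
#' @param series data.frame with columns `mean_activation` and
#'   `mean_distance` (raw values; normalization is internal)
#' @return index of the selected member; the H values are attached as the
#'   `"H"` attribute
#' @export
harmonic_selection <- function(series) {
  stopifnot(nrow(series) >= 2)
  r <- series$mean_activation
  d <- series$mean_distance
  if (max(r) <= 0) stop("all-zero activations")
  rn <- r / max(r)
  dn <- if (max(d) > 0) d / max(d) else d
  H <- ifelse(rn + dn > 0, 2 * rn * dn / (rn + dn), 0)
  out <- which.max(H)
  attr(out, "H") <- H
  out
}

# quadratic P-spline fit (GCV smoothing), safe for small series: a compact
# basis (k = 5) keeps all coefficients identified when the x values cluster,
# and the first-order difference penalty shrinks toward local constancy so
# no slope is extrapolated into unsampled regions of the size axis
fit_quadratic_spline <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  k <- max(4, min(5, n - 1))
  dat <- data.frame(x = x, y = y)
  fit <- try(mgcv::gam(y ~ s(x, k = k, bs = "ps", m = c(1, 1)), data = dat),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- stats::lm(y ~ x + I(x^2), data = dat)
  function(x_new) as.numeric(stats::predict(fit, data.frame(x = x_new)))
}

#' Bipartite invariance index (BII)
#'
#' Fits a quadratic smoothing spline of normalized activation versus
#' variable-subfield relative size, evaluates it on a uniform grid over
#' `[0, 1]` with activations clamped to `[0, 1]`, and returns the
#' trapezoidal area under the curve. Size-0 (pure MEI, activation 1) and
#' size-1 (full-texture) anchors are expected to be part of the series.
#'
#' @param series data.frame with columns `size` (relative variable-subfield
#'   area in `[0, 1]`) and `activation` (mean activation ratio to the MEI)
#' @param n_grid evaluation grid resolution (default 101)
#' @return scalar BII in `[0, 1]`
#' @export
bipartite_invariance_index <- function(series, n_grid = 101) {
  if (nrow(series) < 3) stop("need at least 3 series points")
  f <- fit_quadratic_spline(series$size, series$activation)
  xs <- seq(0, 1, length.out = n_grid)
  ys <- pmin(pmax(f(xs), 0), 1)
  sum((ys[-1] + ys[-n_grid]) / 2) * (xs[2] - xs[1])
}

#' Fit the bipartite texture model to a neuron
#'
#' Runs the full bipartite pipeline: variable-mask series from the VEI
#' variance map, per-member texture optimization and texture-VEI rendering
#' (plus the size-1 full-texture member), harmonic-mean selection of
#' VEIs_partial, and the BII.
#'
#' @param model a `model_neuron`
#' @param mei the neuron's `mei`
#' @param veis the neuron's `vei_set`
#' @param config a [synthesis_config()] with `seed`
#' @param fractions variance fractions for the mask series
#' @param iters,K,lr texture-optimization settings (see [optimize_texture()])
#' @param n_render rendered texture-VEIs per member (default `config$n_veis`)
#' @return object of class `bipartite_fit`: series data.frame (size,
#'   variance_fraction, mean_activation, mean_distance, H), selected index,
#'   `veis_partial`, `veis_full`, masks, canvases, `bii`
#' @export
fit_bipartite <- function(model, mei, veis,
                          config = synthesis_config(seed = 1),
                          fractions = seq(0.20, 0.60, by = 0.05),
                          iters = 1000, K = 16, lr = 1.0,
                          n_render = config$n_veis) {
  if (is.null(config$seed)) stop("config$seed is required")
  series_masks <- variable_mask_series(veis, mei$mask, fractions)
  # size-1 member: the whole mask is variable (full-texture model)
  sup <- mei$mask > 0.3
  full_masks <- structure(list(m_mei = mei$mask, m_v = mei$mask,
                               m_f = mei$mask * 0, indicator_v = sup,
                               variance_fraction = 1, target_fraction = 1,
                               size = 1), class = "subfield_masks")
  members <- c(series_masks, list(full_masks))
  r_mei <- mei$activation
  maskv <- as.vector(mei$mask)
  rendered <- vector("list", length(members))
  act <- dist <- numeric(length(members))
  canvases <- vector("list", length(members))
  for (i in seq_along(members)) {
    mk <- members[[i]]
    fixed_part <- matrix(as.vector(mk$m_f) * as.vector(mei$image),
                         model$shape[1], model$shape[2])
    cfg_i <- config; cfg_i$seed <- config$seed + 37 * i
    canvases[[i]] <- optimize_texture(model, mk, fixed_part, cfg_i,
                                      iters = iters, K = K, lr = lr,
                                      init_sd = sqrt(mean(mei$image[mk$indicator_v]^2)))
    rnd <- render_texture_veis(canvases[[i]], mk, fixed_part, n = n_render,
                               seed = config$seed + 37 * i + 1, config = config)
    rendered[[i]] <- rnd
    r <- respond_batch_only(model, rnd$images)
    act[i] <- mean(r) / r_mei
    dist[i] <- mean_pairwise_distance(rnd$images, maskv)
  }
  sizes <- vapply(members, `[[`, numeric(1), "size")
  series <- data.frame(size = sizes,
                       variance_fraction = vapply(members, `[[`, numeric(1),
                                                  "variance_fraction"),
                       mean_activation = act,
                       mean_distance = dist)
  sel <- harmonic_selection(series)
  series$H <- attr(sel, "H")
  # BII series includes the size-0 anchor (pure MEI: ratio 1, by definition)
  bii_series <- rbind(data.frame(size = 0, activation = 1),
                      data.frame(size = sizes, activation = act))
  bii <- bipartite_invariance_index(bii_series)
  structure(list(series = series, selected = as.integer(sel),
                 masks = members, canvases = canvases,
                 veis_partial = rendered[[as.integer(sel)]],
                 veis_full = rendered[[length(members)]],
                 full_index = length(members),
                 bii = bii, mei = mei, label = model$label),
            class = "bipartite_fit")
}

#' @export
print.bipartite_fit <- function(x, ...) {
  cat("<bipartite_fit>", x$label, "\n  BII:", signif(x$bii, 3),
      "\n  selected member:", x$selected, "of", nrow(x$series),
      sprintf("(size %.2f, activation ratio %.2f)\n",
              x$series$size[x$selected],
              x$series$mean_activation[x$selected]))
  invisible(x)
}

#' @export
plot.bipartite_fit <- function(x, ...) {
  graphics::plot(x$series$size, pmin(pmax(x$series$mean_activation, 0), 1),
                 xlab = "variable subfield size", ylab = "activation ratio",
                 xlim = c(0, 1), ylim = c(0, 1.05), pch = 19, ...)
  f <- fit_quadratic_spline(c(0, x$series$size), c(1, x$series$mean_activation))
  xs <- seq(0, 1, length.out = 101)
  graphics::lines(xs, pmin(pmax(f(xs), 0), 1))
  graphics::legend("bottomleft", bty = "n",
                   legend = sprintf("BII = %.2f", x$bii))
  invisible(x)
}

#' No-spatial-division control VEIs
#'
#' Parameterizes VEIs as `(1 - c) m_mei T + c MEI` (two fully overlapping
#' components, no spatial division), optimizing a texture per `c`,
#' harmonic-selecting the best set, and interpolating the
#' activation-at-matched-diversity and diversity-at-matched-activation
#' against the neuron's nonparametric VEIs.
#'
#' @param model,mei,veis as in [fit_bipartite()]
#' @param c_grid mixing weights in `[0, 1]`
#' @param config a [synthesis_config()] with `seed`
#' @param iters,K,lr texture-optimization settings
#' @param n_render rendered images per `c`
#' @return list: series (c, mean_activation, mean_distance, H), selected,
#'   images of the selected set, activation_at_matched_diversity,
#'   diversity_at_matched_activation
#' @export
no_spatial_division_veis <- function(model, mei, veis,
                                     c_grid = seq(0, 1, by = 0.2),
                                     config = synthesis_config(seed = 1),
                                     iters = 1000, K = 16, lr = 1.0,
                                     n_render = config$n_veis) {
  stopifnot(all(c_grid >= 0 & c_grid <= 1))
  sup <- mei$mask > 0.3
  masks <- structure(list(m_mei = mei$mask, m_v = mei$mask,
                          m_f = mei$mask * 0, indicator_v = sup,
                          variance_fraction = 1, target_fraction = 1,
                          size = 1), class = "subfield_masks")
  r_mei <- mei$activation
  maskv <- as.vector(mei$mask)
  act <- dist <- numeric(length(c_grid))
  sets <- vector("list", length(c_grid))
  for (i in seq_along(c_grid)) {
    cc <- c_grid[i]
    mk <- masks
    mk$m_v <- (1 - cc) * mei$mask
    fixed_part <- cc * mei$image
    if (cc >= 1) {
      X <- matrix(rep(as.vector(standardize(mei$image, config$std_mean,
                                            config$std_rms, config$clip)),
                      n_render), ncol = n_render)
      sets[[i]] <- list(images = X)
    } else {
      cfg_i <- config; cfg_i$seed <- config$seed + 101 * i
      cv <- optimize_texture(model, mk, fixed_part, cfg_i,
                             iters = iters, K = K, lr = lr,
                             init_sd = sqrt(mean(mei$image[mk$indicator_v]^2)))
      sets[[i]] <- render_texture_veis(cv, mk, fixed_part, n = n_render,
                                       seed = config$seed + 101 * i + 1,
                                       config = config)
    }
    r <- respond_batch_only(model, sets[[i]]$images)
    act[i] <- mean(r) / r_mei
    dist[i] <- mean_pairwise_distance(sets[[i]]$images, maskv)
  }
  series <- data.frame(c = c_grid, mean_activation = act,
                       mean_distance = dist)
  sel <- harmonic_selection(series)
  series$H <- attr(sel, "H")
  vei_act <- mean(veis$ratios)
  vei_div <- veis$mean_pairwise_distance
  ord <- order(dist)
  f_ad <- fit_quadratic_spline(dist[ord], act[ord])
  f_da <- fit_quadratic_spline(act[order(act)], dist[order(act)])
  list(series = series, selected = as.integer(sel),
       images = sets[[as.integer(sel)]]$images,
       activation_at_matched_diversity = f_ad(vei_div),
       diversity_at_matched_activation = f_da(vei_act))
}

#' Two-variable-subfield control VEIs
#'
#' Treats both subfields as shift-invariant: a texture is optimized for the
#' variable subfield and a second texture for the in-mask complement, and
#' composites combine independent random crops of each. The series member
#' with the highest harmonic mean is selected.
#'
#' @param model,mei,veis as in [fit_bipartite()]
#' @param fractions variance fractions for the mask series
#' @param config a [synthesis_config()] with `seed`
#' @param iters,K,lr texture-optimization settings
#' @param n_render images per member
#' @return list: series, selected, images of the selected set
#' @export
two_variable_veis <- function(model, mei, veis,
                              fractions = seq(0.20, 0.60, by = 0.05),
                              config = synthesis_config(seed = 1),
                              iters = 1000, K = 16, lr = 1.0,
                              n_render = config$n_veis) {
  series_masks <- variable_mask_series(veis, mei$mask, fractions)
  r_mei <- mei$activation
  maskv <- as.vector(mei$mask)
  shape <- model$shape
  act <- dist <- numeric(length(series_masks))
  sets <- vector("list", length(series_masks))
  for (i in seq_along(series_masks)) {
    mk <- series_masks[[i]]
    # complement masks: roles swapped
    mk2 <- mk
    mk2$m_v <- mk$m_f; mk2$m_f <- mk$m_v
    mk2$indicator_v <- (mk$m_mei > 0.3) & !mk$indicator_v
    if (!any(mk2$indicator_v)) mk2$indicator_v <- mk$indicator_v
    fixed1 <- matrix(as.vector(mk$m_f) * as.vector(mei$image), shape[1], shape[2])
    fixed2 <- matrix(as.vector(mk2$m_f) * as.vector(mei$image), shape[1], shape[2])
    cfg1 <- config; cfg1$seed <- config$seed + 211 * i
    cfg2 <- config; cfg2$seed <- config$seed + 211 * i + 1
    cv1 <- optimize_texture(model, mk, fixed1, cfg1, iters = iters, K = K,
                            lr = lr,
                            init_sd = sqrt(mean(mei$image[mk$indicator_v]^2)))
    cv2 <- optimize_texture(model, mk2, fixed2, cfg2, iters = iters, K = K,
                            lr = lr,
                            init_sd = sqrt(mean(mei$image[mk2$indicator_v]^2)))
    withr_seed(config$seed + 211 * i + 2)
    off1 <- cbind(sample.int(cv1$offset_range[1], n_render, TRUE),
                  sample.int(cv1$offset_range[2], n_render, TRUE))
    off2 <- cbind(sample.int(cv2$offset_range[1], n_render, TRUE),
                  sample.int(cv2$offset_range[2], n_render, TRUE))
    zero <- numeric(prod(shape))
    c1 <- compose_crops(cv1$texture, off1, cv1$bbox, mk$m_v, zero, shape)
    c2 <- compose_crops(cv2$texture, off2, cv2$bbox, mk2$m_v, zero, shape)
    X <- standardize_batch(c1$X + c2$X, config$std_mean, config$std_rms,
                           config$clip)
    sets[[i]] <- list(images = X)
    r <- respond_batch_only(model, X)
    act[i] <- mean(r) / r_mei
    dist[i] <- mean_pairwise_distance(X, maskv)
  }
  series <- data.frame(fraction = vapply(series_masks, `[[`, numeric(1),
                                         "target_fraction"),
                       mean_activation = act, mean_distance = dist)
  sel <- harmonic_selection(series)
  series$H <- attr(sel, "H")
  list(series = series, selected = as.integer(sel),
       images = sets[[as.integer(sel)]]$images)
}

#' Subfield masking and swapping manipulations
#'
#' Tests the necessity and specificity of the two subfields. Masking uses a
#' binary mask whose smoothing is restricted to regions outside the kept
#' (complementary) subfield, so kept pixels are bit-identical. Swaps replace
#' a subfield's content with externally supplied content, matched in mean
#' and RMS within the substituted region.
#'
#' @param mei the neuron's `mei`
#' @param veis_partial images (npx x n matrix or list) of the partial-texture
#'   VEIs
#' @param masks the selected `subfield_masks`
#' @param mode one of "mask_fixed", "mask_variable", "swap_fixed_natural",
#'   "swap_variable_texture"
#' @param content replacement content for the swap modes: an (npx x n) matrix
#'   (or single matrix) of natural crops or other-neuron texture crops
#' @param smooth_sigma edge-smoothing sigma (default 1.5)
#' @return (npx x n) matrix of manipulated images
#' @export
subfield_manipulation <- function(mei, veis_partial, masks, mode,
                                  content = NULL, smooth_sigma = 1.5) {
  mode <- match.arg(mode, c("mask_fixed", "mask_variable",
                            "swap_fixed_natural", "swap_variable_texture"))
  X <- as_image_batch(veis_partial)
  shape <- dim(masks$m_mei)
  sup <- masks$m_mei > 0.3
  ind_v <- masks$indicator_v & sup
  ind_f <- sup & !masks$indicator_v
  smooth_keep <- function(keep) {
    # binary keep-mask, smoothed, but forced to 1 on the kept subfield
    msk <- gaussian_blur(keep * 1, smooth_sigma)
    msk[keep] <- 1
    msk
  }
  if (mode %in% c("mask_fixed", "mask_variable")) {
    keep <- if (mode == "mask_fixed") ind_v else ind_f
    msk <- as.vector(smooth_keep(keep))
    return(X * msk)
  }
  if (is.null(content)) stop("swap modes require replacement content")
  C <- as_image_batch(content)
  if (ncol(C) == 1) C <- C[, rep(1, ncol(X)), drop = FALSE]
  stopifnot(ncol(C) == ncol(X))
  region <- if (mode == "swap_fixed_natural") ind_f else ind_v
  rv <- as.vector(region)
  out <- X
  for (j in seq_len(ncol(X))) {
    orig <- X[rv, j]
    repl <- C[rv, j]
    s <- stats::sd(repl)
    repl_adj <- if (s < 1e-12) repl - mean(repl) + mean(orig)
                else (repl - mean(repl)) / s * stats::sd(orig) + mean(orig)
    out[rv, j] <- repl_adj
  }
  out
}

#' Median spatial frequency of the two bipartite subfields
#'
#' Indirect comparison: the partial-texture VEIs (fixed subfield = MEI
#' content) versus the substituted set (fixed subfield replaced by texture
#' crops). Each set's radial power spectra (10 bins) are averaged and the
#' median frequency interpolated; the difference is attributable to the
#' fixed-subfield content.
#'
#' @param veis_partial images of the partial-texture VEIs
#' @param substituted_set images with the fixed subfield substituted
#' @param deg_per_pixel degrees per pixel
#' @param shape image grid
#' @return list: `f_fixed` (median frequency of the original set) and
#'   `f_variable` (of the substituted set), cycles/degree
#' @export
subfield_median_frequency <- function(veis_partial, substituted_set,
                                      deg_per_pixel = 2,
                                      shape = default_shape()) {
  med_of <- function(images) {
    X <- as_image_batch(images)
    specs <- lapply(seq_len(ncol(X)), function(j)
      radial_power_spectrum(matrix(X[, j], shape[1], shape[2]),
                            deg_per_pixel))
    pow <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
    median_frequency(list(freq = specs[[1]]$freq, power = pow))
  }
  list(f_fixed = med_of(veis_partial), f_variable = med_of(substituted_set))
}
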