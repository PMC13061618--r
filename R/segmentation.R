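# Alignment between a neuron's bipartite subfield division and
# object/background segmentations: ternary masks, the matching score,
# boundary-crop filtering, grating-scene composition and crop screening.

#' Ternary bipartite mask
#'
#' Binarizes the MEI and variable-subfield masks at `threshold` and labels
#' pixels +1 inside the variable subfield, -1 on the rest of the MEI-mask
#' support, 0 outside.
#'
#' @param m_mei weighted MEI mask matrix
#' @param m_v weighted variable-subfield mask matrix
#' @param threshold binarization threshold (default 0.3)
#' @return integer matrix with values in `{-1, 0, 1}`
#' @export
bipartite_mask <- function(m_mei, m_v, threshold = 0.3) {
  stopifnot(all(dim(m_mei) == dim(m_v)))
  sup <- m_mei > threshold
  if (!any(sup)) stop("empty binarized MEI mask")
  vb <- m_v > threshold
  out <- matrix(0L, nrow(m_mei), ncol(m_mei))
  out[sup] <- -1L
  out[sup & vb] <- 1L
  out
}

#' Matching score between a bipartite mask and a segmentation
#'
#' Raw score `sum(bip * seg) / sum(abs(bip))` rescaled to `[0, 1]`:
#' 1 means the variable subfield aligns perfectly with the object (and the
#' fixed subfield with the background); 0 means the perfect reversal. The
#' raw `[-1, 1]` value is attached as the `"raw"` attribute.
#'
#' @param bip ternary bipartite mask (see [bipartite_mask()])
#' @param seg ternary segmentation mask (+1 object, -1 background) on the
#'   same grid
#' @return scalar in `[0, 1]`
#' @export
matching_score <- function(bip, seg) {
  stopifnot(all(dim(bip) == dim(seg)))
  denom <- sum(abs(bip))
  if (denom == 0) stop("empty bipartite mask")
  raw <- sum(bip * seg) / denom
  out <- (raw + 1) / 2
  attr(out, "raw") <- raw
  out
}

#' Boundary-crop filter
#'
#' TRUE iff the crop contains at least `min_fraction` of both object and
#' background pixels within the receptive-field mask.
#'
#' @param seg_crop ternary segmentation (+1 object, -1 background)
#' @param min_fraction minimum fraction of each class (default 0.2; 0.1 and
#'   0.3 are the robustness variants)
#' @param rf_mask binary (or weighted, thresholded at 0.3) RF mask
#' @return logical scalar
#' @export
boundary_crop_filter <- function(seg_crop, min_fraction = 0.2, rf_mask) {
  stopifnot(all(dim(seg_crop) == dim(rf_mask)))
  inside <- rf_mask > 0.3
  if (!any(inside)) stop("empty RF mask")
  n <- sum(inside)
  f_obj <- sum(seg_crop[inside] > 0) / n
  f_bg <- sum(seg_crop[inside] < 0) / n
  f_obj >= min_fraction && f_bg >= min_fraction
}

#' Grating-scene specification
#'
#' Wavelength bands are in degrees/cycle: the high-frequency band is
#' `[5.83, 15.55]` and the low-frequency band `[15.55, 58.3]`.
#'
#' @param type one of "single", "orientation", "frequency", "both"
#' @param object_band which band feeds the object region for the
#'   frequency-varying types ("high" or "low"; background gets the other)
#' @param blur_sigma boundary blur sigma in pixels (default 1.5)
#' @return list of class `grating_scene_spec`
#' @export
grating_scene_spec <- function(type = c("single", "orientation", "frequency",
                                        "both"),
                               object_band = c("high", "low"),
                               blur_sigma = 1.5) {
  structure(list(type = match.arg(type),
                 object_band = match.arg(object_band),
                 blur_sigma = blur_sigma,
                 band_high = c(5.83, 15.55),
                 band_low = c(15.55, 58.3)),
            class = "grating_scene_spec")
}

full_field_grating <- function(shape, deg_per_pixel, wavelength, theta, phase) {
  g <- grid_coords_deg(shape, deg_per_pixel)
  cos(2 * pi * (g$x * cos(theta) + g$y * sin(theta)) / wavelength + phase)
}

#' Compose an object/background grating scene
#'
#' Samples object and background gratings according to the scene type,
#' standardizes both to identical mean and RMS contrast, composites them via
#' the segmentation mask, and blurs the object-background boundary with a
#' Gaussian (sigma = 1.5 by default).
#'
#' @param seg_mask binary object mask (TRUE/1 = object)
#' @param spec a [grating_scene_spec()]
#' @param deg_per_pixel degrees per pixel
#' @param seed RNG seed (mandatory)
#' @return list: image (matrix), object and background grating parameters
#' @export
compose_grating_scene <- function(seg_mask, spec = grating_scene_spec(),
                                  deg_per_pixel = 2, seed) {
  stopifnot(inherits(spec, "grating_scene_spec"))
  shape <- dim(seg_mask)
  withr_seed(seed)
  bands <- if (spec$object_band == "high")
    list(obj = spec$band_high, bg = spec$band_low)
  else list(obj = spec$band_low, bg = spec$band_high)
  th_o <- stats::runif(1, 0, pi)
  wl_o <- stats::runif(1, bands$obj[1], bands$obj[2])
  ph_o <- stats::runif(1, 0, 2 * pi)
  pars <- switch(spec$type,
    single = list(obj = c(wl_o, th_o, ph_o), bg = c(wl_o, th_o, ph_o)),
    orientation = list(obj = c(wl_o, th_o, ph_o),
                       bg = c(wl_o, stats::runif(1, 0, pi),
                              stats::runif(1, 0, 2 * pi))),
    frequency = list(obj = c(wl_o, th_o, ph_o),
                     bg = c(stats::runif(1, bands$bg[1], bands$bg[2]), th_o,
                            stats::runif(1, 0, 2 * pi))),
    both = list(obj = c(wl_o, th_o, ph_o),
                bg = c(stats::runif(1, bands$bg[1], bands$bg[2]),
                       stats::runif(1, 0, pi), stats::runif(1, 0, 2 * pi))))
  g_obj <- standardize(full_field_grating(shape, deg_per_pixel,
                                          pars$obj[1], pars$obj[2], pars$obj[3]))
  if (spec$type == "single") {
    return(list(image = g_obj, object = pars$obj, background = pars$obj))
  }
  g_bg <- standardize(full_field_grating(shape, deg_per_pixel,
                                         pars$bg[1], pars$bg[2], pars$bg[3]))
  W <- gaussian_blur((seg_mask > 0) * 1, spec$blur_sigma)
  list(image = W * g_obj + (1 - W) * g_bg,
       object = pars$obj, background = pars$bg)
}

#' Screen crops for the most activating ones
#'
#' Masks each crop with the MEI mask and (optionally) matches its mean and
#' RMS within the mask support to the MEI's, computes model responses
#' batch-wise, and returns the `top_k` ranked crops plus a seeded uniform
#' random reference sample.
#'
#' @param model a `model_neuron`
#' @param crops list of matrices or (npx x n) matrix
#' @param mei the neuron's `mei`
#' @param top_k number of top crops (default 100)
#' @param contrast_match match within-mask mean/RMS to the MEI (default TRUE)
#' @param seed RNG seed for the reference sample (mandatory)
#' @return list: indices (ranked, length min(top_k, n)), activations (full
#'   vector), reference_indices, flagged (TRUE when top_k > pool size)
#' @export
screen_crops <- function(model, crops, mei, top_k = 100,
                         contrast_match = TRUE, seed) {
  X <- as_image_batch(crops)
  maskv <- as.vector(mei$mask)
  sup <- maskv > 0.3
  meiv <- as.vector(mei$image)
  mu_t <- mean(meiv[sup]); sd_t <- stats::sd(meiv[sup])
  M <- X * maskv
  if (contrast_match) {
    M <- apply(M, 2, function(v) {
      s <- stats::sd(v[sup])
      if (s < 1e-12) return(v)
      v[sup] <- (v[sup] - mean(v[sup])) / s * sd_t + mu_t
      v
    })
  }
  r <- respond_batch_only(model, M)
  flagged <- top_k > ncol(X)
  k <- min(top_k, ncol(X))
  ord <- order(r, decreasing = TRUE)
  withr_seed(seed)
  ref <- sample.int(ncol(X), k)
  list(indices = ord[seq_len(k)], activations = r,
       reference_indices = ref, flagged = flagged)
}
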