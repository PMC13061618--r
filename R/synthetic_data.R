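# Synthetic fixtures: naturalistic 1/f image pools, blob segmentation masks,
# a planted bipartite ground-truth neuron, and synthetic connectome tables.
# Every generator is a pure function of its seed and arguments.

#' Naturalistic (1/f) images
#'
#' Spatially correlated noise with a `1/f^exponent` amplitude spectrum and
#' random phases, standardized to mean 0 / RMS contrast 0.25. Exponent 0
#' gives white noise.
#'
#' @param n number of images
#' @param shape grid c(rows, cols)
#' @param spectral_exponent amplitude falloff exponent (default 1)
#' @param seed RNG seed (mandatory)
#' @param rms_target RMS contrast (default 0.25)
#' @return list of image matrices
#' @export
naturalistic_images <- function(n, shape = default_shape(),
                                spectral_exponent = 1.0, seed,
                                rms_target = 0.25) {
  stopifnot(n >= 1)
  rows <- shape[1]; cols <- shape[2]
  fr <- ifelse(seq_len(rows) - 1 <= rows / 2, seq_len(rows) - 1,
               seq_len(rows) - 1 - rows) / rows
  fc <- ifelse(seq_len(cols) - 1 <= cols / 2, seq_len(cols) - 1,
               seq_len(cols) - 1 - cols) / cols
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- 1 / pmax(f, 1e-9)^spectral_exponent
  amp[1, 1] <- 0
  withr_seed(seed)
  lapply(seq_len(n), function(i) {
    w <- matrix(stats::rnorm(rows * cols), rows, cols)
    img <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (rows * cols)
    standardize(img, 0, rms_target)
  })
}

# 4-connected component labeling (flood fill); returns an integer matrix
label4 <- function(mask) {
  rows <- nrow(mask); cols <- ncol(mask)
  lab <- matrix(0L, rows, cols)
  cur <- 0L
  idx_todo <- which(mask)
  for (s in idx_todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% rows + 1L
      cc <- (p - 1L) %/% rows + 1L
      nb <- c(if (r > 1) p - 1L, if (r < rows) p + 1L,
              if (cc > 1) p - rows, if (cc < cols) p + rows)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Blob segmentation masks
#'
#' Thresholded smoothed Gaussian fields; the largest 4-connected
#' suprathreshold region becomes the object (+1), everything else background
#' (-1). Object area fractions are kept within `[0.2, 0.8]` by resampling.
#'
#' @param n number of masks
#' @param shape grid c(rows, cols)
#' @param smoothness Gaussian field correlation length in pixels (default 5)
#' @param seed RNG seed (mandatory)
#' @return list of ternary matrices (+1 object, -1 background)
#' @export
blob_segmentation_masks <- function(n, shape = default_shape(),
                                    smoothness = 5, seed) {
  withr_seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      field <- gaussian_blur(matrix(stats::rnorm(prod(shape)),
                                    shape[1], shape[2]), smoothness)
      target <- stats::runif(1, 0.3, 0.7)
      thr <- stats::quantile(field, 1 - target)
      lab <- label4(field > thr)
      if (max(lab) < 1) next
      counts <- tabulate(lab[lab > 0])
      obj <- lab == which.max(counts)
      frac <- mean(obj)
      if (frac >= 0.2 && frac <= 0.8) {
        out[[i]] <- matrix(ifelse(obj, 1L, -1L), shape[1], shape[2])
        break
      }
    }
  }
  out
}

#' Planted bipartite ground-truth neuron
#'
#' A neuron whose receptive field is split into a fixed subfield (left half,
#' preferring a fixed low-frequency Gabor pattern) and a variable subfield
#' (right half, tolerating integer shifts of a high-frequency texture
#' template). The response is `h(<m_f I, F>) * (1 + E_v(I)) * g`, where
#' `h` is a smooth bell tuned to the calibrated drive of the ideal composite
#' (deviations of the fixed-pattern match in either direction cost
#' response), `E_v` is the energy of the image against the masked texture
#' carrier and its quadrature partner (so every shift of the texture -- a
#' pure phase change of the carrier -- drives the neuron identically), and
#' `g` in `(0, 1]` is a divisive-normalization factor, the ratio of
#' pattern-aligned to total energy within the RF: content aligned with
#' neither template is suppressive rather than merely ignored. All factors
#' are smooth, so gradients are alive everywhere. The zero image returns
#' the tuning-curve baseline `h(0)` (stored as `$baseline`).
#'
#' @param shape grid c(rows, cols)
#' @param freq_fixed_low fixed-subfield frequency in cycles/degree (0.05)
#' @param freq_variable_high variable-subfield frequency in cycles/degree
#'   (0.125); must exceed `freq_fixed_low`
#' @param deg_per_pixel degrees per pixel
#' @param seed RNG seed (for the template orientation draws)
#' @param rf_radius_deg RF radius in degrees (default 14)
#' @return a `model_neuron` with extra fields `m_v_true`, `m_f_true`,
#'   `fixed_template`, `texture_template`, `baseline`
#' @export
planted_bipartite_neuron <- function(shape = default_shape(),
                                     freq_fixed_low = 0.05,
                                     freq_variable_high = 0.125,
                                     deg_per_pixel = 2, seed = 1,
                                     rf_radius_deg = 14) {
  stopifnot(freq_variable_high > freq_fixed_low)
  g <- grid_coords_deg(shape, deg_per_pixel)
  r2 <- g$x^2 + g$y^2
  rf <- r2 <= rf_radius_deg^2
  # left/right split of the RF disc into fixed and variable subfields
  split_x <- 0
  m_f <- rf & g$x < split_x
  m_v <- rf & g$x >= split_x
  withr_seed(seed)
  th_f <- stats::runif(1, 0, pi)
  th_v <- stats::runif(1, 0, pi)
  fixed_template <- gabor_image(
    gabor_params(mu_x = -0.5 * rf_radius_deg, sigma = rf_radius_deg / 2.8,
                 theta = th_f, wavelength = 1 / freq_fixed_low, phase = 0),
    shape, deg_per_pixel) * m_f
  # envelope-free carrier plus its quadrature partner, pooled over local
  # tiles of the variable subfield: each tile is an energy detector over the
  # masked quadrature pair, so any shift of the carrier -- a phase change --
  # drives the tile identically, tile phases are independent (a rich,
  # continuous invariance manifold), and re-phasing one part of the
  # subfield leaves the other tiles' drives untouched (local pooling)
  phase_arg <- 2 * pi * (g$x * cos(th_v) + g$y * sin(th_v)) *
    freq_variable_high
  tex_base <- cos(phase_arg)
  tex_quad <- sin(phase_arg)
  xs_v <- g$x[m_v]
  tile_edges <- stats::quantile(xs_v, probs = seq(0, 1, length.out = 4))
  tile_edges[1] <- tile_edges[1] - 1
  tile_of <- findInterval(g$x, tile_edges, rightmost.closed = TRUE)
  upper_half <- g$y < 0
  n_tiles <- 6L
  tiles <- vector("list", n_tiles)
  k <- 0L
  for (band in 1:3) for (half in c(TRUE, FALSE)) {
    k <- k + 1L
    tiles[[k]] <- m_v & tile_of == band & (upper_half == half)
  }
  Ts <- do.call(cbind, lapply(tiles, function(tl)
    cbind(as.vector(tex_base * tl), as.vector(tex_quad * tl))))
  mfF <- as.vector(fixed_template * m_f)
  # scale projections so an ideal standardized composite drives both the
  # fixed branch and the total pooled texture energy to ~3; equal drives
  # keep the MEI's contrast balanced across the two subfields
  ideal <- standardize(fixed_template + tex_base * m_v, 0, 0.25)
  iv <- as.vector(ideal)
  tile_energy <- function(v) {
    Pv <- matrix(as.vector(crossprod(Ts, v)), nrow = 2)
    sum(sqrt(colSums(Pv^2)))
  }
  s_f <- 3 / max(sum(iv * mfF), 1e-9)
  s_v <- 3 / max(tile_energy(iv), 1e-9)
  mfFs <- mfF * s_f
  Tss <- Ts * s_v
  # orthonormal bases of the preferred subspaces, for divisive normalization
  # (tile supports are disjoint and each quadrature pair is near-orthogonal,
  # so column normalization suffices)
  u_f <- mfF / sqrt(sum(mfF^2))
  U_v <- sweep(Ts, 2, pmax(sqrt(colSums(Ts^2)), 1e-9), `/`)
  rfv <- as.vector((m_f | m_v) * 1)
  eps_g <- 1e-3
  # tuned (Lorentzian) fixed branch: h(af) = Hmax / (1 + (af - a0)^2/w^2),
  # peaked at the calibrated drive of the ideal composite. Deviations in
  # either direction cost response, so neither the optimizer nor the
  # diversity term can drift the fixed-pattern drive, while the heavy tails
  # keep gradients alive far from the peak; VEI diversity is forced into
  # the genuinely tolerant texture subfield.
  Hmax <- 3; a0 <- 3; w_f <- 1.2
  Ug <- cbind(u_f, U_v)                          # npx x (1 + 2 n_tiles)
  n_basis <- ncol(Ug)
  eval_batch <- function(X) {
    n <- ncol(X)
    npx <- nrow(X)
    af <- as.vector(crossprod(mfFs, X))          # 1 x n
    AB <- crossprod(Tss, X)                      # (2 n_tiles) x n
    dim(AB) <- c(2L, n_tiles, n)
    tile_av <- sqrt(colSums(AB^2))               # n_tiles x n
    av <- colSums(tile_av)
    dev <- (af - a0) / w_f
    sp <- Hmax / (1 + dev^2)
    base <- sp * (1 + av)
    # divisive normalization: energy within the RF that is aligned with the
    # preferred subspaces over the total RF energy; off-pattern content is
    # suppressive, so the neuron is selective, not merely insensitive
    P <- crossprod(Ug, X)                        # n_basis x n
    e_al <- colSums(P^2)
    Xrf <- X * rfv
    e_rf <- colSums(Xrf^2)
    g <- pmin((e_al + eps_g) / (e_rf + eps_g), 1)
    r <- base * g
    # gradients: product rule over the three factors
    W <- AB / rep(pmax(tile_av, 1e-12), each = 2)
    dim(W) <- c(2L * n_tiles, n)
    G_base <- mfFs %*% t(-2 * Hmax * dev / (w_f * (1 + dev^2)^2) * (1 + av) * g) +
      (Tss %*% W) * rep(sp * g, each = npx)
    dg_scale <- ifelse(g < 1, base / (e_rf + eps_g), 0)
    G_g <- (Ug %*% (P * rep(2 * dg_scale, each = n_basis))) -
      Xrf * rep(2 * dg_scale * (e_al + eps_g) / (e_rf + eps_g), each = npx)
    list(r = r, G = G_base + G_g)
  }
  neuron <- model_neuron(
    respond = function(img) eval_batch(matrix(as.vector(img)))$r,
    grad = function(img) matrix(eval_batch(matrix(as.vector(img)))$G,
                                shape[1], shape[2]),
    shape = shape, label = "planted bipartite neuron",
    eval_batch = eval_batch)
  neuron$m_v_true <- m_v * 1
  neuron$m_f_true <- m_f * 1
  neuron$fixed_template <- fixed_template
  neuron$texture_template <- tex_base   # full-field carrier; composites
                                        # apply m_v after shifting
  neuron$baseline <- Hmax / (1 + (a0 / w_f)^2)
  neuron$kind <- "planted_bipartite"
  neuron
}

#' Synthetic connectome pair table
#'
#' Pairs of presynaptic and postsynaptic neurons with planted functional
#' effects: connection log-odds increase with latent functional similarity
#' (`like_to_like_beta`) and decrease with presynaptic diversity
#' (`decay_rate`, which also scales the synapse conversion rate
#' `rate0 * exp(-decay_rate * diversity_pre)`); connected postsynaptic
#' partners sit `hierarchy_delta` higher on the diversity axis. The
#' intercept is calibrated so the expected number of connected pairs is
#' `target_connected`.
#'
#' @param n_pre presynaptic neurons (default 20)
#' @param n_post postsynaptic neurons (default 500)
#' @param like_to_like_beta similarity coefficient on the connection
#'   log-odds (default 2)
#' @param hierarchy_delta planted diversity increase of connected
#'   postsynaptic partners (default 0.15)
#' @param decay_rate diversity decay of connectivity and conversion rate
#'   (default 1.5)
#' @param target_connected expected connected pairs (default 700)
#' @param rate0 baseline conversion rate, synapses per mm (default 15)
#' @param seed RNG seed (mandatory)
#' @return data.frame: presyn_id, postsyn_id, connected, n_syn,
#'   co_travel_mm, mei_similarity, vei_similarity, similarity_latent,
#'   diversity_pre, diversity_post
#' @export
synthetic_connectome <- function(n_pre = 20, n_post = 500,
                                 like_to_like_beta = 2,
                                 hierarchy_delta = 0.15,
                                 decay_rate = 1.5,
                                 target_connected = 700,
                                 rate0 = 15, seed) {
  stopifnot(rate0 > 0, n_pre >= 1, n_post >= 1)
  withr_seed(seed)
  d <- 5
  z_pre <- matrix(stats::rnorm(n_pre * d), n_pre, d)
  z_post <- matrix(stats::rnorm(n_post * d), n_post, d)
  zn_pre <- z_pre / sqrt(rowSums(z_pre^2))
  zn_post <- z_post / sqrt(rowSums(z_post^2))
  sim <- zn_pre %*% t(zn_post)                    # n_pre x n_post cosines
  div_pre <- stats::runif(n_pre, 0.2, 1.2)
  div_post0 <- stats::runif(n_post, 0.2, 1.2)
  eta <- like_to_like_beta * sim - decay_rate * matrix(div_pre, n_pre, n_post)
  # calibrate the intercept for the expected connected-pair count
  f <- function(alpha) sum(stats::plogis(alpha + eta)) - target_connected
  alpha <- stats::uniroot(f, c(-30, 10))$root
  p <- stats::plogis(alpha + eta)
  conn <- matrix(stats::runif(n_pre * n_post) < p, n_pre, n_post)
  pre_id <- rep(seq_len(n_pre), times = n_post)
  post_id <- rep(seq_len(n_post), each = n_pre)
  connected <- as.vector(conn)
  co_travel <- stats::rlnorm(n_pre * n_post, meanlog = log(0.05), sdlog = 0.5)
  rate_pre <- rate0 * exp(-decay_rate * div_pre)
  n_syn <- integer(n_pre * n_post)
  idx_c <- which(connected)
  n_syn[idx_c] <- 1L + stats::rpois(length(idx_c),
                                    rate_pre[pre_id[idx_c]] * co_travel[idx_c])
  div_post_pair <- div_post0[post_id]
  div_post_pair[idx_c] <- div_pre[pre_id[idx_c]] + hierarchy_delta +
    stats::rnorm(length(idx_c), sd = 0.05)
  simv <- as.vector(sim)
  out <- data.frame(
    presyn_id = pre_id, postsyn_id = post_id,
    connected = connected, n_syn = n_syn, co_travel_mm = co_travel,
    similarity_latent = simv,
    mei_similarity = simv + stats::rnorm(length(simv), sd = 0.1),
    vei_similarity = simv + stats::rnorm(length(simv), sd = 0.1),
    diversity_pre = div_pre[pre_id],
    diversity_post = div_post_pair)
  attr(out, "truth") <- list(like_to_like_beta = like_to_like_beta,
                             hierarchy_delta = hierarchy_delta,
                             decay_rate = decay_rate, rate0 = rate0,
                             alpha = alpha)
  out
}
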