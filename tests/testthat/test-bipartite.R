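test_that("variable-mask series tracks the variance map pixel by pixel", {
  set.seed(30)
  m_mei <- matrix(0, 36, 64); m_mei[10:27, 14:50] <- 1
  # variance concentrated in the left half of the mask
  X <- matrix(0, 36 * 64, 10)
  left <- matrix(FALSE, 36, 64); left[10:27, 14:31] <- TRUE
  X[as.vector(left), ] <- rnorm(sum(left) * 10, sd = 2)
  X[as.vector(m_mei > 0 & !left), ] <- rnorm(sum(m_mei > 0 & !left) * 10,
                                             sd = 0.05)
  ser <- variable_mask_series(X, m_mei, fractions = c(0.3, 0.5, 1.0))
  expect_true(all(ser[[1]]$indicator_v[!left] == FALSE))
  expect_true(all(ser[[2]]$indicator_v[!left] == FALSE))
  # fraction 1.0 covers the whole support
  expect_equal(ser[[3]]$indicator_v, m_mei > 0.3, ignore_attr = TRUE)

  # achieved fraction within one pixel's variance of the target
  v <- apply(X, 1, var) * as.vector(m_mei > 0.3)
  vmax <- max(v) / sum(v)
  for (s in ser) expect_lt(abs(s$variance_fraction - s$target_fraction),
                           vmax + 1e-12)
  # subfields partition the weighted mask
  s1 <- ser[[1]]
  expect_equal(s1$m_v + s1$m_f, m_mei * (m_mei > 0.3), ignore_attr = TRUE)
})

test_that("harmonic selection maximizes 2rd/(r+d) on normalized series", {
  ser <- data.frame(mean_activation = c(1.0, 0.9, 0.5),
                    mean_distance = c(0.4, 0.9, 1.0))
  sel <- harmonic_selection(ser)
  expect_equal(as.integer(sel), 2L)
  H <- attr(sel, "H")
  brute <- 2 * c(1, .9, .5) * c(.4, .9, 1) / (c(1, .9, .5) + c(.4, .9, 1))
  expect_equal(H, brute, tolerance = 1e-12)

  # both normalized values 1 -> H = 1 and selected
  ser2 <- data.frame(mean_activation = c(0.5, 1), mean_distance = c(0.2, 1))
  s2 <- harmonic_selection(ser2)
  expect_equal(as.integer(s2), 2L)
  expect_equal(attr(s2, "H")[2], 1)
  # r = 1, d = 0 -> H = 0
  ser3 <- data.frame(mean_activation = c(1, 0.5), mean_distance = c(0, 1))
  expect_equal(attr(harmonic_selection(ser3), "H")[1], 0)
  expect_error(harmonic_selection(data.frame(mean_activation = c(0, 0),
                                             mean_distance = c(1, 1))))
})

test_that("BII equals the trapezoid oracle on closed-form activation curves", {
  sizes <- seq(0, 1, by = 0.1)
  flat <- data.frame(size = sizes, activation = rep(1, 11))
  expect_equal(bipartite_invariance_index(flat), 1, tolerance = 1e-6)
  lin <- data.frame(size = sizes, activation = 1 - sizes)
  expect_equal(bipartite_invariance_index(lin), 0.5, tolerance = 0.02)
  quad <- data.frame(size = sizes, activation = (1 - sizes)^2)
  oracle <- {
    xs <- seq(0, 1, length.out = 101)
    ys <- (1 - xs)^2
    sum((ys[-1] + ys[-101]) / 2) * 0.01
  }
  expect_equal(bipartite_invariance_index(quad), oracle, tolerance = 0.02)
  expect_error(bipartite_invariance_index(flat[1:2, ]))
})

test_that("texture rendering composites crops per the bipartite equation", {
  p <- ref_params()
  cc <- complex_cell(p)
  cfg <- quick_config(seed = 11)
  mei <- cache_get("mei_complex_quick", function() synthesize_mei(cc, cfg))
  veis <- cache_get("veis_complex_quick", function()
    synthesize_veis(cc, mei, cfg))
  ser <- variable_mask_series(veis, mei$mask, fractions = c(0.4))
  mk <- ser[[1]]
  fixed_part <- matrix(as.vector(mk$m_f) * as.vector(mei$image), 36, 64)
  cv <- optimize_texture(cc, mk, fixed_part, cfg, iters = 120, K = 6,
                         init_sd = sqrt(mean(mei$image[mk$indicator_v]^2)))
  cv2 <- optimize_texture(cc, mk, fixed_part, cfg, iters = 120, K = 6,
                          init_sd = sqrt(mean(mei$image[mk$indicator_v]^2)))
  expect_identical(cv$texture, cv2$texture)      # seed-reproducible

  rnd <- render_texture_veis(cv, mk, fixed_part, n = 20, seed = 7,
                             config = cfg)
  # fixed-subfield pixels identical across the n composites (up to the
  # per-image standardization scale)
  fix_idx <- which(as.vector(mk$m_f) > 0.3)
  ref <- rnd$images[fix_idx, 1]
  cors <- apply(rnd$images[fix_idx, -1, drop = FALSE], 2,
                function(v) cor(v, ref))
  expect_true(all(cors > 0.999))
  # identical offsets give identical images
  dup <- which(duplicated(rnd$offsets) | duplicated(rnd$offsets, fromLast = TRUE))
  if (length(dup) >= 2) {
    key <- paste(rnd$offsets[, 1], rnd$offsets[, 2])
    grp <- split(seq_len(20), key)
    grp <- grp[[which(lengths(grp) >= 2)[1]]]
    expect_equal(rnd$images[, grp[1]], rnd$images[, grp[2]], tolerance = 1e-12)
  }
  # offsets cover many distinct values
  expect_gte(nrow(unique(rnd$offsets)), 10)
})

test_that("subfield manipulations preserve kept pixels and matched moments", {
  p <- ref_params()
  cc <- complex_cell(p)
  cfg <- quick_config(seed = 11)
  mei <- cache_get("mei_complex_quick", function() synthesize_mei(cc, cfg))
  veis <- cache_get("veis_complex_quick", function()
    synthesize_veis(cc, mei, cfg))
  ser <- variable_mask_series(veis, mei$mask, fractions = c(0.4))
  mk <- ser[[1]]
  X <- veis$images[, 1:5]

  masked <- subfield_manipulation(mei, X, mk, "mask_fixed")
  v_idx <- which(as.vector(mk$indicator_v & (mk$m_mei > 0.3)))
  expect_identical(masked[v_idx, ], X[v_idx, ])   # bit-identical kept pixels
  f_core <- which(as.vector(!mk$indicator_v & (mk$m_mei > 0.3)))
  # removed subfield is strongly attenuated away from the boundary
  expect_lt(mean(abs(masked[f_core, ])), mean(abs(X[f_core, ])))

  crops <- veiscope:::as_image_batch(naturalistic_images(5, seed = 61))
  swapped <- subfield_manipulation(mei, X, mk, "swap_fixed_natural",
                                   content = crops)
  f_idx <- which(as.vector((mk$m_mei > 0.3) & !mk$indicator_v))
  for (j in 1:5) {
    expect_lt(abs(mean(swapped[f_idx, j]) - mean(X[f_idx, j])) /
                max(abs(mean(X[f_idx, j])), 1e-6), 0.02 + 1e-9)
    expect_lt(abs(sd(swapped[f_idx, j]) - sd(X[f_idx, j])) / sd(X[f_idx, j]),
              0.02)
  }
  expect_error(subfield_manipulation(mei, X, mk, "bogus"))
  expect_error(subfield_manipulation(mei, X, mk, "swap_fixed_natural"))
})

test_that("subfield median frequencies separate low and high content", {
  g <- grid_coords_deg(c(36, 64), 2)
  low <- cos(2 * pi * 0.05 * g$x)
  high <- cos(2 * pi * 0.2 * (g$x * cos(1) + g$y * sin(1)))
  set_a <- lapply(1:4, function(i) standardize(low + 0.05 * high))
  set_b <- lapply(1:4, function(i) standardize(high + 0.05 * low))
  mf <- subfield_median_frequency(set_a, set_b, deg_per_pixel = 2)
  expect_lt(mf$f_fixed, mf$f_variable)
  expect_lt(abs(mf$f_fixed - 0.05), 0.05)
  expect_lt(abs(mf$f_variable - 0.2), 0.05)
})
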