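test_that("MEI synthesis recovers the generating Gabor and beats random screening", {
  p <- ref_params()
  sc <- simple_cell(p)
  mei <- cache_get("mei_simple", function()
    synthesize_mei(sc, synthesis_config(seed = 11)))
  g0 <- standardize(gabor_image(p))
  sup <- mei$mask > 0.3
  expect_gt(abs(cor(mei$image[sup], g0[sup])), 0.9)

  pool <- naturalistic_images(1000, seed = 3)
  expect_gte(mei$activation, max(neuron_respond(sc, pool)))

  mei2 <- synthesize_mei(sc, synthesis_config(seed = 12, mei_iters = 600))
  m <- (mei$mask > 0.3) & (mei2$mask > 0.3)
  expect_gt(abs(cor(mei$image[m], mei2$image[m])), 0.8)
})

test_that("MEI mask pipeline: hull containment, largest component, zero outside", {
  g <- grid_coords_deg(c(36, 64), 2)
  blob <- exp(-((g$x + 10)^2 + g$y^2) / 120)
  # hull oracle: brute-force point-in-hull over the suprathreshold set
  z <- (blob - mean(blob)) / sd(blob)
  pts <- which(abs(z) > 1.5, arr.ind = TRUE)
  hull_oracle <- veiscope:::fill_convex_hull(pts, c(36, 64))
  mask <- extract_mei_mask(blob)
  iou <- sum(mask > 0.5 & hull_oracle > 0.5) /
    sum(mask > 0.5 | hull_oracle > 0.5)
  expect_gt(iou, 0.8)

  # two blobs, second one-tenth the area: only the larger survives
  blob2 <- blob + exp(-((g$x - 40)^2 + (g$y - 20)^2) / 2)
  mask2 <- extract_mei_mask(blob2)
  expect_equal(sum(mask2[, 45:64] > 0.3), 0)   # smaller blob's hull excluded

  # pre-smoothing hull is exactly 0 outside; smoothing leaves only an
  # exponential tail
  expect_true(all(mask[hull_oracle == 0 & gaussian_blur(hull_oracle, 1.5) < 1e-4]
                  < 1e-3))
  expect_error(extract_mei_mask(matrix(rep(c(-1, 1), 100), 20, 10)), "no RF")
})

test_that("VEI sets honor the activation floor and the lambda = 0 ablation collapses", {
  p <- ref_params()
  cc <- complex_cell(p)
  cfg <- quick_config(seed = 11)
  mei <- cache_get("mei_complex_quick", function() synthesize_mei(cc, cfg))
  veis <- cache_get("veis_complex_quick", function()
    synthesize_veis(cc, mei, cfg))
  expect_gte(min(veis$ratios), cfg$c)
  expect_false(veis$violated)
  expect_gt(veis$min_pairwise_distance, 0)

  # lambda ~ 0: no diversity force, near-copies of the MEI
  cfg0 <- quick_config(seed = 11)
  cfg0$lambda_grid <- c(1e-12)
  v0 <- synthesize_veis(cc, mei, cfg0)
  d_upper <- cache_get("d_upper_ref", function()
    exhaustive_gabor_veis(cc, mask = mei$mask)$mean_distance)
  expect_lt(v0$mean_pairwise_distance, d_upper / 4)
})

test_that("distance-matched controls stay within the budget and under-activate", {
  p <- ref_params()
  cc <- complex_cell(p)
  cfg <- quick_config(seed = 11)
  mei <- cache_get("mei_complex_quick", function() synthesize_mei(cc, cfg))
  veis <- cache_get("veis_complex_quick", function()
    synthesize_veis(cc, mei, cfg))
  ctrl <- synthesize_distance_controls(cc, mei, veis, cfg)
  expect_true(all(ctrl$distances <= ctrl$d_target + 1e-8))
  # d_target is the minimum VEI-to-MEI masked distance, so every control is
  # at least as close to the MEI as every VEI
  d_vei <- apply(veis$images, 2, function(v)
    masked_distance(matrix(v, 36, 64), mei$image, mei$mask))
  expect_equal(ctrl$d_target, min(d_vei))
  expect_true(all(ctrl$distances <= min(d_vei) + 1e-8))
  # moving away from the MEI costs response: controls activate below the MEI
  expect_lt(mean(ctrl$activations), mei$activation)
})

test_that("natural controls pass the brute-force distance filter", {
  p <- ref_params()
  cc <- complex_cell(p)
  cfg <- quick_config(seed = 11)
  mei <- cache_get("mei_complex_quick", function() synthesize_mei(cc, cfg))
  pool <- naturalistic_images(1000, seed = 17)
  X <- veiscope:::as_image_batch(pool)
  brute <- vapply(seq_len(ncol(X)), function(i)
    masked_distance(matrix(X[, i], 36, 64), mei$image, mei$mask), numeric(1))
  d_target <- as.numeric(stats::quantile(brute, 0.5))   # populated band
  sel <- sample_natural_controls(pool, mei, d_target, k = 20)
  expect_lte(ncol(sel$images), 20)
  ok <- which(brute >= 0.8 * d_target & brute <= d_target)
  expect_true(all(sel$indices %in% ok))
  expect_equal(sel$indices, utils::head(ok, 20))
  # the MEI itself (distance 0) is always excluded
  expect_warning(sel0 <- sample_natural_controls(list(mei$image), mei,
                                                 d_target),
                 "no crops")
  expect_equal(length(sel0$indices), 0)
})

test_that("neuronal-space distance is a negative Pearson correlation", {
  pop <- lapply(sample_gabor_population(5, seed = 41), complex_cell)
  set.seed(6)
  a <- standardize(matrix(rnorm(36 * 64), 36, 64))
  b <- standardize(matrix(rnorm(36 * 64), 36, 64))
  expect_equal(neuronal_space_distance(pop, a, a), -1)
  expect_equal(neuronal_space_distance(pop, a, b),
               neuronal_space_distance(pop, b, a))
  ra <- vapply(pop, function(m) m$respond(a), numeric(1))
  rb <- vapply(pop, function(m) m$respond(b), numeric(1))
  expect_equal(neuronal_space_distance(pop, a, b), -cor(ra, rb))
  expect_error(neuronal_space_distance(pop[1:2], a, b))
})

test_that("integer image shifts zero-pad and invert cleanly", {
  img <- matrix(1:12, 3, 4)
  s <- shift_image(img, 1, -1)
  expect_equal(s[2:3, 1:3], img[1:2, 2:4])
  expect_true(all(s[1, ] == 0) && all(s[, 4] == 0))
  expect_equal(shift_image(shift_image(img, 1, 1), -1, -1)[1:2, 1:3],
               img[1:2, 1:3])
})
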