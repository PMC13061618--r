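test_that("ternary bipartite masks label the subfields per the brute-force rule", {
  m_mei <- gaussian_blur({m <- matrix(0, 36, 64); m[10:27, 20:45] <- 1; m}, 1.5)
  m_v <- m_mei * {m <- matrix(0, 36, 64); m[10:27, 20:32] <- 1; m}
  tern <- bipartite_mask(m_mei, m_v)
  brute <- matrix(0L, 36, 64)
  brute[m_mei > 0.3] <- -1L
  brute[m_mei > 0.3 & m_v > 0.3] <- 1L
  expect_identical(tern, brute)
  expect_equal(sum(tern == 1), sum(m_v > 0.3))
  # m_v = m_mei -> all +1 within support; empty m_v -> all -1
  expect_true(all(bipartite_mask(m_mei, m_mei)[m_mei > 0.3] == 1))
  expect_true(all(bipartite_mask(m_mei, m_mei * 0)[m_mei > 0.3] == -1))
  expect_error(bipartite_mask(m_mei * 0, m_v), "empty")
})

test_that("matching score anchors at 1/0 and centers at 0.5 for random labels", {
  m_mei <- matrix(0, 36, 64); m_mei[10:27, 20:45] <- 1
  m_v <- matrix(0, 36, 64); m_v[10:27, 20:32] <- 1
  bip <- bipartite_mask(m_mei, m_v)
  seg_align <- matrix(-1L, 36, 64); seg_align[m_v > 0.3] <- 1L
  expect_equal(as.numeric(matching_score(bip, seg_align)), 1)
  expect_equal(as.numeric(matching_score(bip, -seg_align)), 0)
  # simultaneous relabeling invariance
  expect_equal(as.numeric(matching_score(-bip, -seg_align)), 1)

  set.seed(77)
  N <- sum(abs(bip))
  scores <- replicate(200, {
    seg <- matrix(sample(c(-1L, 1L), 36 * 64, replace = TRUE), 36, 64)
    as.numeric(matching_score(bip, seg))
  })
  expect_lt(abs(mean(scores) - 0.5), 3 / sqrt(N))
  expect_error(matching_score(bip * 0L, seg_align), "empty")
})

test_that("boundary-crop filter applies strict per-class fractions", {
  rf <- matrix(1, 10, 10)
  all_obj <- matrix(1L, 10, 10)
  expect_false(boundary_crop_filter(all_obj, 0.2, rf))
  half <- matrix(rep(c(1L, -1L), each = 50), 10, 10)
  expect_true(boundary_crop_filter(half, 0.2, rf))
  # 19.9% object at threshold 0.2 fails (counting oracle: 199/1000)
  rf2 <- matrix(1, 20, 50)
  crop <- matrix(-1L, 20, 50)
  crop[seq_len(199)] <- 1L
  expect_false(boundary_crop_filter(crop, 0.2, rf2))
  crop[200] <- 1L
  expect_true(boundary_crop_filter(crop, 0.2, rf2))
  expect_true(boundary_crop_filter(crop, 0.1, rf2))
  expect_error(boundary_crop_filter(half, 0.2, rf * 0), "empty")
})

test_that("grating scenes composite contrast-matched gratings through the mask", {
  seg <- matrix(0, 36, 64); seg[, 1:32] <- 1
  sp <- grating_scene_spec("frequency")
  sc <- compose_grating_scene(seg, sp, deg_per_pixel = 2, seed = 3)
  # frequency-only: orientations equal, wavelengths from different bands
  expect_equal(sc$object[2], sc$background[2])
  expect_true(sc$object[1] >= 5.83 && sc$object[1] <= 15.55)
  expect_true(sc$background[1] >= 15.55 && sc$background[1] <= 58.3)

  # far from the boundary the scene equals the pure grating
  g_obj <- standardize(veiscope:::full_field_grating(c(36, 64), 2,
    sc$object[1], sc$object[2], sc$object[3]))
  expect_lt(max(abs(sc$image[, 1:20] - g_obj[, 1:20])), 1e-3)

  # object and background regions conserve mean and RMS within 2% pre-blur
  g_bg <- standardize(veiscope:::full_field_grating(c(36, 64), 2,
    sc$background[1], sc$background[2], sc$background[3]))
  expect_lt(abs(sd(g_obj) - sd(g_bg)) / sd(g_bg), 0.02)
  expect_lt(abs(mean(g_obj) - mean(g_bg)), 0.02)

  # single type ignores the mask entirely
  sc1 <- compose_grating_scene(seg, grating_scene_spec("single"),
                               deg_per_pixel = 2, seed = 4)
  or1 <- veiscope:::full_field_grating(c(36, 64), 2, sc1$object[1],
                                       sc1$object[2], sc1$object[3])
  expect_equal(sc1$image, standardize(or1), tolerance = 1e-12)
  expect_identical(compose_grating_scene(seg, sp, 2, seed = 3)$image, sc$image)
})

test_that("crop screening ranks by response with a reproducible reference", {
  p <- ref_params()
  cc <- complex_cell(p)
  mei <- cache_get("mei_complex_quick", function()
    synthesize_mei(cc, quick_config(seed = 11)))
  pool <- c(list(mei$image), naturalistic_images(2000, seed = 71))
  scr <- screen_crops(cc, pool, mei, top_k = 50, seed = 5)
  # the MEI ranks at or near the top of its own screening
  expect_lte(which(scr$indices == 1), 5)
  # ranking matches a brute-force sort of the activations
  expect_equal(scr$indices, order(scr$activations, decreasing = TRUE)[1:50])
  scr2 <- screen_crops(cc, pool, mei, top_k = 50, seed = 5)
  expect_identical(scr$reference_indices, scr2$reference_indices)
  scr3 <- screen_crops(cc, pool[1:30], mei, top_k = 50, seed = 5)
  expect_true(scr3$flagged)
})

test_that("frequency-preferring complex cells favor matching grating regions", {
  # a complex cell tuned inside the high-frequency band responds more to
  # frequency-only scenes whose object band covers its RF
  p <- gabor_params(sigma = 6, theta = 0.8, wavelength = 10, phase = 0)
  cc <- complex_cell(p)
  seg <- matrix(0, 36, 64); seg[, 1:48] <- 1   # object region covers the RF
  resp_hi <- resp_lo <- numeric(30)
  for (i in 1:30) {
    hi <- compose_grating_scene(seg, grating_scene_spec("frequency", "high"),
                                2, seed = 100 + i)
    lo <- compose_grating_scene(seg, grating_scene_spec("frequency", "low"),
                                2, seed = 100 + i)
    resp_hi[i] <- cc$respond(standardize(hi$image))
    resp_lo[i] <- cc$respond(standardize(lo$image))
  }
  expect_gt(mean(resp_hi), mean(resp_lo))
})
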