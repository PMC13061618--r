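test_that("naturalistic images are standardized, seeded, and spectrum-correct", {
  imgs <- naturalistic_images(20, seed = 2)
  for (im in imgs[1:5]) {
    expect_lt(abs(mean(im)), 1e-9)
    expect_equal(sqrt(mean((im - mean(im))^2)), 0.25, tolerance = 1e-9)
  }
  expect_identical(naturalistic_images(3, seed = 8),
                   naturalistic_images(3, seed = 8))
  # 1/f images concentrate power at low frequencies
  pow1 <- radial_power_spectrum(naturalistic_images(1, shape = c(64, 64),
                                                    seed = 4)[[1]], 2)$power
  expect_gt(pow1[1], pow1[8])
})

test_that("blob masks are single 4-connected objects with bounded area", {
  masks <- blob_segmentation_masks(60, seed = 6)
  fr <- vapply(masks, function(m) mean(m > 0), numeric(1))
  expect_true(all(fr >= 0.2 & fr <= 0.8))
  # the object is one 4-connected component
  for (m in masks[1:10]) {
    lab <- veiscope:::label4(m > 0)
    expect_equal(max(lab), 1L)
  }
  expect_identical(blob_segmentation_masks(2, seed = 3),
                   blob_segmentation_masks(2, seed = 3))
})

test_that("the planted bipartite neuron gates on its fixed pattern and tolerates shifts", {
  nb <- planted_bipartite_neuron(seed = 2)
  # ideal composite: fixed template plus the texture at a tested shift
  comp <- standardize(nb$fixed_template + shift_image(nb$texture_template, 2, 2) *
                        (nb$m_v_true > 0), 0, 0.25)
  shifts <- expand.grid(dr = seq(-4, 4, 2), dc = seq(-4, 4, 2))
  rs <- vapply(seq_len(nrow(shifts)), function(i) {
    img <- standardize(nb$fixed_template +
                         shift_image(nb$texture_template, shifts$dr[i],
                                     shifts$dc[i]) * (nb$m_v_true > 0),
                       0, 0.25)
    nb$respond(img)
  }, numeric(1))
  expect_true(all(rs > 0))
  # response to any tested shift within 5% of the best tested shift
  expect_gt(min(rs) / max(rs), 0.95)

  # zero image sits at the documented tuning-curve baseline, far below the
  # composite response
  expect_equal(as.numeric(nb$respond(matrix(0, 36, 64))), nb$baseline,
               tolerance = 1e-9)
  expect_lt(nb$baseline, 0.1 * nb$respond(comp))

  # removing the fixed pattern collapses the response below half
  no_fixed <- standardize(shift_image(nb$texture_template, 0, 0) *
                            (nb$m_v_true > 0), 0, 0.25)
  expect_lt(nb$respond(no_fixed), 0.5 * nb$respond(comp))

  # gradients agree with finite differences (softplus keeps them alive)
  g <- nb$grad(comp)
  eps <- 1e-6
  for (idx in c(400, 1100, 1900)) {
    d <- comp; d[idx] <- d[idx] + eps
    fd <- (nb$respond(d) - nb$respond(comp)) / eps
    expect_equal(g[idx], fd, tolerance = 1e-2)
  }
})

test_that("synthetic connectomes are pure functions of their seed with planted effects", {
  t1 <- synthetic_connectome(seed = 12)
  t2 <- synthetic_connectome(seed = 12)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 20 * 500)
  expect_true(all(t1$n_syn[t1$connected] >= 1))
  expect_true(all(t1$n_syn[!t1$connected] == 0))
  expect_true(all(t1$co_travel_mm > 0))
  # connected count near the calibrated target
  expect_lt(abs(sum(t1$connected) - 700), 150)

  # null model: similarity difference within bootstrap noise of zero
  null <- synthetic_connectome(like_to_like_beta = 0, hierarchy_delta = 0,
                               decay_rate = 0, seed = 13)
  bt <- bootstrap_mean_difference(null$vei_similarity[null$connected],
                                  null$vei_similarity[!null$connected],
                                  n_resamples = 1000, seed = 1)
  expect_gt(bt$p, 0.05)

  # planted hierarchy: postsynaptic diversity above presynaptic for connected
  expect_gt(mean(t1$diversity_post[t1$connected] -
                   t1$diversity_pre[t1$connected]), 0)
})

test_that("planted like-to-like and diversity-decay effects are recoverable", {
  # similarity difference detected in at least 90% of tables
  det <- vapply(1:100, function(s) {
    tab <- synthetic_connectome(n_pre = 10, n_post = 200,
                                target_connected = 300, seed = 100 + s)
    stats::t.test(tab$vei_similarity[tab$connected],
                  tab$vei_similarity[!tab$connected])$p.value < 0.05 &&
      mean(tab$vei_similarity[tab$connected]) >
        mean(tab$vei_similarity[!tab$connected])
  }, logical(1))
  expect_gte(mean(det), 0.9)

  # positive conversion-rate decay recovered in at least 95% of simulations
  pos <- vapply(1:200, function(s) {
    tab <- synthetic_connectome(n_pre = 12, n_post = 150,
                                target_connected = 250, seed = 300 + s)
    con <- tab[tab$connected, ]
    rate <- tapply(con$n_syn, con$presyn_id, sum) /
      tapply(con$co_travel_mm, con$presyn_id, sum)
    div <- tapply(con$diversity_pre, con$presyn_id, mean)
    fit <- fit_exponential_decay(as.numeric(div), as.numeric(rate))
    is.finite(fit$rate) && fit$rate > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})
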