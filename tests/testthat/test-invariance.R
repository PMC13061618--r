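test_that("mean pairwise distance matches a brute-force double loop", {
  a <- matrix(0, 2, 2)
  expect_equal(mean_pairwise_distance(list(a, a)), 0)
  # three images at mutual distance 1: scaled unit basis vectors
  e1 <- a; e1[1, 1] <- 1
  e2 <- a; e2[2, 2] <- 1
  e3 <- a; e3[1, 2] <- 1
  tri <- lapply(list(e1, e2, e3), function(m) m / sqrt(2))
  expect_equal(mean_pairwise_distance(tri), 1)

  set.seed(14)
  imgs <- replicate(20, matrix(rnorm(25), 5, 5), simplify = FALSE)
  mask <- matrix(runif(25), 5, 5)
  brute <- 0; np <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    brute <- brute + sqrt(sum((mask * (imgs[[i]] - imgs[[j]]))^2))
    np <- np + 1
  }
  expect_equal(mean_pairwise_distance(imgs, mask), brute / np,
               tolerance = 1e-12)
})

test_that("greedy max-min selection matches brute force on collinear points", {
  # 6 points on a line; best 3-subset by min pairwise distance is the two
  # extremes plus the midpoint
  xs <- c(0, 1, 2.2, 5, 7.8, 10)
  X <- matrix(0, 4, 6)
  X[1, ] <- xs
  brute_best <- NULL; best_val <- -Inf
  for (s in utils::combn(6, 3, simplify = FALSE)) {
    v <- min(dist(xs[s]))
    if (v > best_val) { best_val <- v; brute_best <- s }
  }
  sel <- greedy_max_min_select(X, 3, start = 1L)
  expect_setequal(sel, brute_best)

  # permutation invariance given a deterministic start element
  perm <- c(3, 1, 6, 2, 5, 4)
  selp <- greedy_max_min_select(X[, perm], 3, start = which(perm == 1))
  expect_setequal(perm[selp], brute_best)
})

test_that("diversity calibration separates simple and complex populations", {
  cal <- cache_get("calib_small", function()
    calibrate_diversity_bounds(n_cells = 8, seed = 5))
  expect_gt(cal$d_upper, cal$d_lower)
  # simple-cell distances are parameter independent (CV below 6%)
  expect_lt(sd(cal$simple_distances) / mean(cal$simple_distances), 0.06)
  expect_lt(sd(cal$complex_distances) / mean(cal$complex_distances), 0.06)

  # complex-cell admissible set contains every phase at the optimum
  p <- ref_params()
  cc <- complex_cell(p)
  bank_resp <- vapply(seq(0, 2 * pi, length.out = 17)[-17], function(ph) {
    pp <- p; pp$phase <- ph
    cc$respond(standardize(gabor_image(pp)))
  }, numeric(1))
  expect_true(all(bank_resp >= 0.85 * max(bank_resp)))
})

test_that("the diversity index is the stated affine map and scale invariant", {
  cal <- structure(list(d_lower = 2, d_upper = 6), class = "diversity_calibration")
  expect_equal(diversity_index(2, cal), 0)
  expect_equal(diversity_index(6, cal), 1)
  expect_equal(diversity_index(4, cal), 0.5)
  # rescaling all distances with recalibrated bounds leaves D unchanged
  cal_s <- structure(list(d_lower = 2 * 3.7, d_upper = 6 * 3.7),
                     class = "diversity_calibration")
  d <- runif(10, 0, 10)
  expect_equal(diversity_index(d * 3.7, cal_s), diversity_index(d, cal),
               tolerance = 1e-12)
  expect_error(diversity_index(1, structure(list(d_lower = 2, d_upper = 2),
                                            class = "diversity_calibration")))
})

test_that("latent basis retains the planted rank and reconstructs", {
  # population whose responses live in a rank-3 subspace
  set.seed(20)
  B <- matrix(rnorm(36 * 64 * 3), 36 * 64, 3)
  pop <- lapply(1:12, function(i) {
    w <- as.vector(B %*% rnorm(3))
    model_neuron(respond = function(img) sum(img * w) + 100,
                 grad = function(img) matrix(w, 36, 64))
  })
  lib <- naturalistic_images(40, seed = 33)
  basis <- build_latent_basis(pop, lib, var_threshold = 0.95)
  expect_equal(basis$k, 3)
  full <- build_latent_basis(pop, lib, var_threshold = 1.0)
  expect_gte(sum(full$var_explained[seq_len(full$k)]), 1 - 1e-9)
  # reconstruction error at threshold 0.95 is at most 5% of variance
  expect_gte(sum(basis$var_explained[seq_len(basis$k)]), 0.95)
})

test_that("representational similarity is a mean pairwise latent cosine", {
  set.seed(21)
  pop <- lapply(sample_gabor_population(6, seed = 44), complex_cell)
  lib <- naturalistic_images(30, seed = 34)
  basis <- build_latent_basis(pop, lib)
  img <- lib[[1]]
  expect_equal(as.numeric(representational_similarity(basis, list(img), list(img))),
               1, tolerance = 1e-9)

  A <- naturalistic_images(4, seed = 35)
  B <- naturalistic_images(3, seed = 36)
  ZA <- veiscope:::latent_project(basis, A)
  ZB <- veiscope:::latent_project(basis, B)
  brute <- mean(outer(seq_len(4), seq_len(3), Vectorize(function(i, j)
    sum(ZA[i, ] * ZB[j, ]) / sqrt(sum(ZA[i, ]^2) * sum(ZB[j, ]^2)))))
  expect_equal(as.numeric(representational_similarity(basis, A, B)), brute,
               tolerance = 1e-10)
})

test_that("natural VEI selection screens, refines the mask, and is near optimal", {
  p <- ref_params()
  cc <- complex_cell(p)
  mei <- cache_get("mei_complex_quick", function()
    synthesize_mei(cc, quick_config(seed = 11)))
  pool <- c(list(mei$image), naturalistic_images(300, seed = 51))
  sel <- select_natural_veis(pool, cc, mei, k = 10)
  # the MEI itself is admissible (activation ratio about 1 after masking)
  expect_true(1 %in% sel$indices || length(sel$indices) == 10)
  expect_lte(ncol(sel$images), 10)
  if (ncol(sel$images) >= 3) {
    # selected min pairwise distance beats random subsets of the same size
    Xsel <- sel$images
    dmin_sel <- min(veiscope:::pairwise_masked_distances(
      Xsel, as.vector(mei$mask))[upper.tri(diag(ncol(Xsel)))])
    k <- ncol(Xsel)
    adm <- sel$admissible
    set.seed(9)
    worse <- replicate(200, {
      idx <- sample(seq_len(ncol(adm)), k)
      D <- veiscope:::pairwise_masked_distances(adm[, idx], as.vector(mei$mask))
      min(D[upper.tri(D)])
    })
    expect_gte(dmin_sel, max(worse) * 0.999)
  }
})
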