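test_that("autoencoder topology follows the pooling rules at any scale", {
  big <- build_cae(c(224L, 224L, 3L), filters = c(64L, 128L))
  expect_equal(big$latent_shape, c(56L, 56L, 128L))
  small <- build_cae(c(64L, 64L, 3L), filters = c(16L, 32L))
  expect_equal(small$latent_shape, c(16L, 16L, 32L))
  expect_error(build_cae(c(50L, 50L, 3L)), "divisible")

  # encode-then-decode returns the input shape
  tiny <- build_cae(c(16L, 16L, 1L), filters = c(4L, 8L))
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  expect_equal(dim(nn_predict(tiny$net, x)), dim(x))
  expect_equal(dim(cae_encode(tiny, x)), c(4, 4, 8, 2))
})

test_that("an autoencoder memorizes a single constant image", {
  cae <- build_cae(c(8L, 8L, 1L), filters = c(4L, 8L))
  x <- array(0.7, c(8, 8, 1, 2))
  cae <- train_cae(cae, x, train_config(1e-2, epochs = 150, batch_size = 1,
                                        patience = 150, seed = 1), xval = x)
  expect_lt(reconstruction_mse(x, cae_reconstruct(cae, x)), 1e-3)
})

test_that("level heads have the published output widths and sigmoid range", {
  h2b <- build_l2_head(32L, "backbone")
  expect_equal(h2b$net$output_shape, 3L)
  expect_equal(h2b$net$layers[[1]]$shape, c(4L, 4L, 2L))  # reshaped square-ish
  expect_true(any(vapply(h2b$net$layers, function(l) l$type == "conv", logical(1))))

  h2c <- build_l2_head(64L, "cae")
  expect_equal(h2c$net$output_shape, 3L)
  expect_false(any(vapply(h2c$net$layers, function(l) l$type == "conv", logical(1))))

  h3 <- build_l3_head(32L, "backbone")
  expect_equal(h3$net$output_shape, 10L)

  x <- matrix(rnorm(5 * 64), 5, 64)
  p <- nn_predict(h2c$net, x)
  expect_true(all(p > 0 & p < 1))

  # zero weights force sigmoid(0) = 0.5 everywhere
  z <- h2c$net
  for (i in seq_along(z$layers)) {
    if (!is.null(z$layers[[i]]$W)) {
      z$layers[[i]]$W[] <- 0; z$layers[[i]]$b[] <- 0
    }
  }
  expect_true(all(nn_predict(z, x) == 0.5))
})

test_that("a level-1 backbone classifier pools to one sigmoid unit", {
  bb <- build_backbone(c(16L, 16L, 1L), filters = c(4L, 8L))
  l1 <- build_l1_backbone_classifier(bb)
  expect_equal(l1$net$output_shape, 1L)
  x <- array(stats::runif(16 * 16 * 3), c(16, 16, 1, 3))
  p <- nn_predict(l1$net, x)
  expect_true(all(p > 0 & p < 1))
  h1 <- mvskel:::nn_forward_upto(l1$net, x, l1$penultimate)
  expect_equal(dim(h1), c(3, 32))
})

test_that("combined multiview features concatenate per-view channel blocks", {
  bb <- build_backbone(c(16L, 16L, 1L), filters = c(4L, 8L))
  dv <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  lat <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  f <- extract_combined_features(dv, lat, bb)
  expect_equal(dim(f)[3], 16)  # 8 + 8 channels
  fs <- extract_combined_features(lat, dv, bb)
  expect_equal(f[, , 1:8, ], fs[, , 9:16, ])
  same <- extract_combined_features(dv, dv, bb)
  expect_equal(same[, , 1:8, ], same[, , 9:16, ])
})

fit_small <- function(family, view = "MV", n = 40, seed = 2) {
  ds <- small_cohort(n = n, size = 32, abnormal = 0.5, seed = seed)
  cur <- curate_dataset(ds, curation_config(size = 32))
  ctl <- fit_control(family,
                     cae = train_config(2e-3, epochs = 4, batch_size = 8),
                     l1 = train_config(1e-3, epochs = 5),
                     l2 = train_config(1e-3, epochs = 5),
                     l3 = train_config(1e-3, epochs = 5),
                     cae_filters = c(4L, 8L), backbone_filters = c(4L, 8L),
                     hp = head_hp(dense_widths = c(32L, 16L, 8L)))
  list(fit = mvskel_fit(cur$composites, cur$labels, default_tax,
                        family = family, view = view, control = ctl,
                        seed = seed),
       cur = cur)
}

test_that("both families fit end to end and predict calibrated shapes", {
  for (family in c("cae", "backbone")) {
    out <- fit_small(family)
    pr <- predict(out$fit, out$cur$composites)
    n <- length(out$cur$specimen_ids)
    expect_length(pr$p_l1, n)
    expect_equal(dim(pr$p_l2), c(n, 3))
    expect_equal(dim(pr$p_l3), c(n, 10))
    expect_equal(dim(pr$vector), c(n, 13))
    expect_true(all(pr$vector > 0 & pr$vector < 1))
    expect_equal(colnames(pr$vector),
                 c(default_tax$retained_l2, default_tax$retained_l3))
    # identical inputs give identical outputs
    pr2 <- predict(out$fit, out$cur$composites)
    expect_identical(pr$vector, pr2$vector)
  }
})

test_that("upstream layers stay bit-identical after downstream training", {
  out <- fit_small("cae")
  fit <- out$fit
  # the level-2 layers embedded in the level-3 chain equal the level-2 chain's
  n_pre <- 8L  # 6 encoder layers + flatten + standardize
  l2_in_l3 <- fit$chains$l3$layers[(n_pre + 1):(n_pre + 2)]
  l2_own <- fit$chains$l2$layers[(n_pre + 1):(n_pre + 2)]
  for (i in seq_along(l2_in_l3)) {
    expect_identical(l2_in_l3[[i]]$W, l2_own[[i]]$W)
    expect_identical(l2_in_l3[[i]]$b, l2_own[[i]]$b)
  }
  # the trunk is shared bit-identically by all three chains
  for (i in 1:6) {
    expect_identical(fit$chains$l1$layers[[i]]$W, fit$chains$l3$layers[[i]]$W)
  }
})

test_that("level-2 inputs react to trunk perturbations (no stale caches)", {
  out <- fit_small("cae")
  fit <- out$fit
  x <- out$cur$composites[, , , 1:3]
  p0 <- nn_predict(fit$chains$l2, x)
  fit$chains$l2$layers[[1]]$W <- fit$chains$l2$layers[[1]]$W + 0.5
  p1 <- nn_predict(fit$chains$l2, x)
  expect_false(identical(p0, p1))
})

test_that("fitting requires abnormal specimens for the deeper levels", {
  ds <- small_cohort(n = 12, size = 32, abnormal = 0, seed = 3)
  cur <- curate_dataset(ds, curation_config(size = 32))
  expect_error(
    mvskel_fit(cur$composites, cur$labels, default_tax, family = "cae",
               control = fit_control("cae",
                                     cae = train_config(1e-3, epochs = 2),
                                     cae_filters = c(4L, 8L))),
    "no abnormal"
  )
})

test_that("a trivially view-separable class is learned nearly perfectly", {
  # Morphology (stroke thickening) is plainly visible in the DV view; mixed
  # with the pelvic-nodule class it must be ranked almost perfectly among
  # abnormal test specimens
  prev <- c(Morphology = 0.5, Other = 0.5)
  cfg <- phantom_config(n_specimens = 120, image_size = c(64, 64),
                        abnormal_fraction = 0.5, prevalence = prev, seed = 19)
  ds <- generate_dataset(cfg, default_tax)
  cur <- curate_dataset(ds, curation_config(size = 64))
  sp <- make_splits(cur$labels, split_spec(), 19)
  ctl <- fit_control("cae",
                     cae = train_config(2e-3, epochs = 10, batch_size = 8),
                     l1 = train_config(1e-3, epochs = 30, batch_size = 16),
                     l2 = train_config(1e-3, epochs = 30, batch_size = 16),
                     l3 = train_config(1e-3, epochs = 30, batch_size = 16),
                     cae_filters = c(8L, 16L),
                     hp = head_hp(dense_widths = c(128L, 64L, 32L)))
  fit <- mvskel_fit(mvskel:::batch_select(cur$composites, sp$train),
                    cur$labels[sp$train], default_tax, family = "cae",
                    view = "DV", control = ctl, seed = 19,
                    xval = mvskel:::batch_select(cur$composites, sp$val),
                    labels_val = cur$labels[sp$val])
  pr <- predict(fit, mvskel:::batch_select(cur$composites, sp$test))
  te <- cur$labels[sp$test]
  y1 <- vapply(te, function(l) l$l1 == "abnormal", logical(1))
  expect_gt(roc_auc(pr$p_l1, y1), 0.9)
  abn <- which(y1)
  j <- which(default_tax$retained_l3 == "Morphology")
  y_morph <- vapply(te[abn], function(l) "Morphology" %in% l$l3_set, logical(1))
  expect_gt(roc_auc(pr$p_l3[abn, j], y_morph), 0.9)
})
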