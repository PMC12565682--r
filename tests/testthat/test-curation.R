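test_that("quality filtering applies the intensity and field-of-view rules", {
  base <- matrix(0.3, 64, 64)
  recs <- c(lapply(1:10, function(i) rec(paste0("s", i), "DV", base + i * 1e-3)),
            list(rec("white", "DV", matrix(1, 64, 64))))
  out <- filter_images(recs, quality_config(k = 3))
  expect_equal(length(out$kept), 10)
  expect_equal(out$log$specimen_id, "white")
  expect_equal(out$log$rule, "intensity-outlier")

  # zero-variance cohort: everything kept
  same <- lapply(1:5, function(i) rec(paste0("s", i), "DV", base))
  expect_equal(length(filter_images(same)$kept), 5)

  # square image outside a 1.5-3.0 aspect band
  sq <- list(rec("sq", "DV", matrix(0.5, 64, 64)))
  out2 <- filter_images(sq, quality_config(aspect_band = c(1.5, 3.0)))
  expect_equal(length(out2$kept), 0)
  expect_equal(out2$log$rule, "field-of-view")
})

test_that("resize_normalize resamples bilinearly and min-max normalizes", {
  const <- resize_normalize(matrix(0.5, 448, 448), c(224, 224))
  expect_equal(dim(const), c(224, 224))
  expect_true(all(const == 0))

  ramp <- matrix(rep(seq(0, 1, length.out = 336), each = 112), 112, 336)
  out <- resize_normalize(ramp, c(224, 224))
  expect_equal(dim(out), c(224, 224))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  expect_error(resize_normalize(matrix(1, 1, 1)), "degenerate")
})

test_that("specimen grouping keeps full-body pairs and logs the rest", {
  m <- matrix(0.5, 8, 8)
  recs <- list(rec("a", "DV", m), rec("a", "DV", m), rec("a", "LAT", m),
               rec("b", "DV", m),
               rec("c", "OTHER", m), rec("c", "DV", m), rec("c", "LAT", m))
  g <- group_by_specimen(recs)
  expect_setequal(names(g$groups), c("a", "c"))
  expect_equal(length(g$groups$a$DV), 2)
  expect_equal(length(g$groups$a$LAT), 1)
  expect_equal(g$excluded$specimen_id, "b")
  expect_match(g$excluded$reason, "missing-LAT")
  # the skull/other view did not contribute to c's group
  expect_equal(length(g$groups$c$DV), 1)
})

test_that("mean_view is the pixel-wise arithmetic mean", {
  a <- matrix(0.2, 4, 4); b <- matrix(0.4, 4, 4)
  expect_equal(mean_view(list(a, b)), matrix(0.3, 4, 4))
  expect_equal(mean_view(list(a)), a)
  expect_equal(mean_view(list(b, b, b)), b)
  expect_error(mean_view(list(a, matrix(0, 2, 2))), "shapes differ")
  expect_error(mean_view(list()), "at least one")
})

test_that("canny finds a single thin line on a step edge and ignores flats", {
  img <- matrix(0, 32, 32); img[, 17:32] <- 1
  e <- canny_edge_map(img, sigma = 1)
  cols <- unique(which(e == 1, arr.ind = TRUE)[, 2])
  expect_length(cols, 1)
  expect_equal(length(unique(which(e == 1, arr.ind = TRUE)[, 1])), 32)

  expect_true(all(canny_edge_map(matrix(0.7, 32, 32)) == 0))
  expect_error(canny_edge_map(img, low_threshold = 0.3, high_threshold = 0.2),
               "smaller")
})

test_that("canny is invariant to contrast inversion", {
  img <- matrix(0, 32, 32); img[, 17:32] <- 1
  expect_identical(canny_edge_map(img), canny_edge_map(1 - img))
  r <- render_view(mvskel:::normal_phantom(phantom_config(image_size = c(64, 64))),
                   "DV", phantom_config(image_size = c(64, 64)), noise = FALSE)
  expect_identical(canny_edge_map(r), canny_edge_map(1 - r))
})

test_that("edge cleaning removes components below the size threshold", {
  e <- matrix(0, 20, 20)
  e[5, 5:16] <- 1      # 12-pixel line
  e[15, 2:4] <- 1      # 3-pixel speck
  out <- clean_edges(e, min_size = 10)
  expect_equal(sum(out), 12)
  expect_true(all(out[5, 5:16] == 1))
})

test_that("edge blending is a clipped convex combination favouring DV", {
  dv <- matrix(1, 8, 8); lat <- matrix(0, 8, 8)
  expect_equal(blend_edges(dv, lat, w_dv = 1), dv)
  expect_equal(blend_edges(dv, dv, w_dv = 0.3), dv)
  expect_true(all(blend_edges(dv, lat, 0.6) == 0.6))
  expect_error(blend_edges(dv, matrix(0, 4, 4)), "shapes differ")
  # bounded by the max of binary inputs
  set.seed(1)
  a <- matrix(rbinom(64, 1, 0.3), 8, 8); b <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_true(all(blend_edges(a, b, 0.6) <= pmax(a, b)))
})

test_that("composites stack channels in the documented order with range checks", {
  d <- matrix(0.1, 8, 8); l <- matrix(0.2, 8, 8); e <- matrix(1, 8, 8)
  comp <- compose_multiview(d, l, e, "s1")
  expect_equal(dim(comp), c(8, 8, 3))
  expect_identical(comp[, , 1], d)
  expect_identical(comp[, , 2], l)
  expect_error(compose_multiview(d * 15, l, e, "s1"), "\\[0, 1\\]")
  z <- matrix(0, 8, 8)
  expect_silent(compose_multiview(z, z, z, "s0"))
})

test_that("curation is deterministic and preserves specimen counts", {
  ds <- small_cohort(n = 10, seed = 9)
  c1 <- curate_dataset(ds, curation_config(size = 64))
  c2 <- curate_dataset(ds, curation_config(size = 64))
  expect_identical(c1$composites, c2$composites)

  ids_with_full <- unique(vapply(ds$records, function(r) r$specimen_id, character(1)))
  expect_equal(length(c1$specimen_ids) + nrow(c1$exclusions) +
                 length(setdiff(ids_with_full,
                                c(c1$specimen_ids, c1$exclusions$specimen_id))),
               length(ids_with_full))
})

test_that("repeat acquisitions of one image reduce to that image in the composite", {
  # no noise or jitter: both acquisitions per view are identical, so the
  # mean-view channels must equal the normalized single renders
  cfg <- phantom_config(n_specimens = 3, image_size = c(64, 64),
                        abnormal_fraction = 0, noise_sigma = 0,
                        center_jitter = 0,
                        acquisitions_per_view = c(2L, 2L), seed = 4)
  ds <- generate_dataset(cfg, default_tax)
  cur <- curate_dataset(ds, curation_config(size = 64))
  id <- cur$specimen_ids[1]
  dv <- ds$records[[which(vapply(ds$records, function(r)
    r$specimen_id == id && r$view == "DV", logical(1)))[1]]]$pixels
  expect_equal(cur$composites[, , 1, 1], resize_normalize(dv, c(64, 64)),
               tolerance = 1e-12)
})
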