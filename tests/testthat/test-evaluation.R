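test_that("roc_auc reproduces the pairwise concordance oracle exactly", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_true(is.na(roc_auc(1:4, c(1, 1, 1, 1))))

  set.seed(10)
  for (i in 1:500) {
    n <- sample(2:30, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) labels[sample(n, 1)] <- 1 - labels[1]
    expect_identical(roc_auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("complement scores mirror the AUC for tie-free data", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    scores <- sample(seq_len(1000), n)  # distinct
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  }
})

test_that("per-level means skip flagged-missing classes", {
  expect_equal(as.numeric(per_level_mean_auc(c(0.8, 0.9, 1.0))), 0.9)
  expect_equal(as.numeric(per_level_mean_auc(0.7)), 0.7)
  m <- per_level_mean_auc(c(0.8, NA, 0.9))
  expect_equal(as.numeric(m), 0.85)
  expect_equal(attr(m, "n_skipped"), 1)
  expect_true(is.na(per_level_mean_auc(c(NA_real_, NA_real_))))
})

test_that("splits are stratified, exhaustive, disjoint and reproducible", {
  tax <- default_tax
  labels <- lapply(1:100, function(i) {
    codes <- if (i <= 30) "kyphosis" else character(0)
    specimen_union(list(codes), paste0("s", i), tax)
  })
  sp <- make_splits(labels, split_spec(), 42)
  expect_equal(lengths(sp), c(train = 70, val = 20, test = 10))
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), 1:100)
  # stratification keeps 30% abnormal in each split
  for (part in sp) {
    expect_equal(sum(part <= 30) / length(part), 0.3, tolerance = 0.01)
  }
  expect_identical(sp, make_splits(labels, split_spec(), 42))
  expect_false(identical(sp, make_splits(labels, split_spec(), 43)))

  tiny <- labels[c(1, 31:39)]  # one abnormal cannot fill three splits
  expect_error(make_splits(tiny, split_spec(), 1), "larger|more specimens")
})

test_that("reconstruction error is the plain per-pixel mean square", {
  a <- matrix(0, 8, 8); b <- matrix(1, 8, 8)
  expect_equal(reconstruction_mse(a, a), 0)
  expect_equal(reconstruction_mse(a, b), 1)
  expect_equal(reconstruction_mse(a, a + 0.5), 0.25)
  expect_error(reconstruction_mse(a, matrix(0, 4, 4)), "shapes differ")
})

test_that("SSIM matches its closed form on analytic fixtures", {
  set.seed(12)
  x <- matrix(stats::runif(400), 20, 20)
  expect_equal(reconstruction_ssim(x, x), 1.0)
  y <- matrix(stats::runif(400), 20, 20)
  expect_equal(reconstruction_ssim(x, y), reconstruction_ssim(y, x))

  # constant images: variance terms vanish, luminance term remains
  a <- 0.3; b <- 0.8
  expected <- (2 * a * b + 0.01^2) / (a^2 + b^2 + 0.01^2)
  expect_equal(reconstruction_ssim(matrix(a, 15, 15), matrix(b, 15, 15)),
               expected, tolerance = 1e-12)

  # a checkerboard against its negative: strong anticorrelation, SSIM < 0;
  # cross-check against an explicit per-window oracle
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_lt(reconstruction_ssim(cb, 1 - cb), 0)
  ssim_oracle <- function(a, b, w = 7, C1 = 1e-4, C2 = 9e-4) {
    vals <- c()
    for (i in 1:(nrow(a) - w + 1)) for (j in 1:(ncol(a) - w + 1)) {
      pa <- a[i:(i + w - 1), j:(j + w - 1)]
      pb <- b[i:(i + w - 1), j:(j + w - 1)]
      ma <- mean(pa); mb <- mean(pb)
      va <- mean(pa^2) - ma^2; vb <- mean(pb^2) - mb^2
      cab <- mean(pa * pb) - ma * mb
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                  ((ma^2 + mb^2 + C1) * (va + vb + C2)))
    }
    mean(vals)
  }
  expect_equal(reconstruction_ssim(cb, 1 - cb), ssim_oracle(cb, 1 - cb),
               tolerance = 1e-10)
  expect_equal(reconstruction_ssim(x, y), ssim_oracle(x, y), tolerance = 1e-10)

  expect_error(reconstruction_ssim(x, matrix(0, 4, 4)), "shapes differ")
  expect_error(reconstruction_ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("report aggregation reproduces hand-computed means and deviations", {
  raw <- expand.grid(seed = 1:3, view = c("DV", "MV"), level = "Level_2",
                     class = c("Spine", "Ribcage"), stringsAsFactors = FALSE)
  set.seed(13)
  raw$auc <- stats::runif(nrow(raw), 0.5, 1)
  rep <- mvskel:::build_report(raw)
  for (i in seq_len(nrow(rep$per_class))) {
    sub <- raw$auc[raw$view == rep$per_class$view[i] &
                     raw$class == rep$per_class$class[i]]
    expect_equal(rep$per_class$mean_auc[i], mean(sub))
    expect_equal(rep$per_class$sd_auc[i], stats::sd(sub))
  }
  # per-level means average the level's class AUCs within seed first
  for (v in c("DV", "MV")) {
    per_seed <- sapply(1:3, function(s) mean(raw$auc[raw$seed == s & raw$view == v]))
    expect_equal(rep$per_level$mean_auc[rep$per_level$view == v], mean(per_seed))
    expect_equal(rep$per_level$sd_auc[rep$per_level$view == v], stats::sd(per_seed))
  }
})

test_that("experiment reports carry the full row structure per view mode", {
  ds <- small_cohort(n = 40, size = 32, abnormal = 0.5, seed = 23)
  cur <- curate_dataset(ds, curation_config(size = 32))
  ctl <- fit_control("cae",
                     cae = train_config(2e-3, epochs = 3, batch_size = 8),
                     l1 = train_config(1e-3, epochs = 4),
                     l2 = train_config(1e-3, epochs = 4),
                     l3 = train_config(1e-3, epochs = 4),
                     cae_filters = c(4L, 8L),
                     hp = head_hp(dense_widths = c(32L, 16L, 8L)))
  rep <- run_experiment(cur, default_tax, family = "cae",
                        view_modes = c("DV", "MV"),
                        split = split_spec(seeds = c(5L, 6L)), control = ctl)
  expect_s3_class(rep, "mvskel_report")
  # 1 + 3 + 10 rows per view mode
  expect_equal(nrow(rep$per_class), 2 * 14)
  expect_equal(sort(unique(rep$raw$seed)), c(5, 6))
  expect_true(all(rep$per_class$mean_auc >= 0 & rep$per_class$mean_auc <= 1,
                  na.rm = TRUE))
  expect_true(all(rep$recon$ssim >= -1 & rep$recon$ssim <= 1))

  # rerun with identical seeds and config reproduces the report
  rep2 <- run_experiment(cur, default_tax, family = "cae",
                         view_modes = c("DV", "MV"),
                         split = split_spec(seeds = c(5L, 6L)), control = ctl)
  expect_identical(rep$raw, rep2$raw)

  tmp <- withr::local_tempdir()
  write_report(rep, tmp)
  expect_true(file.exists(file.path(tmp, "per_class_auc.csv")))
  expect_true(file.exists(file.path(tmp, "report.json")))
})
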