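# Evaluation protocol: stratified 70/20/10 splits repeated over seeds,
# threshold-free per-class AUC, per-level mean AUC, and reconstruction
# quality metrics for the autoencoder family.

#' Split specification
#'
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param seeds Distinct integer seeds; the experiment is repeated once per
#'   seed with a fresh split.
#' @param stratify_by Stratification variable; only level-1 stratification is
#'   implemented (it preserves the normal/abnormal imbalance in every split).
#' @export
split_spec <- function(fractions = c(train = 0.7, val = 0.2, test = 0.1),
                       seeds = c(101L, 102L, 103L, 104L, 105L),
                       stratify_by = "l1") {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3,
            !anyDuplicated(seeds), stratify_by == "l1")
  structure(list(fractions = fractions, seeds = as.integer(seeds),
                 stratify_by = stratify_by), class = "mvskel_split_spec")
}

# largest-remainder allocation of n items to the three fractions
allocate <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified train/validation/test split
#'
#' Splits specimens into disjoint, exhaustive train/validation/test sets,
#' stratified by the level-1 label, deterministically for a given seed.
#'
#' @param labels List of `mvskel_label`.
#' @param spec An [split_spec()].
#' @param seed Integer seed for this repetition.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
make_splits <- function(labels, spec = split_spec(), seed = spec$seeds[1]) {
  if (length(labels) < 10) stop("need at least 10 specimens to split")
  l1 <- vapply(labels, function(l) l$l1, character(1))
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (stratum in unique(l1)) {
    idx <- sample(which(l1 == stratum))
    sizes <- allocate(length(idx), spec$fractions)
    if (any(sizes == 0)) {
      stop("stratum '", stratum, "' is empty in one of the splits; ",
           "use more specimens or coarser fractions")
    }
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    out$val <- c(out$val, idx[sizes[1] + seq_len(sizes[2])])
    out$test <- c(out$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  lapply(out, sort)
}

#' Threshold-free ROC AUC
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Mean AUC over a level's classes
#'
#' Unweighted arithmetic mean over per-class AUCs, skipping flagged-missing
#' (`NA`) entries; the number skipped is attached as attribute `n_skipped`.
#'
#' @param aucs Numeric vector of per-class AUCs (may contain `NA`).
#' @return Mean AUC (or `NA` when all entries are missing).
#' @export
per_level_mean_auc <- function(aucs) {
  n_skip <- sum(is.na(aucs))
  out <- if (n_skip == length(aucs)) NA_real_ else mean(aucs, na.rm = TRUE)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Mean squared reconstruction error
#'
#' Mean of squared per-pixel differences over all pixels.
#'
#' @param x,x_rec Arrays of identical shape.
#' @export
reconstruction_mse <- function(x, x_rec) {
  if (!identical(dim(x) %||% length(x), dim(x_rec) %||% length(x_rec))) {
    stop("shapes differ")
  }
  mean((x - x_rec)^2)
}

# local window means over the valid region via integral images
local_mean <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1, W + 1)
  P[2:(H + 1), 2:(W + 1)] <- cs
  i <- 1:(H - w + 1); j <- 1:(W - w + 1)
  (P[i + w, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
     P[i + w, j, drop = FALSE] + P[i, j, drop = FALSE]) / (w * w)
}

#' Structural similarity (SSIM)
#'
#' Standard SSIM with a uniform 7x7 window, constants `k1 = 0.01`,
#' `k2 = 0.03` and dynamic range 1 (population variances, averaged over the
#' valid window positions).  Multichannel inputs are averaged channel-wise.
#'
#' @param x,x_rec Matrices or 3-D arrays in `[0, 1]` of identical shape.
#' @param window Window side length.
#' @param k1,k2 Stabilization constants.
#' @return SSIM in `[-1, 1]`.
#' @export
reconstruction_ssim <- function(x, x_rec, window = 7L, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(x), dim(x_rec))) stop("shapes differ")
  if (length(dim(x)) == 3) {
    return(mean(vapply(seq_len(dim(x)[3]), function(c) {
      reconstruction_ssim(x[, , c], x_rec[, , c], window, k1, k2)
    }, numeric(1))))
  }
  if (any(dim(x) < window)) stop("image smaller than the SSIM window")
  C1 <- (k1 * 1)^2; C2 <- (k2 * 1)^2
  mx <- local_mean(x, window); my <- local_mean(x_rec, window)
  sxx <- local_mean(x * x, window) - mx^2
  syy <- local_mean(x_rec * x_rec, window) - my^2
  sxy <- local_mean(x * x_rec, window) - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

#' Run the multi-seed single-view vs. multiview experiment
#'
#' For each seed and view mode: split specimens (stratified 70/20/10), fit
#' the hierarchy on the training split with the validation split driving
#' early stopping, score the held-out test split, and record per-class
#' threshold-free AUCs (level 1 on all test specimens; levels 2 and 3 on the
#' abnormal test specimens, matching the training population).  Classes
#' absent from a test split are flagged missing, not imputed.  For the CAE
#' family, test-set reconstruction MSE and SSIM are also recorded.
#'
#' @param curated An `mvskel_curated` (with labels).
#' @param taxonomy An `mvskel_taxonomy`.
#' @param family `"cae"` or `"backbone"`.
#' @param view_modes Subset of `c("DV", "LAT", "MV")`.
#' @param split An [split_spec()].
#' @param control An [fit_control()].
#' @param verbose Print progress.
#' @return An object of class `mvskel_report`.
#' @export
run_experiment <- function(curated, taxonomy, family = "cae",
                           view_modes = c("DV", "LAT", "MV"),
                           split = split_spec(),
                           control = fit_control(family),
                           verbose = FALSE) {
  x <- curated$composites; labels <- curated$labels
  rows <- list(); recon <- list(); k <- 0L; rk <- 0L
  for (seed in split$seeds) {
    sp <- make_splits(labels, split, seed)
    for (mode in view_modes) {
      if (verbose) message("seed ", seed, " view ", mode)
      fit <- mvskel_fit(batch_select(x, sp$train), labels[sp$train], taxonomy,
                        family = family, view = mode, control = control,
                        seed = seed,
                        xval = batch_select(x, sp$val), labels_val = labels[sp$val])
      xte <- batch_select(x, sp$test)
      pr <- predict(fit, xte)
      ym <- label_matrix(labels[sp$test], taxonomy)
      abn <- which(ym$y1[, 1] == 1)
      k <- k + 1L
      rows[[k]] <- data.frame(seed = seed, view = mode, level = "Level_1",
                              class = "Binary", auc = roc_auc(pr$p_l1, ym$y1[, 1]))
      for (j in seq_along(taxonomy$retained_l2)) {
        k <- k + 1L
        rows[[k]] <- data.frame(seed = seed, view = mode, level = "Level_2",
                                class = taxonomy$retained_l2[j],
                                auc = roc_auc(pr$p_l2[abn, j], ym$y2[abn, j]))
      }
      for (j in seq_along(taxonomy$retained_l3)) {
        k <- k + 1L
        rows[[k]] <- data.frame(seed = seed, view = mode, level = "Level_3",
                                class = taxonomy$retained_l3[j],
                                auc = roc_auc(pr$p_l3[abn, j], ym$y3[abn, j]))
      }
      if (family == "cae") {
        xv <- select_view(xte, mode)
        xr <- cae_reconstruct(fit$trunk, xv)
        nte <- dim(xv)[4]
        mses <- vapply(seq_len(nte), function(i) {
          reconstruction_mse(xv[, , , i], xr[, , , i])
        }, numeric(1))
        ssims <- vapply(seq_len(nte), function(i) {
          a <- array(xv[, , , i], dim(xv)[1:3])
          b <- array(xr[, , , i], dim(xr)[1:3])
          reconstruction_ssim(a, b)
        }, numeric(1))
        rk <- rk + 1L
        recon[[rk]] <- data.frame(seed = seed, view = mode,
                                  mse = mean(mses), ssim = mean(ssims))
      }
    }
  }
  raw <- do.call(rbind, rows)
  build_report(raw, if (rk) do.call(rbind, recon),
               list(family = family, view_modes = view_modes, split = split))
}

build_report <- function(raw, recon = NULL, settings = list()) {
  agg <- stats::aggregate(auc ~ view + level + class, data = raw,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v)),
                          na.action = stats::na.pass)
  per_class <- data.frame(level = agg$level, class = agg$class, view = agg$view,
                          mean_auc = agg$auc[, "mean"], sd_auc = agg$auc[, "sd"])
  # per-seed level means (classes with missing AUC skipped), then seed stats
  lm <- stats::aggregate(auc ~ seed + view + level, data = raw,
                         FUN = function(v) mean(v, na.rm = TRUE),
                         na.action = stats::na.pass)
  agg2 <- stats::aggregate(auc ~ view + level, data = lm,
                           FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  per_level <- data.frame(level = agg2$level, view = agg2$view,
                          mean_auc = agg2$auc[, "mean"], sd_auc = agg2$auc[, "sd"])
  structure(list(per_class = per_class, per_level = per_level,
                 recon = recon, raw = raw, settings = settings),
            class = "mvskel_report")
}

#' @export
print.mvskel_report <- function(x, digits = 3, ...) {
  cat("Hierarchical classification report (",
      length(unique(x$raw$seed)), " seeds)\n", sep = "")
  views <- unique(x$per_class$view)
  wide <- NULL
  for (v in views) {
    sub <- x$per_class[x$per_class$view == v, ]
    cols <- sub[, c("mean_auc", "sd_auc")]
    names(cols) <- paste0(v, c("_mean", "_sd"))
    wide <- if (is.null(wide)) cbind(sub[, c("level", "class")], cols)
            else cbind(wide, cols)
  }
  ord <- order(match(wide$level, c("Level_1", "Level_2", "Level_3")))
  print(format(wide[ord, ], digits = digits), row.names = FALSE)
  cat("\nPer-level mean AUC:\n")
  print(format(x$per_level, digits = digits), row.names = FALSE)
  if (!is.null(x$recon)) {
    cat("\nReconstruction (test split):\n")
    print(format(stats::aggregate(cbind(mse, ssim) ~ view, data = x$recon, FUN = mean),
                 digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes the per-class table as CSV, the full report (including per-seed raw
#' values) as JSON.
#'
#' @param report An `mvskel_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_class, file.path(dir, "per_class_auc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_level, file.path(dir, "per_level_auc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_class = report$per_class, per_level = report$per_level,
         recon = report$recon, raw = report$raw),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA, na = "null"
  )
  invisible(dir)
}

#' The standard phantom benchmark
#'
#' Simulates a balanced phantom cohort (600 specimens at 64x64, half
#' abnormal, six abnormality classes visible in exactly one view), curates it
#' into multiview composites, and runs the multi-seed experiment for the DV,
#' LAT and MV view modes.  This is the package's stand-in for large-scale
#' screens: the single-view-visible classes make the multiview advantage at
#' levels 2 and 3 measurable on synthetic data.
#'
#' @param taxonomy An `mvskel_taxonomy`.
#' @param seed Base seed; the generator uses it and the repetition seeds are
#'   `seed + 0:(n_seeds-1)`.
#' @param n_specimens,size Cohort size and render resolution.
#' @param n_seeds Number of split/training repetitions.
#' @param family Classifier family.
#' @param control Training control; the default trains the autoencoder with
#'   Adam at 0.002 (batch 8, at most 25 epochs) and the heads at 0.001
#'   (batch 16, at most 40/100/100 epochs for L1/L2/L3), all with patience
#'   3, and uses a 512-unit first hidden layer in the heads (the level-3
#'   head reads the level-2 first hidden representation, so its width
#'   bounds how much latent information survives the chain).  Sized for a
#'   few minutes on one CPU.
#' @param verbose Print progress.
#' @return An `mvskel_report`.
#' @export
phantom_benchmark <- function(taxonomy, seed = 11L, n_specimens = 600L,
                              size = 64L, n_seeds = 3L, family = "cae",
                              control = NULL, verbose = FALSE) {
  control <- control %||% fit_control(
    family,
    cae = train_config(learning_rate = 2e-3, epochs = 25L, batch_size = 8L),
    l1 = train_config(learning_rate = 1e-3, epochs = 40L, batch_size = 16L),
    l2 = train_config(learning_rate = 1e-3, epochs = 100L, batch_size = 16L),
    l3 = train_config(learning_rate = 1e-3, epochs = 100L, batch_size = 16L),
    cae_filters = c(8L, 16L),
    hp = head_hp(dense_widths = c(512L, 128L, 64L))
  )
  # spine-region abnormalities are kept individually rarer than the ribcage
  # and whole-body ones so that every level-2 class (including Spine, whose
  # six level-3 children would otherwise make it near-universal) has both
  # positives and negatives in abnormal test splits
  prev <- c(Caudal = 0.15, Thoracic = 0.15, Cervical = 0.15, Lumbar = 0.15,
            Morphology = 0.15, Shape = 0.15, Digits = 0.05, Fusion = 0.30,
            Joints = 0.30, Other = 0.30)
  cfg <- phantom_config(n_specimens = n_specimens, image_size = c(size, size),
                        abnormal_fraction = 0.5, prevalence = prev,
                        seed = seed)
  ds <- generate_dataset(cfg, taxonomy)
  cur <- curate_dataset(ds, curation_config(size = size))
  run_experiment(cur, taxonomy, family = family,
                 view_modes = c("DV", "LAT", "MV"),
                 split = split_spec(seeds = seed + seq_len(n_seeds) - 1L),
                 control = control, verbose = verbose)
}
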