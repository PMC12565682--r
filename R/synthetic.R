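# Phantom mouse-skeleton radiograph simulator.
#
# The generator emulates the *structure* of a multi-center whole-body X-ray
# phenotyping screen -- two full-body projections per specimen (dorsoventral
# and lateral, possibly several acquisitions each), strong normal/abnormal
# imbalance, multiple co-occurring abnormalities, per-center brightness
# variation -- not mouse anatomy or X-ray physics.  Crucially, each injected
# abnormality class has a *defined view visibility* (some edits displace
# geometry only in the coronal plane and are therefore invisible in the
# lateral projection, and vice versa), which is what makes single-view vs.
# multiview comparisons meaningful on simulated data.

# Representative ground-truth code emitted per injected level-3 class.
GEN_CLASS_CODES <- c(
  Caudal = "caudal-truncation",
  Thoracic = "thoracic-displacement",
  Cervical = "cervical-displacement",
  Lumbar = "lumbar-displacement",
  Morphology = "vertebral-morphology",
  Shape = "kyphosis",
  Digits = "syndactylism",
  Fusion = "rib-fusion",
  Joints = "joint-dislocation",
  Other = "pelvis-anomaly"
)

#' Phantom dataset configuration
#'
#' @param n_specimens Number of specimens to simulate.
#' @param image_size `(rows, cols)` of rendered views.
#' @param abnormal_fraction Probability that a specimen carries at least one
#'   abnormality.  The default mirrors the strong imbalance of real screens,
#'   where abnormal specimens are a small minority.
#' @param prevalence Named probabilities (per level-3 class) with which each
#'   abnormality is independently present in an abnormal specimen; several
#'   classes therefore co-occur frequently.
#' @param acquisitions_per_view Integer range `(min, max)` of acquisitions
#'   per view per specimen.
#' @param n_centers Number of simulated phenotyping centers (each gets a
#'   fixed brightness factor).
#' @param center_jitter Standard deviation of per-image log-brightness jitter.
#' @param noise_sigma Additive Gaussian pixel noise scale.
#' @param stroke_width Gaussian stroke radius in pixels at the 128-pixel
#'   reference scale (rescaled with image size).
#' @param seed Integer seed; regeneration with the same config is
#'   byte-identical.
#' @return A list of class `mvskel_phantom_config`.
#' @export
phantom_config <- function(n_specimens = 100L,
                           image_size = c(128L, 128L),
                           abnormal_fraction = 0.1,
                           prevalence = c(Caudal = 0.25, Thoracic = 0.25,
                                          Cervical = 0.25, Lumbar = 0.25,
                                          Morphology = 0.25, Shape = 0.25,
                                          Digits = 0.05, Fusion = 0.25,
                                          Joints = 0.25, Other = 0.25),
                           acquisitions_per_view = c(1L, 2L),
                           n_centers = 3L,
                           center_jitter = 0.1,
                           noise_sigma = 0.02,
                           stroke_width = 2.0,
                           seed = 1L) {
  stopifnot(n_specimens >= 1, abnormal_fraction >= 0, abnormal_fraction <= 1,
            all(prevalence >= 0), all(prevalence <= 1),
            length(image_size) == 2, all(image_size >= 32))
  structure(list(n_specimens = as.integer(n_specimens),
                 image_size = as.integer(image_size),
                 abnormal_fraction = abnormal_fraction,
                 prevalence = prevalence,
                 acquisitions_per_view = as.integer(acquisitions_per_view),
                 n_centers = as.integer(n_centers),
                 center_jitter = center_jitter,
                 noise_sigma = noise_sigma,
                 stroke_width = stroke_width,
                 seed = as.integer(seed)),
            class = "mvskel_phantom_config")
}

# A normal phantom with small individual geometric variation drawn from the
# current RNG stream.
normal_phantom <- function(config) {
  list(
    x_center = 0.5 + stats::runif(1, -0.02, 0.02),
    scale = stats::runif(1, 0.97, 1.03),
    stroke_sigma = config$stroke_width,
    sagittal_arch = stats::runif(1, 0.02, 0.035),
    coronal_wiggle = stats::runif(1, 0, 0.006),
    n_caudal = 12L,
    bumps = list(),
    kyphosis = 0,
    fused_ribs = FALSE, joint_gap = FALSE,
    digit_merge = FALSE, nodule = FALSE
  )
}

#' Inject an abnormality into a phantom
#'
#' Applies the deterministic geometric edit associated with a level-3 class.
#' Each edit has a fixed view visibility: coronal-plane displacements
#' (Cervical, Lumbar) only alter the dorsoventral render, sagittal-plane
#' displacements (Thoracic) and the kyphosis-like spinal curvature (Shape)
#' only alter the lateral render, rib fusion / limb-joint gaps / digit merges
#' live in the dorsoventral projection, and tail truncation (Caudal), stroke
#' thickening (Morphology) and the pelvic nodule (Other) are visible in both.
#'
#' @param phantom A phantom as produced by [sample_phantom()].
#' @param l3_class One of the level-3 class names.
#' @return The edited phantom.
#' @export
inject_abnormality <- function(phantom, l3_class) {
  switch(l3_class,
    Cervical = {
      phantom$bumps <- c(phantom$bumps,
                         list(list(plane = "coronal", center = 0.15, width = 0.045, amp = 0.07)))
    },
    Thoracic = {
      phantom$bumps <- c(phantom$bumps,
                         list(list(plane = "sagittal", center = 0.31, width = 0.06, amp = 0.07)))
    },
    Lumbar = {
      phantom$bumps <- c(phantom$bumps,
                         list(list(plane = "coronal", center = 0.51, width = 0.055, amp = 0.07)))
    },
    Caudal = phantom$n_caudal <- 6L,
    Morphology = phantom$stroke_sigma <- phantom$stroke_sigma * 1.9,
    Shape = phantom$kyphosis <- 0.09,
    Fusion = phantom$fused_ribs <- TRUE,
    Joints = phantom$joint_gap <- TRUE,
    Digits = phantom$digit_merge <- TRUE,
    Other = phantom$nodule <- TRUE,
    stop("unknown level-3 class: ", l3_class)
  )
  phantom
}

#' Sample a phantom and its ground-truth abnormality set
#'
#' With probability `abnormal_fraction` the phantom receives at least one
#' injected abnormality; classes are drawn independently per the configured
#' prevalences (so abnormalities co-occur), and a specimen that drew none is
#' assigned a single class sampled proportionally to prevalence.
#'
#' @param config An [phantom_config()] object.
#' @return List with `phantom`, `classes` (injected level-3 classes) and
#'   `codes` (ground-truth abnormality codes).
#' @export
sample_phantom <- function(config) {
  ph <- normal_phantom(config)
  classes <- character(0)
  if (stats::runif(1) < config$abnormal_fraction) {
    p <- config$prevalence
    hit <- stats::runif(length(p)) < p
    classes <- names(p)[hit]
    if (!length(classes)) {
      classes <- sample(names(p), 1L, prob = p)
    }
    for (cl in classes) ph <- inject_abnormality(ph, cl)
  }
  list(phantom = ph, classes = classes,
       codes = unname(GEN_CLASS_CODES[classes]))
}

# Spine offset (in the requested anatomical plane) as a function of
# normalized arclength s in [0, 1].
spine_offset <- function(phantom, s, plane) {
  off <- if (plane == "coronal") {
    phantom$coronal_wiggle * sin(3 * pi * s)
  } else {
    phantom$sagittal_arch * sin(pi * s) +
      phantom$kyphosis * exp(-((s - 0.40) / 0.16)^2)
  }
  for (b in phantom$bumps) {
    if (b$plane == plane) off <- off + b$amp * exp(-((s - b$center) / b$width)^2)
  }
  off
}

# Point cloud (u = horizontal, v = vertical, both in [0,1]) of a phantom's
# projection onto one plane.  DV = coronal projection, LAT = sagittal.
phantom_points <- function(phantom, view) {
  plane <- if (view == "DV") "coronal" else "sagittal"
  xc <- phantom$x_center
  sc <- phantom$scale
  v_of_s <- function(s) 0.14 + 0.80 * sc * s

  # spine + tail (tail = s > 0.66, truncated in proportion to caudal count)
  s_max <- 0.66 + 0.34 * phantom$n_caudal / 12
  s <- seq(0, s_max, length.out = 420)
  pts <- cbind(xc + spine_offset(phantom, s, plane), v_of_s(s))

  # skull outline (ellipse), both views
  t <- seq(0, 2 * pi, length.out = 90)
  a <- if (view == "DV") 0.065 * sc else 0.075 * sc
  b <- 0.045 * sc
  pts <- rbind(pts, cbind(xc + a * cos(t), 0.085 + b * sin(t)))

  if (view == "DV") {
    # ribs: arcs attached to the thoracic spine, coronal plane only
    rib_s <- seq(0.22, 0.40, length.out = 7)
    if (phantom$fused_ribs) {
      # merge pairs 2+3 and 4+5 into single arcs
      rib_s <- c(rib_s[1], mean(rib_s[2:3]), mean(rib_s[4:5]), rib_s[6], rib_s[7])
    }
    tt <- seq(0, 1, length.out = 45)
    for (sj in rib_s) {
      u0 <- xc + spine_offset(phantom, sj, "coronal")
      for (sgn in c(-1, 1)) {
        pts <- rbind(pts, cbind(u0 + sgn * (0.015 + 0.14 * sc * tt),
                                v_of_s(sj) + 0.05 * tt^1.5))
      }
    }
    # limbs (two segments + digits), coronal plane only
    limb <- function(s_attach, spread, drop) {
      u0 <- xc + spine_offset(phantom, s_attach, "coronal")
      v0 <- v_of_s(s_attach)
      out <- NULL
      for (sgn in c(-1, 1)) {
        joint <- c(u0 + sgn * spread * 0.6, v0 + drop * 0.4)
        paw <- c(u0 + sgn * spread, v0 + drop)
        seg <- function(p, q) {
          tt <- seq(0, 1, length.out = 60)
          cbind(p[1] + (q[1] - p[1]) * tt, p[2] + (q[2] - p[2]) * tt)
        }
        s1 <- seg(c(u0, v0), joint)
        s2 <- seg(joint, paw)
        if (phantom$joint_gap) {
          keep <- function(m) m[sqrt((m[, 1] - joint[1])^2 + (m[, 2] - joint[2])^2) > 0.022, , drop = FALSE]
          s1 <- keep(s1); s2 <- keep(s2)
        }
        out <- rbind(out, s1, s2)
        # digits fan out from the paw
        dig_t <- seq(0, 1, length.out = 18)
        if (phantom$digit_merge) {
          d <- cbind(paw[1] + sgn * 0.035 * dig_t, paw[2] + 0.012 * dig_t)
          out <- rbind(out, d, d + 0.002)  # double-stamped single digit
        } else {
          for (ang in c(-0.35, 0, 0.35)) {
            out <- rbind(out, cbind(paw[1] + sgn * 0.035 * dig_t * cos(ang),
                                    paw[2] + 0.035 * dig_t * sin(ang) + 0.008 * dig_t))
          }
        }
      }
      out
    }
    pts <- rbind(pts, limb(0.21, 0.18 * sc, 0.075), limb(0.60, 0.19 * sc, 0.10))
  }

  if (phantom$nodule) {
    off <- if (view == "DV") 0.07 else 0.05
    t <- seq(0, 2 * pi, length.out = 40)
    pts <- rbind(pts, cbind(xc + off + 0.016 * cos(t), 0.62 + 0.016 * sin(t)))
  }
  pts
}

#' Render one projection of a phantom
#'
#' Rasterizes the phantom's geometry for the requested plane (DV = coronal,
#' LAT = sagittal) as bright strokes on a dark background, smooths with a
#' Gaussian of the phantom's stroke width, applies a multiplicative
#' brightness factor (center effect and per-image jitter drawn from the
#' current RNG stream) and additive Gaussian noise, and clips to `[0, 1]`.
#'
#' @param phantom A phantom.
#' @param view `"DV"` or `"LAT"`.
#' @param config An [phantom_config()].
#' @param center_factor Fixed brightness multiplier of the simulated center.
#' @param noise If `FALSE`, the render is fully deterministic given the
#'   phantom (no jitter, no noise).
#' @return Matrix `(rows, cols)` of intensities in `[0, 1]`.
#' @export
render_view <- function(phantom, view, config, center_factor = 1, noise = TRUE) {
  H <- config$image_size[1]; W <- config$image_size[2]
  canvas <- matrix(0, H, W)
  pts <- phantom_points(phantom, view)
  row <- pmin(pmax(round(pts[, 2] * (H - 1)) + 1, 1), H)
  col <- pmin(pmax(round(pts[, 1] * (W - 1)) + 1, 1), W)
  canvas[cbind(row, col)] <- 1
  sigma <- phantom$stroke_sigma * min(H, W) / 128
  sm <- EBImage::gblur(canvas, sigma = sigma, boundary = 0)
  sm <- as.matrix(sm)
  if (max(sm) > 0) sm <- sm / max(sm) * 0.85
  if (noise) {
    fac <- center_factor * exp(stats::rnorm(1, 0, config$center_jitter))
    sm <- sm * fac + matrix(stats::rnorm(H * W, 0, config$noise_sigma), H, W)
  } else {
    sm <- sm * center_factor
  }
  pmin(pmax(sm, 0), 1)
}

#' Generate a phantom dataset
#'
#' Simulates `n_specimens` phantoms, renders one or more acquisitions of the
#' DV and LAT views for each, and assembles the metadata table, image records
#' and hierarchical specimen labels that the curation stage consumes.  Labels
#' are hierarchically consistent by construction (every injected level-3 code
#' carries its level-2 parent).
#'
#' @param config An [phantom_config()].
#' @param taxonomy An `mvskel_taxonomy`.
#' @param dir Optional output directory; when given, images are written as
#'   PNG, the metadata table as `metadata.csv`, and a provenance manifest as
#'   `manifest.yaml`.
#' @return An object of class `mvskel_dataset`: list with `metadata` (one row
#'   per image), `records` (list of image records with `specimen_id`, `view`,
#'   `pixels`), `labels` (list of `mvskel_label`), `truth` (list of injected
#'   level-3 classes per specimen) and `config`.
#' @export
generate_dataset <- function(config, taxonomy, dir = NULL) {
  set.seed(config$seed)
  centers <- stats::runif(config$n_centers, 0.85, 1.15)
  meta <- list(); records <- list(); labels <- list(); truth <- list()
  k <- 0L
  for (i in seq_len(config$n_specimens)) {
    id <- sprintf("SP%05d", i)
    center <- sample.int(config$n_centers, 1L)
    draw <- sample_phantom(config)
    rng <- config$acquisitions_per_view
    n_acq <- c(DV = sample(rng[1]:rng[2], 1L), LAT = sample(rng[1]:rng[2], 1L))
    for (view in c("DV", "LAT")) {
      for (a in seq_len(n_acq[[view]])) {
        k <- k + 1L
        px <- render_view(draw$phantom, view, config, centers[center])
        fname <- sprintf("%s_%s_%d.png", id, view, a)
        meta[[k]] <- data.frame(
          specimen_id = id, view = view, path = fname,
          codes = paste(draw$codes, collapse = ";"),
          center = sprintf("C%02d", center), stringsAsFactors = FALSE
        )
        records[[k]] <- list(specimen_id = id, view = view, pixels = px,
                             source_center = sprintf("C%02d", center))
      }
    }
    labels[[i]] <- specimen_union(list(draw$codes), id, taxonomy)
    truth[[i]] <- draw$classes
  }
  metadata <- do.call(rbind, meta)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(records)) {
      png::writePNG(records[[j]]$pixels, file.path(dir, metadata$path[j]))
    }
    utils::write.csv(metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
    yaml::write_yaml(list(generator = "mvskel phantom", seed = config$seed,
                          n_specimens = config$n_specimens,
                          image_size = config$image_size,
                          abnormal_fraction = config$abnormal_fraction),
                     file.path(dir, "manifest.yaml"))
  }
  structure(list(metadata = metadata, records = records, labels = labels,
                 truth = truth, config = config),
            class = "mvskel_dataset")
}

#' @export
print.mvskel_dataset <- function(x, ...) {
  n_ab <- sum(vapply(x$labels, function(l) l$l1 == "abnormal", logical(1)))
  cat("<mvskel_dataset> ", length(x$labels), " specimens (", n_ab, " abnormal), ",
      nrow(x$metadata), " images at ",
      paste(x$config$image_size, collapse = "x"), "\n", sep = "")
  invisible(x)
}
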