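# Specimen-wise multiview compact representation.
#
# Pipeline: quality filter -> resize + min-max normalize -> group per
# specimen (full-body DV/LAT only) -> per-view mean image -> Canny edge maps
# of the two means -> small-component cleaning -> weighted DV/LAT edge blend
# -> stack (mean-DV, mean-LAT, edge blend) into one 3-channel composite.

#' Quality-filter configuration
#'
#' @param k Intensity-outlier width: an image is rejected when its mean
#'   intensity falls outside `mean +/- k * sd` of its per-view cohort.
#' @param aspect_band Accepted `rows/cols` aspect-ratio band (field-of-view
#'   rule).
#' @return List of class `mvskel_quality_config`.
#' @export
quality_config <- function(k = 3, aspect_band = c(0.5, 2.0)) {
  stopifnot(k > 0, length(aspect_band) == 2, aspect_band[1] < aspect_band[2])
  structure(list(k = k, aspect_band = aspect_band), class = "mvskel_quality_config")
}

#' Filter out low-quality images
#'
#' Applies two rules per image: (a) intensity outlier -- mean intensity
#' outside `mean +/- k*sd` of its per-view cohort (zero-variance cohorts
#' reject nothing); (b) field of view -- aspect ratio outside the configured
#' band.  Every rejection is logged with the rule that fired.
#'
#' @param records List of image records (`specimen_id`, `view`, `pixels`).
#' @param quality An [quality_config()].
#' @return List with `kept` (records) and `log` (data frame of rejections).
#' @export
filter_images <- function(records, quality = quality_config()) {
  if (!length(records)) return(list(kept = records, log = rejection_log()))
  means <- vapply(records, function(r) mean(r$pixels), numeric(1))
  views <- vapply(records, function(r) r$view, character(1))
  aspect <- vapply(records, function(r) nrow(r$pixels) / ncol(r$pixels), numeric(1))
  reject <- character(length(records))
  for (v in unique(views)) {
    i <- which(views == v)
    mu <- mean(means[i]); sdv <- stats::sd(means[i])
    if (length(i) > 1 && is.finite(sdv) && sdv > 0) {
      out <- abs(means[i] - mu) > quality$k * sdv
      reject[i[out]] <- "intensity-outlier"
    }
  }
  fov <- aspect < quality$aspect_band[1] | aspect > quality$aspect_band[2]
  reject[fov & reject == ""] <- "field-of-view"
  bad <- which(reject != "")
  log <- rejection_log(
    specimen_id = vapply(records[bad], function(r) r$specimen_id, character(1)),
    view = views[bad], rule = reject[bad]
  )
  list(kept = records[reject == ""], log = log)
}

rejection_log <- function(specimen_id = character(0), view = character(0),
                          rule = character(0)) {
  data.frame(specimen_id = specimen_id, view = view, rule = rule,
             stringsAsFactors = FALSE)
}

#' Resize and normalize an image
#'
#' Bilinear resampling to the target size followed by min-max normalization
#' to `[0, 1]`; a constant image maps to all zeros.
#'
#' @param pixels Grayscale matrix.
#' @param size Target `(rows, cols)`.
#' @return Matrix of the target size with values in `[0, 1]`.
#' @export
resize_normalize <- function(pixels, size = c(224L, 224L)) {
  if (!is.matrix(pixels) || nrow(pixels) < 2 || ncol(pixels) < 2) {
    stop("image is degenerate (needs at least 2x2 pixels)")
  }
  out <- as.matrix(EBImage::resize(pixels, w = size[1], h = size[2]))
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0
}

#' Group image records by specimen
#'
#' Keeps full-body DV and LAT records only (other views are discarded) and
#' excludes specimens that lack either view, logging each exclusion.
#'
#' @param records List of image records.
#' @return List with `groups` (named list; per specimen a list with `DV` and
#'   `LAT` record lists) and `excluded` (data frame specimen_id, reason).
#' @export
group_by_specimen <- function(records) {
  views <- vapply(records, function(r) r$view, character(1))
  records <- records[views %in% c("DV", "LAT")]
  ids <- vapply(records, function(r) r$specimen_id, character(1))
  groups <- list(); excluded <- list()
  for (id in unique(ids)) {
    rs <- records[ids == id]
    vs <- vapply(rs, function(r) r$view, character(1))
    if (!all(c("DV", "LAT") %in% vs)) {
      excluded[[id]] <- data.frame(
        specimen_id = id,
        reason = paste0("missing-", paste(setdiff(c("DV", "LAT"), vs), collapse = "+")),
        stringsAsFactors = FALSE
      )
      next
    }
    groups[[id]] <- list(DV = rs[vs == "DV"], LAT = rs[vs == "LAT"])
  }
  list(groups = groups,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(specimen_id = character(0), reason = character(0)))
}

#' Pixel-wise mean of same-size images
#'
#' @param images List of matrices with identical dimensions.
#' @return Matrix of the common size.
#' @export
mean_view <- function(images) {
  if (!length(images)) stop("mean_view needs at least one image")
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) stop("mean_view: image shapes differ")
  }
  Reduce(`+`, images) / length(images)
}

# zero-padded neighbor shift of a matrix (dy, dx in pixels)
shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Canny edge map
#'
#' The standard pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, double thresholding
#' and hysteresis (weak edge pixels survive only in connected components that
#' contain a strong pixel).  Thresholds apply to the gradient magnitude of
#' `[0, 1]`-scaled intensities with unit-normalized Sobel kernels, so a full
#' 0-to-1 step edge has magnitude about 0.5.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param sigma Gaussian smoothing scale in pixels (0 disables smoothing).
#' @param low_threshold,high_threshold Hysteresis thresholds on the gradient
#'   magnitude.
#' @return Binary matrix (0/1) of the same size.
#' @export
canny_edge_map <- function(image, sigma = 1.0, low_threshold = 0.1,
                           high_threshold = 0.2) {
  if (low_threshold >= high_threshold) {
    stop("low_threshold must be smaller than high_threshold")
  }
  sm <- if (sigma > 0) {
    as.matrix(EBImage::gblur(image, sigma = sigma, boundary = "replicate"))
  } else image
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  ky <- t(kx)
  gx <- conv3x3(sm, kx)
  gy <- conv3x3(sm, ky)
  # rounding keeps exactly-symmetric inputs (e.g. an image and its negative)
  # on the same side of the suppression tie-breaks
  mag <- round(sqrt(gx^2 + gy^2), 12)

  # non-maximum suppression with 4 quantized directions; ties along a
  # two-pixel plateau keep the pixel on the positive-direction side only
  ang <- atan2(gy, gx) %% pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))  # 0:|, 1:/, 2:-, 3:\
  nms <- mag
  n1 <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  for (sct in 0:3) {
    d <- n1[[sct + 1]]
    a <- shift_mat(mag, d[1], d[2])
    b <- shift_mat(mag, -d[1], -d[2])
    sup <- (sector == sct) & (mag < a | mag <= b)
    nms[sup] <- 0
  }

  strong <- nms >= high_threshold
  weak <- nms >= low_threshold
  if (!any(strong)) return(matrix(0, nrow(image), ncol(image)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  out <- matrix(0, nrow(image), ncol(image))
  out[lab %in% keep[keep > 0]] <- 1
  out
}

# 3x3 'same' convolution with replicate padding (small helper for Sobel)
conv3x3 <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  mp <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  mp <- cbind(mp[, 1, drop = FALSE], mp, mp[, W, drop = FALSE])
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3) {
    if (k[i, j] != 0) out <- out + k[i, j] * mp[i:(i + H - 1), j:(j + W - 1)]
  }
  out
}

#' Remove small connected components from a binary edge map
#'
#' @param edges Binary matrix.
#' @param min_size Minimum component pixel count to keep.
#' @return Cleaned binary matrix.
#' @export
clean_edges <- function(edges, min_size = 10L) {
  if (min_size <= 1 || !any(edges > 0)) return(edges)
  lab <- EBImage::bwlabel(edges > 0)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_size)
  out <- edges
  out[lab %in% drop] <- 0
  out
}

#' Blend DV and LAT edge maps
#'
#' Convex combination `w_dv * dv + (1 - w_dv) * lat`, clipped to `[0, 1]`.
#' The default weight gives the dorsoventral view slightly more influence.
#'
#' @param dv_edges,lat_edges Same-size matrices in `[0, 1]`.
#' @param w_dv DV weight in `[0, 1]`.
#' @return Matrix in `[0, 1]`.
#' @export
blend_edges <- function(dv_edges, lat_edges, w_dv = 0.6) {
  if (!identical(dim(dv_edges), dim(lat_edges))) stop("edge map shapes differ")
  stopifnot(w_dv >= 0, w_dv <= 1)
  pmin(pmax(w_dv * dv_edges + (1 - w_dv) * lat_edges, 0), 1)
}

#' Stack the multiview composite
#'
#' Channel order is fixed: 1 = mean DV, 2 = mean LAT, 3 = blended edge map.
#'
#' @param mean_dv,mean_lat,edge_blend Same-size matrices in `[0, 1]`.
#' @param specimen_id Specimen identifier.
#' @param provenance Optional named counts of source images per view.
#' @return 3-D array `(rows, cols, 3)` of class `mvskel_composite`.
#' @export
compose_multiview <- function(mean_dv, mean_lat, edge_blend, specimen_id,
                              provenance = c(DV = NA_integer_, LAT = NA_integer_)) {
  chans <- list(mean_dv, mean_lat, edge_blend)
  d <- dim(mean_dv)
  for (ch in chans) {
    if (!identical(dim(ch), d)) stop("composite channels must share one shape")
    if (any(ch < 0 | ch > 1)) stop("composite channel values must lie in [0, 1]")
  }
  structure(array(c(mean_dv, mean_lat, edge_blend), c(d, 3L)),
            specimen_id = as.character(specimen_id),
            provenance = provenance,
            class = "mvskel_composite")
}

#' Curation parameters
#'
#' @param size Composite side length in pixels.
#' @param canny_sigma,canny_low,canny_high Canny parameters
#'   (see [canny_edge_map()]).
#' @param w_dv DV weight of the edge blend.
#' @param min_edge_component Minimum connected-component size kept by edge
#'   cleaning (pixels).
#' @param quality An [quality_config()].
#' @return List of class `mvskel_curation_config`.
#' @export
curation_config <- function(size = 224L, canny_sigma = 1.0, canny_low = 0.1,
                            canny_high = 0.2, w_dv = 0.6,
                            min_edge_component = 10L,
                            quality = quality_config()) {
  structure(list(size = as.integer(size), canny_sigma = canny_sigma,
                 canny_low = canny_low, canny_high = canny_high, w_dv = w_dv,
                 min_edge_component = as.integer(min_edge_component),
                 quality = quality),
            class = "mvskel_curation_config")
}

#' Build specimen-wise multiview composites
#'
#' Runs the full curation pipeline over a set of image records: quality
#' filtering, resize + normalization, per-specimen grouping (full-body views
#' only), per-view means, Canny edge maps of the mean images, edge cleaning,
#' weighted blending and channel stacking.
#'
#' @param dataset An `mvskel_dataset` (or a bare list of image records).
#' @param config An [curation_config()].
#' @return List of class `mvskel_curated`: `composites` array
#'   `(size, size, 3, n)`, `specimen_ids`, `labels` (when the input carries
#'   labels, subset and ordered to match), `provenance` (per-specimen view
#'   counts), `rejections` and `exclusions` logs.
#' @export
curate_dataset <- function(dataset, config = curation_config()) {
  records <- if (inherits(dataset, "mvskel_dataset")) dataset$records else dataset
  filt <- filter_images(records, config$quality)
  kept <- lapply(filt$kept, function(r) {
    r$pixels <- resize_normalize(r$pixels, c(config$size, config$size))
    r
  })
  grp <- group_by_specimen(kept)
  ids <- names(grp$groups)
  n <- length(ids)
  comps <- array(0, c(config$size, config$size, 3L, n))
  prov <- matrix(0L, n, 2, dimnames = list(ids, c("DV", "LAT")))
  for (i in seq_len(n)) {
    g <- grp$groups[[i]]
    mdv <- mean_view(lapply(g$DV, `[[`, "pixels"))
    mlat <- mean_view(lapply(g$LAT, `[[`, "pixels"))
    edv <- clean_edges(canny_edge_map(mdv, config$canny_sigma, config$canny_low,
                                      config$canny_high), config$min_edge_component)
    elat <- clean_edges(canny_edge_map(mlat, config$canny_sigma, config$canny_low,
                                       config$canny_high), config$min_edge_component)
    blend <- blend_edges(edv, elat, config$w_dv)
    comps[, , , i] <- compose_multiview(mdv, mlat, blend, ids[i])
    prov[i, ] <- c(length(g$DV), length(g$LAT))
  }
  labels <- NULL
  if (inherits(dataset, "mvskel_dataset")) {
    lab_ids <- vapply(dataset$labels, function(l) l$specimen_id, character(1))
    labels <- dataset$labels[match(ids, lab_ids)]
  }
  structure(list(composites = comps, specimen_ids = ids, labels = labels,
                 provenance = prov, rejections = filt$log,
                 exclusions = grp$excluded, config = config),
            class = "mvskel_curated")
}

#' @export
print.mvskel_curated <- function(x, ...) {
  cat("<mvskel_curated> ", length(x$specimen_ids), " composites (",
      x$config$size, "x", x$config$size, "x3); ",
      nrow(x$rejections), " images rejected, ",
      nrow(x$exclusions), " specimens excluded\n", sep = "")
  invisible(x)
}
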