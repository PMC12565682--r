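# Readers and writers for the artifact formats: CSV metadata tables (one row
# per image; semicolon-separated abnormality codes), PNG/TIFF grayscale
# images, composite PNGs with sidecar manifests, YAML run configuration and
# provenance records.

#' Read an image metadata table
#'
#' Expects a CSV with header and columns `specimen_id`, `view`, `path`,
#' `codes` (semicolon-separated abnormality codes; empty for a normal
#' image).  View strings are normalized case-insensitively: `dv` maps to DV,
#' `lat`/`lv` to LAT, anything else to OTHER (with a warning).
#'
#' @param path CSV path.
#' @return Data frame with normalized `view` and a `codes_list` list-column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(specimen_id = "character"))
  required <- c("specimen_id", "view", "path", "codes")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  v <- toupper(trimws(df$view))
  v[v == "LV"] <- "LAT"
  unknown <- !(v %in% c("DV", "LAT", "SKULL", "FORELIMBS", "HINDLIMBS", "OTHER"))
  if (any(unknown)) {
    warning("unknown view string(s) mapped to OTHER: ",
            paste(unique(df$view[unknown]), collapse = ", "))
    v[unknown] <- "OTHER"
  }
  v[!(v %in% c("DV", "LAT"))] <- "OTHER"
  df$view <- v
  df$codes <- as.character(df$codes)
  df$codes[is.na(df$codes)] <- ""
  df$codes_list <- lapply(df$codes, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    trimws(parts[nzchar(trimws(parts))])
  })
  df
}

#' Write an image metadata table
#'
#' @param df Data frame as returned by [read_metadata()] (the `codes_list`
#'   column, if present, is serialized back into `codes`).
#' @param path Output CSV path.
#' @export
write_metadata <- function(df, path) {
  if (!is.null(df$codes_list)) {
    df$codes <- vapply(df$codes_list, paste, character(1), collapse = ";")
    df$codes_list <- NULL
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a grayscale image
#'
#' Reads PNG (8- or 16-bit; `png` scales both to `[0, 1]`) or TIFF.  Color
#' images are collapsed to grayscale by channel averaging.
#'
#' @param path Image path.
#' @return Matrix of intensities in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("the 'tiff' package is needed for TIFF input")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  pmin(pmax(img, 0), 1)
}

#' Load image records described by a metadata table
#'
#' @param metadata Data frame from [read_metadata()].
#' @param root Directory that `path` entries are relative to.
#' @param on_missing `"skip"` (log and drop) or `"error"`.
#' @return List with `records` and `skipped` (character paths).
#' @export
load_image_records <- function(metadata, root = ".", on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  records <- list(); skipped <- character(0); k <- 0L
  for (i in seq_len(nrow(metadata))) {
    p <- file.path(root, metadata$path[i])
    if (!file.exists(p)) {
      if (on_missing == "error") stop("image not found: ", p)
      skipped <- c(skipped, p)
      next
    }
    k <- k + 1L
    records[[k]] <- list(specimen_id = metadata$specimen_id[i],
                         view = metadata$view[i],
                         pixels = load_image(p))
  }
  list(records = records, skipped = skipped)
}

#' Write curated composites and their manifest
#'
#' Each composite is written as a 3-channel PNG; the sidecar `manifest.csv`
#' records specimen id, the 13-slot label vector and the per-view source
#' image counts.
#'
#' @param curated An `mvskel_curated`.
#' @param dir Output directory.
#' @export
write_composites <- function(curated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- curated$specimen_ids
  vecs <- NULL
  for (i in seq_along(ids)) {
    png::writePNG(curated$composites[, , , i],
                  file.path(dir, paste0(ids[i], "_mv.png")))
  }
  if (!is.null(curated$labels)) {
    vecs <- t(vapply(curated$labels, function(l) l$vector, integer(13)))
  }
  man <- data.frame(specimen_id = ids,
                    n_dv = curated$provenance[, "DV"],
                    n_lat = curated$provenance[, "LAT"])
  if (!is.null(vecs)) man$label_vector <- apply(vecs, 1, paste, collapse = "")
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read or write a run configuration
#'
#' Run configurations are YAML files mirroring the training hyperparameter
#' sheet (optimizer, loss, epochs, learning rate, batch size, patience) plus
#' curation and split settings.
#'
#' @param path YAML path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config A list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a provenance record for a run
#'
#' Records the configuration, its MD5 hash, the seed and package version, so
#' a run's outputs can be reproduced from the record alone.
#'
#' @param dir Output directory.
#' @param config A list (run configuration).
#' @param seed The run seed.
#' @export
write_provenance <- function(dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile()
  yaml::write_yaml(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  yaml::write_yaml(
    list(config = config, config_md5 = hash, seed = seed,
         package_version = as.character(utils::packageVersion("mvskel")),
         r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "provenance.yaml")
  )
  invisible(file.path(dir, "provenance.yaml"))
}
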