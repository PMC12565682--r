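#' @useDynLib mvskel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Full codomains of the two subclass mappings.  The level-3 ordering follows
# the order the classes are introduced in and fixes the slots of the encoded
# label vector, so it must never be reordered silently.
C2_FULL <- c("Limbs", "Ribcage", "Skull", "Spine", "Whole-body")
C3_FULL <- c("Caudal", "Thoracic", "Cervical", "Lumbar", "Morphology",
             "Shape", "Digits", "Fusion", "Joints", "Other")

# Default retained classes for modeling: Skull and Limbs carry too few
# abnormal specimens in whole-body screens and are excluded from levels 2/3
# (specimens whose only findings are Skull/Limbs stay level-1 abnormal).
RETAINED_L2_DEFAULT <- c("Spine", "Ribcage", "Whole-body")
RETAINED_L3_DEFAULT <- C3_FULL

#' Load an abnormality taxonomy
#'
#' A taxonomy maps each expert abnormality code to its level-2 anatomical
#' subclass (one of Limbs, Ribcage, Skull, Spine, Whole-body) and its level-3
#' specific subclass (one of Caudal, Thoracic, Cervical, Lumbar, Morphology,
#' Shape, Digits, Fusion, Joints, Other).  The bundled default is a synthetic
#' 53-code catalogue covering every subclass member typically annotated in
#' whole-body mouse phenotyping screens.
#'
#' @param path Path to a taxonomy CSV with columns `code`, `name`, `l2`, `l3`.
#'   `NULL` (default) loads the bundled default taxonomy.
#' @param retained_l2,retained_l3 Ordered character vectors of the level-2 and
#'   level-3 classes retained for modeling.  Their lengths define the label
#'   vector length (3 + 10 = 13 by default), and their order defines its slots.
#' @return An object of class `mvskel_taxonomy`: a list with elements `codes`
#'   (data frame), `retained_l2` and `retained_l3`.
#' @examples
#' tax <- load_taxonomy()
#' nrow(tax$codes)      # 53
#' tax$retained_l2      # Spine, Ribcage, Whole-body
#' @export
load_taxonomy <- function(path = NULL,
                          retained_l2 = RETAINED_L2_DEFAULT,
                          retained_l3 = RETAINED_L3_DEFAULT) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_taxonomy.csv", package = "mvskel")
  }
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  codes <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_taxonomy(codes, retained_l2, retained_l3)
}

#' Construct and validate a taxonomy
#'
#' @param codes Data frame with columns `code`, `name`, `l2`, `l3`.
#' @inheritParams load_taxonomy
#' @return An `mvskel_taxonomy` object.
#' @export
new_taxonomy <- function(codes,
                         retained_l2 = RETAINED_L2_DEFAULT,
                         retained_l3 = RETAINED_L3_DEFAULT) {
  required <- c("code", "name", "l2", "l3")
  missing_cols <- setdiff(required, names(codes))
  if (length(missing_cols)) {
    stop("taxonomy is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(codes) == 0L) stop("taxonomy must be nonempty")
  dup <- codes$code[duplicated(codes$code)]
  if (length(dup)) stop("duplicate taxonomy code(s): ", paste(unique(dup), collapse = ", "))
  bad2 <- !(codes$l2 %in% C2_FULL)
  if (any(bad2)) {
    stop("unknown level-2 subclass '", codes$l2[bad2][1L], "' for code '",
         codes$code[bad2][1L], "'")
  }
  bad3 <- !(codes$l3 %in% C3_FULL)
  if (any(bad3)) {
    stop("unknown level-3 subclass '", codes$l3[bad3][1L], "' for code '",
         codes$code[bad3][1L], "'")
  }
  if (!all(retained_l2 %in% C2_FULL)) stop("retained_l2 must be a subset of the level-2 codomain")
  if (!all(retained_l3 %in% C3_FULL)) stop("retained_l3 must be a subset of the level-3 codomain")
  if (anyDuplicated(retained_l2) || anyDuplicated(retained_l3)) {
    stop("retained class lists must not contain duplicates")
  }
  structure(
    list(codes = codes[, required], retained_l2 = retained_l2, retained_l3 = retained_l3),
    class = "mvskel_taxonomy"
  )
}

#' @export
print.mvskel_taxonomy <- function(x, ...) {
  cat("<mvskel_taxonomy> ", nrow(x$codes), " abnormality codes\n", sep = "")
  cat("  retained level-2 classes: ", paste(x$retained_l2, collapse = ", "), "\n", sep = "")
  cat("  retained level-3 classes: ", paste(x$retained_l3, collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_codes <- function(codes, taxonomy) {
  unknown <- setdiff(codes, taxonomy$codes$code)
  if (length(unknown)) {
    stop("unknown abnormality code(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Top-level (level-1) label of an abnormality set
#'
#' A specimen or image is `"abnormal"` if at least one expert abnormality code
#' is present and `"normal"` otherwise.
#'
#' @param codes Character vector of abnormality codes (possibly empty).
#' @param taxonomy An `mvskel_taxonomy`.
#' @return `"abnormal"` or `"normal"`.
#' @export
assign_l1 <- function(codes, taxonomy) {
  check_codes(codes, taxonomy)
  if (length(codes) >= 1L) "abnormal" else "normal"
}

#' Level-2 image of an abnormality set
#'
#' Maps each code to its anatomical subclass and returns the set image, in
#' canonical codomain order.  The empty set maps to the empty set.
#'
#' @inheritParams assign_l1
#' @return Character vector, a subset of the level-2 codomain.
#' @export
map_l2 <- function(codes, taxonomy) {
  check_codes(codes, taxonomy)
  m <- taxonomy$codes$l2[match(codes, taxonomy$codes$code)]
  C2_FULL[C2_FULL %in% m]
}

#' Level-3 image of an abnormality set
#'
#' @inheritParams assign_l1
#' @return Character vector, a subset of the level-3 codomain.
#' @export
map_l3 <- function(codes, taxonomy) {
  check_codes(codes, taxonomy)
  m <- taxonomy$codes$l3[match(codes, taxonomy$codes$code)]
  C3_FULL[C3_FULL %in% m]
}

# Codes whose level-2 class is retained.  Level-2/3 bits are only contributed
# by retained codes; this guarantees that a set level-3 bit always has a set
# level-2 parent bit.
retained_codes <- function(codes, taxonomy) {
  l2 <- taxonomy$codes$l2[match(codes, taxonomy$codes$code)]
  codes[l2 %in% taxonomy$retained_l2]
}

#' Specimen-wise hierarchical label from per-image labels
#'
#' A specimen's abnormality set is the union of the abnormality sets of all
#' its images.  Level-1 is derived from the full union; the level-2 and
#' level-3 sets only receive contributions from codes whose level-2 class is
#' retained (by default Skull and Limbs findings keep a specimen level-1
#' abnormal but contribute no level-2/3 bits).
#'
#' @param image_codes List of character vectors, one per image of the
#'   specimen (empty vector for a normal image).
#' @param specimen_id Specimen identifier.
#' @param taxonomy An `mvskel_taxonomy`.
#' @return An object of class `mvskel_label`: list with `specimen_id`,
#'   `codes`, `l1`, `l2_set`, `l3_set`, and the encoded binary `vector`.
#' @export
specimen_union <- function(image_codes, specimen_id, taxonomy) {
  if (!is.list(image_codes) || length(image_codes) == 0L) {
    stop("specimen has no images")
  }
  codes <- unique(unlist(image_codes, use.names = FALSE))
  codes <- as.character(codes[!is.na(codes) & nzchar(codes)])
  check_codes(codes, taxonomy)
  kept <- retained_codes(codes, taxonomy)
  l2_set <- intersect(map_l2(kept, taxonomy), taxonomy$retained_l2)
  l2_set <- taxonomy$retained_l2[taxonomy$retained_l2 %in% l2_set]
  l3_set <- intersect(map_l3(kept, taxonomy), taxonomy$retained_l3)
  l3_set <- taxonomy$retained_l3[taxonomy$retained_l3 %in% l3_set]
  lab <- structure(
    list(specimen_id = as.character(specimen_id), codes = codes,
         l1 = assign_l1(codes, taxonomy), l2_set = l2_set, l3_set = l3_set,
         vector = NULL),
    class = "mvskel_label"
  )
  lab$vector <- encode_label_vector(lab, taxonomy)
  lab
}

#' @export
print.mvskel_label <- function(x, ...) {
  cat("<mvskel_label> specimen ", x$specimen_id, ": ", x$l1, "\n", sep = "")
  if (x$l1 == "abnormal") {
    cat("  codes:  ", paste(x$codes, collapse = ", "), "\n", sep = "")
    cat("  level2: ", if (length(x$l2_set)) paste(x$l2_set, collapse = ", ") else "(none retained)", "\n", sep = "")
    cat("  level3: ", if (length(x$l3_set)) paste(x$l3_set, collapse = ", ") else "(none retained)", "\n", sep = "")
  }
  invisible(x)
}

#' Encode a hierarchical label as a binary vector
#'
#' The vector has one slot per retained level-2 class followed by one slot per
#' retained level-3 class (length 13 under the defaults).  A normal specimen
#' encodes to all zeros.
#'
#' @param label An `mvskel_label` (or any list with `l2_set`/`l3_set`).
#' @param taxonomy An `mvskel_taxonomy`.
#' @return Named integer vector of 0/1 of length
#'   `length(retained_l2) + length(retained_l3)`.
#' @export
encode_label_vector <- function(label, taxonomy) {
  if (!all(label$l2_set %in% taxonomy$retained_l2)) {
    stop("label level-2 set is not a subset of the retained level-2 classes")
  }
  if (!all(label$l3_set %in% taxonomy$retained_l3)) {
    stop("label level-3 set is not a subset of the retained level-3 classes")
  }
  v <- c(as.integer(taxonomy$retained_l2 %in% label$l2_set),
         as.integer(taxonomy$retained_l3 %in% label$l3_set))
  names(v) <- c(paste0("L2:", taxonomy$retained_l2), paste0("L3:", taxonomy$retained_l3))
  v
}

#' Decode a binary label vector
#'
#' Inverse of [encode_label_vector()]: recovers the level-2 and level-3 class
#' sets from the 13-slot vector.
#'
#' @param vec Binary vector as produced by [encode_label_vector()].
#' @param taxonomy An `mvskel_taxonomy`.
#' @return List with `l2_set` and `l3_set`.
#' @export
decode_label_vector <- function(vec, taxonomy) {
  n2 <- length(taxonomy$retained_l2)
  n3 <- length(taxonomy$retained_l3)
  if (length(vec) != n2 + n3) {
    stop("label vector has length ", length(vec), ", expected ", n2 + n3)
  }
  list(l2_set = taxonomy$retained_l2[vec[seq_len(n2)] != 0],
       l3_set = taxonomy$retained_l3[vec[n2 + seq_len(n3)] != 0])
}

#' Summarize a labeled specimen set
#'
#' Counts specimens per distinct level-2 class combination among the abnormal
#' specimens, sorted by descending count, together with abnormal and normal
#' totals.
#'
#' @param labels List of `mvskel_label` objects.
#' @return A data frame of class `mvskel_summary` with columns `l1`,
#'   `l2_combination`, `n`, and attributes `total_abnormal`, `total_normal`.
#' @export
summarize_dataset <- function(labels) {
  l1 <- vapply(labels, function(l) l$l1, character(1))
  abn <- labels[l1 == "abnormal"]
  combo <- vapply(abn, function(l) {
    if (length(l$l2_set)) paste0("[", paste(l$l2_set, collapse = ", "), "]") else "[]"
  }, character(1))
  tab <- if (length(combo)) sort(table(combo), decreasing = TRUE) else table(character(0))
  out <- data.frame(
    l1 = rep("Abnormal", length(tab)),
    l2_combination = names(tab),
    n = as.integer(tab),
    stringsAsFactors = FALSE
  )
  attr(out, "total_abnormal") <- length(abn)
  attr(out, "total_normal") <- sum(l1 == "normal")
  class(out) <- c("mvskel_summary", "data.frame")
  out
}

#' @export
print.mvskel_summary <- function(x, ...) {
  cat("Specimen-wise dataset summary\n")
  print.data.frame(x, row.names = FALSE)
  cat("Total abnormal:", attr(x, "total_abnormal"),
      " Total normal:", attr(x, "total_normal"), "\n")
  invisible(x)
}

#' Write a dataset summary as delimited text
#'
#' @param x An `mvskel_summary`.
#' @param path Output CSV path.
#' @export
write_summary <- function(x, path) {
  out <- rbind(
    x[, c("l1", "l2_combination", "n")],
    data.frame(l1 = "Total Abnormal count", l2_combination = "-",
               n = attr(x, "total_abnormal"))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Expand a level-2 combination count table into specimen labels
#'
#' Published specimen inventories are often reported as counts per level-2
#' class combination (e.g. 601 specimens labeled `[Spine]`).  This helper
#' materializes such a table as individual specimen labels (picking one
#' representative code per class) so that it can be fed through
#' [summarize_dataset()] and the rest of the label algebra.
#'
#' @param counts Data frame with columns `l2_combination`
#'   (semicolon-separated retained level-2 class names) and `n`.
#' @param taxonomy An `mvskel_taxonomy`.
#' @return List of `mvskel_label` objects, one per specimen.
#' @export
labels_from_combination_counts <- function(counts, taxonomy) {
  rep_code <- function(cls) {
    # first taxonomy code of that level-2 class
    taxonomy$codes$code[match(cls, taxonomy$codes$l2)]
  }
  labels <- list()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    classes <- strsplit(counts$l2_combination[i], ";", fixed = TRUE)[[1]]
    classes <- trimws(classes)
    codes <- rep_code(classes)
    if (anyNA(codes)) stop("no taxonomy code for class: ",
                           paste(classes[is.na(codes)], collapse = ", "))
    for (j in seq_len(counts$n[i])) {
      k <- k + 1L
      labels[[k]] <- specimen_union(list(codes), sprintf("s%06d", k), taxonomy)
    }
  }
  labels
}

#' Full-body view selection totals
#'
#' Given a per-view image inventory (one row per acquisition view with image
#' and abnormality counts), applies the "full-body views only" selection used
#' to build specimen-wise multiview datasets and returns the retained totals.
#'
#' @param view_counts Data frame with columns `view`, `n_images`,
#'   `n_abnormalities`.  Views whose name starts with "Full body" are retained.
#' @return List with `n_images` and `n_abnormalities` totals of the retained
#'   (full-body) views.
#' @export
select_fullbody_views <- function(view_counts) {
  required <- c("view", "n_images", "n_abnormalities")
  missing_cols <- setdiff(required, names(view_counts))
  if (length(missing_cols)) {
    stop("view_counts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- grepl("^full[ -]?body", view_counts$view, ignore.case = TRUE)
  list(n_images = sum(view_counts$n_images[keep]),
       n_abnormalities = sum(view_counts$n_abnormalities[keep]))
}
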