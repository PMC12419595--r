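# Pair-list and image IO plus run configuration. The canonical input is a
# CSV pair list (kin_type, parent_path, child_path, label, fold) next to a
# directory of pre-aligned 64x64 grayscale face crops; no numerics live
# here.

PAIR_COLUMNS <- c("kin_type", "parent_path", "child_path", "label", "fold")

validate_pair_list <- function(df) {
  missing <- setdiff(PAIR_COLUMNS, names(df))
  if (length(missing)) {
    stopf("pair list is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  bad <- which(!(df$kin_type %in% KIN_TYPES))
  if (length(bad)) {
    stopf("unknown kin_type '%s' in row %d", df$kin_type[bad[1]], bad[1])
  }
  bad <- which(!(df$label %in% c(-1, 1)))
  if (length(bad)) {
    stopf("label must be +1 or -1 (row %d has %s)", bad[1],
          df$label[bad[1]])
  }
  bad <- which(!(df$fold %in% 1:5))
  if (length(bad)) {
    stopf("fold must lie in 1..5 (row %d has %s)", bad[1], df$fold[bad[1]])
  }
  df
}

#' Read a pair-list CSV
#'
#' Reads and validates the canonical pairing metadata: one row per
#' parent-child pair with columns `kin_type` (FS/FD/MS/MD),
#' `parent_path`, `child_path`, `label` (+1/-1) and `fold` (1..5). Row
#' order is preserved. Image paths are validated lazily at load time.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `pair_list`.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stopf("pair list '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_pair_list(df)
  df$label <- as.integer(df$label)
  df$fold <- as.integer(df$fold)
  class(df) <- c("pair_list", "data.frame")
  df
}

#' Write a pair-list CSV
#'
#' Inverse of [read_pair_list]; the round-trip is lossless for any valid
#' pair list.
#'
#' @param records A validated pair-list data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(records, path) {
  validate_pair_list(records)
  utils::write.csv(records[, PAIR_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load an aligned 64x64 grayscale face image
#'
#' Reads a PNG (or, when the EBImage package is available, a JPEG),
#' converts color inputs to grayscale by the standard luma weighting
#' 0.299 R + 0.587 G + 0.114 B, and returns intensities in `[0, 255]`.
#' Images that are not exactly 64x64 are rejected rather than resized,
#' since silent resizing would change the descriptor geometry.
#'
#' @param path Path to the image file.
#' @return 64x64 numeric matrix.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("image '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stopf("reading JPEG requires the EBImage package")
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  } else {
    stopf("unsupported image format '%s'", ext)
  }
  if (length(dim(a)) == 3) {
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  img <- a * 255
  if (nrow(img) != 64 || ncol(img) != 64) {
    stopf("expected a 64x64 image, got %dx%d: %s", nrow(img), ncol(img),
          path)
  }
  img
}

#' Split a pair list into training and test folds
#'
#' The test set is exactly the records assigned to `test_fold`; the
#' training set is the complement. Together they partition the input.
#'
#' @param records A pair-list data frame.
#' @param test_fold Fold index held out for testing.
#' @return List with elements `train` and `test`.
#' @export
split_folds <- function(records, test_fold) {
  is_test <- records$fold == test_fold
  if (!any(is_test)) stopf("test fold %d is empty", test_fold)
  list(train = records[!is_test, , drop = FALSE],
       test = records[is_test, , drop = FALSE])
}

#' Read a run configuration file
#'
#' Reads a YAML configuration; keys under `train` are passed to
#' [train_config], everything else (feature kind, PCA dimension, paths)
#' is returned as-is.
#'
#' @param path Path to a YAML file.
#' @return List with the raw configuration plus a `train` element already
#'   converted to a [train_config].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$train)) cfg$train <- do.call(train_config, cfg$train)
  cfg
}

#' Extract descriptors for every record of a pair list
#'
#' Runs the configured descriptor ([extract_block_lbp] or
#' [extract_grid_sift]) over the parent and child image of every record.
#'
#' @param records A pair-list data frame.
#' @param image_dir Directory that the pair-list paths are relative to
#'   (`""` for absolute paths).
#' @param feature `"lbp"` or `"sift"`.
#' @return List with matrices `parent` and `child` (one descriptor per
#'   row) and the `records` metadata.
#' @export
extract_pair_features <- function(records, image_dir = "",
                                  feature = c("lbp", "sift")) {
  feature <- match.arg(feature)
  fn <- if (feature == "lbp") extract_block_lbp else extract_grid_sift
  path_of <- function(p) if (nzchar(image_dir)) file.path(image_dir, p) else p
  desc <- function(paths) {
    t(vapply(paths, function(p) fn(load_image(path_of(p))),
             numeric(if (feature == "lbp") 4096 else 6272)))
  }
  list(parent = desc(records$parent_path),
       child = desc(records$child_path),
       records = records)
}

#' Assemble per-type tasks from a pair list and its features
#'
#' @param features Output of [extract_pair_features] (or any list with
#'   `parent`, `child`, `records`).
#' @return Named list of [task_data] objects, one per kin type present.
#' @export
pairs_to_tasks <- function(features) {
  rec <- features$records
  types <- intersect(KIN_TYPES, unique(rec$kin_type))
  out <- lapply(types, function(tt) {
    i <- which(rec$kin_type == tt)
    task_data(tt, features$parent[i, , drop = FALSE],
              features$child[i, , drop = FALSE],
              rec$label[i], rec$fold[i])
  })
  names(out) <- types
  out
}
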