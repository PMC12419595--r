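#' Labeled feature pairs of one kinship type
#'
#' Bundles all labeled parent-child feature pairs of a single kinship type:
#' a parent feature matrix, a child feature matrix (row i of each forming
#' pair i), pair labels in \{+1, -1\}, and optional cross-validation fold
#' assignments.
#'
#' @param kin_type One of `"FS"`, `"FD"`, `"MS"`, `"MD"`.
#' @param parent,child Numeric matrices of identical dimension, one row per
#'   pair, one column per feature.
#' @param label Numeric vector of +1 (kin) / -1 (not kin), one per pair.
#' @param fold Optional integer vector of fold assignments in `1..5`.
#'
#' @return An object of class `task_data` with fields `kin_type`, `parent`,
#'   `child`, `label`, `fold`, `d` (feature dimension) and `n` (pair count).
#' @export
task_data <- function(kin_type, parent, child, label, fold = NULL) {
  if (!is.character(kin_type) || length(kin_type) != 1L ||
      !(kin_type %in% KIN_TYPES)) {
    stopf("kin_type must be one of %s", paste(KIN_TYPES, collapse = ", "))
  }
  parent <- check_matrix(as.matrix(parent), "parent")
  child <- check_matrix(as.matrix(child), "child")
  if (!identical(dim(parent), dim(child))) {
    stopf("parent and child matrices must have identical dimensions")
  }
  label <- as.numeric(label)
  if (length(label) != nrow(parent)) {
    stopf("need one label per pair (%d pairs, %d labels)",
          nrow(parent), length(label))
  }
  if (!all(label %in% c(-1, 1))) {
    stopf("labels must be +1 or -1")
  }
  if (!is.null(fold)) {
    fold <- as.integer(fold)
    if (length(fold) != nrow(parent) || any(fold < 1L)) {
      stopf("fold must assign a positive fold index to every pair")
    }
  }
  structure(
    list(kin_type = kin_type, parent = parent, child = child,
         label = label, fold = fold, d = ncol(parent), n = nrow(parent)),
    class = "task_data"
  )
}

#' @export
print.task_data <- function(x, ...) {
  cat(sprintf("task_data <%s>: %d pairs (%d positive), d = %d\n",
              x$kin_type, x$n, sum(x$label == 1), x$d))
  invisible(x)
}

# Row subset of a task, keeping fold labels aligned.
subset_task <- function(task, idx) {
  task_data(task$kin_type,
            task$parent[idx, , drop = FALSE],
            task$child[idx, , drop = FALSE],
            task$label[idx],
            if (!is.null(task$fold)) task$fold[idx])
}

check_trainable <- function(task) {
  if (sum(task$label == 1) < 1L || sum(task$label == -1) < 1L) {
    stopf("task %s needs at least one positive and one negative pair",
          task$kin_type)
  }
  invisible(task)
}
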