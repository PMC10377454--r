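#' Binary symptom dataset
#'
#' The unit of all estimation: an `n x p` matrix of 0/1 symptom indicators
#' with unique symptom labels and a group identifier.
#'
#' @param matrix Integer/numeric matrix with entries in {0, 1}, no missing
#'   values.
#' @param labels Symptom names (defaults to the matrix column names).
#' @param group Group identifier string (e.g. `"MDE"`).
#' @return An object of class `symptom_dataset` with elements `matrix`,
#'   `labels`, `group` and `n`.
#' @export
symptom_dataset <- function(matrix, labels = colnames(matrix), group = "all") {
  m <- as.matrix(matrix)
  if (is.null(labels)) stop("symptom labels are required")
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop("one label per column required")
  if (anyDuplicated(labels)) stop("symptom labels must be unique")
  if (ncol(m) < 2) stop("need at least 2 symptoms")
  if (anyNA(m)) stop("missing values are not allowed")
  if (!all(m %in% c(0, 1))) stop("entries must be 0 or 1")
  storage.mode(m) <- "integer"
  colnames(m) <- labels
  rownames(m) <- NULL
  structure(list(matrix = m, labels = labels, group = as.character(group)[1],
                 n = nrow(m)),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat("Symptom dataset '", x$group, "': ", x$n, " participants x ",
      length(x$labels), " binary symptoms\n", sep = "")
  cat("  endorsement: ",
      paste(sprintf("%s %.2f", x$labels, colMeans(x$matrix)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read and write symptom cohorts as CSV
#'
#' The on-disk format is one row per participant: the symptom columns (0/1)
#' plus a `group` column. `write_cohort_csv()` accepts a single dataset or a
#' list of datasets sharing the same labels; `read_cohort_csv()` splits on
#' `group` and returns a named list of [symptom_dataset] objects.
#'
#' @param cohort A [symptom_dataset] or list of them.
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a named list of datasets.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (inherits(cohort, "symptom_dataset")) cohort <- list(cohort)
  labels <- cohort[[1]]$labels
  for (d in cohort) {
    stopifnot(inherits(d, "symptom_dataset"))
    if (!identical(d$labels, labels))
      stop("all groups must share the same symptom labels and order")
  }
  df <- do.call(rbind, lapply(cohort, function(d) {
    out <- as.data.frame(d$matrix)
    out$group <- d$group
    out
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"group" %in% names(df)) stop("cohort CSV must contain a 'group' column")
  labels <- setdiff(names(df), "group")
  groups <- unique(df$group)
  out <- lapply(groups, function(g) {
    symptom_dataset(as.matrix(df[df$group == g, labels, drop = FALSE]),
                    labels = labels, group = g)
  })
  names(out) <- groups
  out
}
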