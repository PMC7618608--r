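#' Build a validated annotation set of vocal elements
#'
#' An annotation set is the package's element inventory: one row per segmented
#' vocal element, with onset/offset times in seconds, a class label, and the
#' identifiers needed for stratified inference (individual, recording).
#' Records are sorted by `(recording, onset)` and validated: onsets are
#' non-negative, every offset exceeds its onset, and intervals within one
#' recording do not overlap. Class labels are opaque, case-sensitive strings;
#' missing labels are mapped to the sentinel class `"unlabeled"`.
#'
#' @param onset,offset numeric vectors of element boundaries, in seconds.
#'   Intervals are half-open `[onset, offset)`; onsets are the quantity used
#'   by all downstream interval analyses.
#' @param element_class character vector of class labels (recycled); `NA` or
#'   empty entries become `"unlabeled"`.
#' @param individual,recording identifiers (recycled).
#' @param provenance optional character scalar recording where the data came
#'   from (file and tier), stored as an attribute.
#' @return A data frame of class `"annotation_set"` with columns `recording`,
#'   `individual`, `onset`, `offset`, `element_class`.
#' @examples
#' annotation_set(onset = c(0, 0.2), offset = c(0.1, 0.35),
#'                element_class = c("click", "noisy"), individual = "b1")
#' @export
annotation_set <- function(onset, offset, element_class = NULL,
                           individual = "unknown", recording = "rec1",
                           provenance = NULL) {
  n <- length(onset)
  if (length(offset) != n) stop("onset and offset must have equal length")
  if (is.null(element_class)) element_class <- rep("unlabeled", n)
  element_class <- as.character(rep_len(element_class, max(n, 0L)))
  element_class[is.na(element_class) | element_class == ""] <- "unlabeled"
  a <- data.frame(
    recording = as.character(rep_len(recording, max(n, 0L))),
    individual = as.character(rep_len(individual, max(n, 0L))),
    onset = as.numeric(onset),
    offset = as.numeric(offset),
    element_class = element_class,
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    a <- a[0L, ]
  }
  a <- a[order(a$recording, a$onset), , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("annotation_set", "data.frame")
  attr(a, "provenance") <- provenance
  validate_annotation_set(a)
}

#' Validate annotation set invariants
#'
#' @param a an object coercible to an annotation set.
#' @return `a`, invisibly unchanged, or an error describing every offending
#'   row (zero/negative durations, negative onsets, overlapping intervals).
#' @export
validate_annotation_set <- function(a) {
  req <- c("recording", "individual", "onset", "offset", "element_class")
  missing_cols <- setdiff(req, names(a))
  if (length(missing_cols)) {
    stop("annotation set lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(a) == 0L) return(a)
  bad <- which(!(a$offset > a$onset))
  if (length(bad)) {
    stop("offset must exceed onset; offending rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (any(a$onset < 0)) {
    stop("negative onsets in rows: ",
         paste(utils::head(which(a$onset < 0), 10L), collapse = ", "))
  }
  for (rec in unique(a$recording)) {
    x <- a[a$recording == rec, , drop = FALSE]
    if (nrow(x) > 1L && any(x$onset[-1L] < x$offset[-nrow(x)] - 1e-12)) {
      stop("overlapping element intervals in recording '", rec, "'")
    }
  }
  a
}

#' Read a tabular element file (CSV/TSV) into an annotation set
#'
#' The delimiter is taken from the file extension (`.tsv`/`.tab` means tab,
#' anything else comma) unless `sep` is given. Column names are configurable
#' through `cols`; a missing class column yields the `"unlabeled"` sentinel,
#' and a missing recording column falls back to the file name.
#'
#' @param path path to a delimited text file with a header row.
#' @param cols named character vector mapping the roles `onset`, `offset`,
#'   `class`, `individual`, `recording` to column names in the file.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return An [annotation_set()].
#' @export
read_element_table <- function(path,
                               cols = c(onset = "onset", offset = "offset",
                                        class = "class",
                                        individual = "individual",
                                        recording = "recording"),
                               sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- cols[c("onset", "offset")]
  if (!all(need %in% names(d))) {
    stop("element table must contain columns: ", paste(need, collapse = ", "))
  }
  pick <- function(role, default) {
    nm <- if (role %in% names(cols)) cols[[role]] else NA_character_
    if (!is.na(nm) && nm %in% names(d)) d[[nm]] else default
  }
  annotation_set(
    onset = as.numeric(d[[cols[["onset"]]]]),
    offset = as.numeric(d[[cols[["offset"]]]]),
    element_class = pick("class", NULL),
    individual = pick("individual", "unknown"),
    recording = pick("recording", basename(path)),
    provenance = path
  )
}

#' Write an annotation set to a delimited element table
#'
#' @param a an [annotation_set()].
#' @param path output file path; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_element_table <- function(a, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  d <- as.data.frame(a)
  names(d)[names(d) == "element_class"] <- "class"
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d elements, %d recording(s), %d individual(s)\n",
              nrow(x), length(unique(x$recording)),
              length(unique(x$individual))))
  if (nrow(x)) {
    cat(sprintf("  time span %.3f-%.3f s; classes: %s\n",
                min(x$onset), max(x$offset),
                paste(sort(unique(x$element_class)), collapse = ", ")))
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}
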