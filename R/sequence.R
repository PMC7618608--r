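#' Group elements into vocal bouts by a silence threshold
#'
#' A bout is a maximal run of elements whose inter-element silences (next
#' onset minus current offset) are strictly below `silence_threshold`; a gap
#' exactly equal to the threshold splits. Singleton bouts are allowed. Bouts
#' never span recordings. Inter-onset intervals and ratios exist only within
#' bouts.
#'
#' @param a an [annotation_set()].
#' @param silence_threshold silence cut-off in seconds (250 ms is the
#'   budgerigar default of the analysis pipeline, 500 ms the human one).
#' @return `a` with an added integer column `bout` (global bout index,
#'   increasing in time within each recording).
#' @export
group_bouts <- function(a, silence_threshold = 0.25) {
  validate_annotation_set(a)
  if (!nrow(a)) {
    a$bout <- integer(0)
    return(a)
  }
  # bouts are cut independently within each recording x individual stream
  key <- paste(a$recording, a$individual, sep = "\r")
  bout <- integer(nrow(a))
  counter <- 0L
  for (idx in split(seq_len(nrow(a)), factor(key, levels = unique(key)))) {
    gap <- c(Inf, a$onset[idx][-1L] - a$offset[idx][-length(idx)])
    local_bout <- cumsum(gap >= silence_threshold)
    bout[idx] <- counter + local_bout
    counter <- counter + max(local_bout)
  }
  a$bout <- bout
  attr(a, "silence_threshold") <- silence_threshold
  a
}

#' Inter-onset intervals of one bout
#'
#' @param onset increasing element onset times of a single bout, seconds.
#' @param element_class class labels aligned with `onset` (optional).
#' @return data frame with one row per IOI: `value` (s), `position` (k, the
#'   index of the terminating element minus one), `class_prev` and
#'   `class_next` (the flanking element classes, the ordered pair label).
#' @export
compute_iois <- function(onset, element_class = NULL) {
  n <- length(onset)
  if (n >= 2L && any(diff(onset) <= 0)) {
    stop("onsets must be strictly increasing within a bout")
  }
  if (is.null(element_class)) element_class <- rep("unlabeled", n)
  if (n < 2L) {
    return(data.frame(value = numeric(0), position = integer(0),
                      class_prev = character(0), class_next = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(value = diff(onset), position = seq_len(n - 1L),
             class_prev = element_class[-n], class_next = element_class[-1L],
             stringsAsFactors = FALSE)
}

#' Revised inter-onset-interval ratio
#'
#' For an ordered sequence of IOIs within one bout, the ratio at step `k` is
#' `IOI_k / (IOI_k + IOI_{k-1})`: the current interval over the sum of the
#' current and the *previous* interval, so the metric describes each event
#' relative to what preceded it. Values lie strictly in (0, 1): 0.5 is
#' isochrony (1:1), 2/3 a short-long (1:2) pair, 1/3 a long-short (2:1)
#' pair; above 0.5 means local deceleration, below 0.5 acceleration.
#'
#' @param iois positive IOI values in bout order; ratios are never computed
#'   across bout boundaries, so pass one bout at a time.
#' @return numeric vector of `length(iois) - 1` ratios (empty if fewer than
#'   two IOIs).
#' @seealso [mirror_ratio()] for the legacy forward-looking definition.
#' @export
ioi_ratio <- function(iois) {
  if (any(!is.finite(iois) | iois <= 0)) {
    stop("IOIs must be positive and finite")
  }
  n <- length(iois)
  if (n < 2L) return(numeric(0))
  iois[-1L] / (iois[-1L] + iois[-n])
}

#' Mirror between the revised and the legacy IOI-ratio
#'
#' The earlier literature defined the ratio against the *next* interval; on
#' the same interval pair the two definitions are mirror images:
#' `legacy = 1 - revised`. The mapping is an involution and leaves 0.5
#' (isochrony) fixed.
#'
#' @param r ratio value(s) strictly inside (0, 1).
#' @return `1 - r`.
#' @export
mirror_ratio <- function(r) {
  if (any(!is.finite(r) | r <= 0 | r >= 1)) {
    stop("ratios must lie strictly in (0, 1)")
  }
  1 - r
}

#' Assemble the full rhythm dataset: bouts, IOIs, ratios, strata
#'
#' Splits an annotation set into bouts per individual, derives all IOIs with
#' their stratum labels (individual and ordered flanking element classes)
#' and all revised IOI-ratios, and records the index bookkeeping that the
#' permutation machinery needs. A bout of `n` elements yields `max(0, n-1)`
#' IOIs and `max(0, n-2)` ratios.
#'
#' @param a an [annotation_set()] (typically cleaned).
#' @param silence_threshold bout silence cut-off in seconds.
#' @return list of class `"rhythm_dataset"` with components
#'   \describe{
#'     \item{elements}{the bout-annotated element table}
#'     \item{bouts}{per-bout summary (size, individual, recording)}
#'     \item{iois}{IOI table: `value`, `bout`, `position`, `individual`,
#'       `class_prev`, `class_next`}
#'     \item{ratios}{ratio table: `value`, `bout`, `position`, `individual`,
#'       and the row indices `i_prev`, `i_cur` of the two constituent IOIs}
#'     \item{summary}{per-individual element/bout/IOI/ratio counts}
#'   }
#' @export
build_dataset <- function(a, silence_threshold = 0.25) {
  a <- group_bouts(a, silence_threshold)
  n_el <- nrow(a)
  if (n_el == 0L) {
    empty <- build_dataset_empty(silence_threshold)
    return(empty)
  }
  bf <- factor(a$bout, levels = unique(a$bout))  # keep time order, not lexical
  bout_sizes <- tapply(rep(1L, n_el), bf, sum)
  bouts <- data.frame(
    bout = as.integer(names(bout_sizes)),
    n_elements = as.integer(bout_sizes),
    individual = as.character(tapply(a$individual, bf, `[`, 1L)),
    recording = as.character(tapply(a$recording, bf, `[`, 1L)),
    stringsAsFactors = FALSE
  )
  rownames(bouts) <- NULL
  ioi_list <- lapply(split(seq_len(n_el), bf), function(idx) {
    d <- compute_iois(a$onset[idx], a$element_class[idx])
    if (nrow(d)) {
      d$bout <- a$bout[idx[1L]]
      d$individual <- a$individual[idx[1L]]
    }
    d
  })
  iois <- do.call(rbind, ioi_list[vapply(ioi_list, nrow, 0L) > 0])
  if (is.null(iois)) {
    iois <- data.frame(value = numeric(0), position = integer(0),
                       class_prev = character(0), class_next = character(0),
                       bout = integer(0), individual = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(iois) <- NULL
  # ratio index pairs: consecutive IOI rows of the same bout
  nio <- nrow(iois)
  if (nio >= 2L) {
    same_bout <- iois$bout[-1L] == iois$bout[-nio]
    i_cur <- which(same_bout) + 1L
    i_prev <- i_cur - 1L
  } else {
    i_cur <- i_prev <- integer(0)
  }
  ratios <- data.frame(
    value = iois$value[i_cur] / (iois$value[i_cur] + iois$value[i_prev]),
    bout = iois$bout[i_cur],
    position = iois$position[i_cur],
    individual = iois$individual[i_cur],
    i_prev = i_prev, i_cur = i_cur,
    stringsAsFactors = FALSE
  )
  ds <- list(elements = a, bouts = bouts, iois = iois, ratios = ratios,
             silence_threshold = silence_threshold)
  ds$summary <- dataset_summary(ds)
  class(ds) <- "rhythm_dataset"
  ds
}

build_dataset_empty <- function(silence_threshold) {
  a <- annotation_set(numeric(0), numeric(0))
  a$bout <- integer(0)
  ds <- list(
    elements = a,
    bouts = data.frame(bout = integer(0), n_elements = integer(0),
                       individual = character(0), recording = character(0)),
    iois = data.frame(value = numeric(0), position = integer(0),
                      class_prev = character(0), class_next = character(0),
                      bout = integer(0), individual = character(0)),
    ratios = data.frame(value = numeric(0), bout = integer(0),
                        position = integer(0), individual = character(0),
                        i_prev = integer(0), i_cur = integer(0)),
    silence_threshold = silence_threshold
  )
  ds$summary <- dataset_summary(ds)
  class(ds) <- "rhythm_dataset"
  ds
}

#' Per-individual bookkeeping summary of a rhythm dataset
#'
#' @param ds a [build_dataset()] result.
#' @return data frame with one row per individual: element, bout, IOI and
#'   ratio counts and mean elements per bout.
#' @export
dataset_summary <- function(ds) {
  ind <- sort(unique(ds$elements$individual))
  if (!length(ind)) {
    return(data.frame(individual = character(0), n_elements = integer(0),
                      n_bouts = integer(0), mean_elements_per_bout = numeric(0),
                      n_iois = integer(0), n_ratios = integer(0)))
  }
  do.call(rbind, lapply(ind, function(i) {
    nb <- sum(ds$bouts$individual == i)
    ne <- sum(ds$elements$individual == i)
    data.frame(individual = i, n_elements = ne, n_bouts = nb,
               mean_elements_per_bout = if (nb) ne / nb else NA_real_,
               n_iois = sum(ds$iois$individual == i),
               n_ratios = sum(ds$ratios$individual == i),
               stringsAsFactors = FALSE)
  }))
}

# Stratum key per IOI row under the three stratification modes.
stratum_keys <- function(iois, stratum_mode = c("pair", "initiating_class",
                                               "individual_only")) {
  stratum_mode <- match.arg(stratum_mode)
  switch(stratum_mode,
    pair = paste(iois$individual, iois$class_prev, iois$class_next,
                 sep = "\r"),
    initiating_class = paste(iois$individual, iois$class_prev, sep = "\r"),
    individual_only = iois$individual
  )
}

#' @export
print.rhythm_dataset <- function(x, ...) {
  cat(sprintf(
    "<rhythm_dataset> %d elements, %d bouts (mean %.2f el/bout), %d IOIs, %d ratios\n",
    nrow(x$elements), nrow(x$bouts),
    if (nrow(x$bouts)) nrow(x$elements) / nrow(x$bouts) else NA,
    nrow(x$iois), nrow(x$ratios)))
  cat(sprintf("  bout silence threshold: %g s; individuals: %s\n",
              x$silence_threshold,
              paste(unique(x$elements$individual), collapse = ", ")))
  invisible(x)
}
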