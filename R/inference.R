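#' Configuration of the permutation rhythm test
#'
#' @param n_permutations number of stratified permutations of the IOI
#'   sequence (default 10,000). Must be at least `1/alpha` so the rejection
#'   quantile is estimable.
#' @param alpha significance level of the maximal-deviation test (default
#'   0.01).
#' @param kde_bandwidth Gaussian kernel bandwidth in ratio units (default
#'   0.01).
#' @param grid_size number of density evaluation points on \[0, 1\]
#'   (default 512).
#' @param stratum_mode exchangeability stratum of the null: `"pair"`
#'   (individual x ordered flanking element classes, the default),
#'   `"initiating_class"` (individual x class of the initiating element) or
#'   `"individual_only"` (used for data without class labels).
#' @param rng_seed master seed; per-permutation streams are derived from it
#'   deterministically, so results are reproducible.
#' @param ci_quantiles lower/upper probabilities of the pointwise permutation
#'   confidence band (default `c(0.005, 0.995)`, a 99% band).
#' @param include_observed logical; whether the observed density enters the
#'   pointwise mean/SD of the null ensemble. Default `FALSE` (permutations
#'   only), the statistically cleaner choice; at 10,000 permutations the two
#'   conventions are numerically indistinguishable.
#' @param within_bout logical; restrict permutation strata to within-bout
#'   shuffles (default `FALSE`: IOIs are exchanged across bouts within a
#'   stratum, positions and bout structure staying fixed).
#' @param band_type `"pointwise"` (default) or `"global"` (a constant
#'   max-envelope band at the test-statistic height).
#' @param subset_rule for pair-restricted analyses: `"both"` (default;
#'   a ratio qualifies if both constituent IOIs carry the pair label) or
#'   `"either"`.
#' @return list of class `"inference_config"`.
#' @export
inference_config <- function(n_permutations = 10000, alpha = 0.01,
                             kde_bandwidth = 0.01, grid_size = 512,
                             stratum_mode = c("pair", "initiating_class",
                                              "individual_only"),
                             rng_seed = 1L,
                             ci_quantiles = c(0.005, 0.995),
                             include_observed = FALSE,
                             within_bout = FALSE,
                             band_type = c("pointwise", "global"),
                             subset_rule = c("both", "either")) {
  cfg <- list(n_permutations = as.integer(n_permutations), alpha = alpha,
              kde_bandwidth = kde_bandwidth,
              grid_size = as.integer(grid_size),
              stratum_mode = match.arg(stratum_mode),
              rng_seed = as.integer(rng_seed),
              ci_quantiles = ci_quantiles,
              include_observed = isTRUE(include_observed),
              within_bout = isTRUE(within_bout),
              band_type = match.arg(band_type),
              subset_rule = match.arg(subset_rule))
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  if (cfg$n_permutations < 1 / cfg$alpha) {
    stop("n_permutations must be at least 1/alpha (need >= ",
         ceiling(1 / cfg$alpha), ")")
  }
  if (cfg$grid_size < 2L) stop("grid_size must be at least 2")
  if (!(length(cfg$ci_quantiles) == 2L &&
        all(cfg$ci_quantiles > 0 & cfg$ci_quantiles < 1) &&
        diff(cfg$ci_quantiles) > 0)) {
    stop("ci_quantiles must be an increasing pair inside (0, 1)")
  }
  class(cfg) <- "inference_config"
  cfg
}

#' Fixed-grid Gaussian kernel density of IOI-ratios
#'
#' Fixed-bandwidth Gaussian KDE evaluated on the same equally spaced grid
#' over \[0, 1\] for every call, so that densities of the observed sequence
#' and of every permutation are pointwise comparable. No boundary-reflection
#' correction is applied: kernel mass can leak past 0 and 1, so the
#' trapezoid integral over the grid may fall slightly below one for samples
#' near the edges.
#'
#' @param ratios ratio values in (0, 1); at least one.
#' @param cfg an [inference_config()] (bandwidth and grid size are used).
#' @return list of class `"density_grid"` with `grid` and `density`.
#' @export
kde_density <- function(ratios, cfg = inference_config()) {
  if (!length(ratios)) stop("cannot estimate a density from zero ratios")
  d <- stats::density(ratios, bw = cfg$kde_bandwidth, kernel = "gaussian",
                      n = cfg$grid_size, from = 0, to = 1)
  structure(list(grid = d$x, density = d$y), class = "density_grid")
}

# Deterministic per-permutation seed streams from one master seed.
derive_perm_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# One stratified shuffle of the IOI value vector: values move uniformly at
# random among positions sharing a stratum; everything else stays put.
shuffle_within_strata <- function(values, strata_idx) {
  for (idx in strata_idx) {
    values[idx] <- values[idx][sample.int(length(idx))]
  }
  values
}

#' One stratified permutation of a dataset's IOI sequence
#'
#' IOI *values* are shuffled uniformly among IOI *positions* sharing the
#' same stratum key (by default: individual and ordered flanking element
#' classes). Positions keep their bout membership, order and stratum labels,
#' so the per-stratum multiset of IOI values is exactly conserved, and
#' ratios recomputed from the permuted values live between IOIs flanked by
#' the same classes and individuals as in the original sequence. Singleton
#' strata are fixed points.
#'
#' @param ds a [build_dataset()] result.
#' @param cfg an [inference_config()] (stratum mode and within-bout flag).
#' @param seed optional seed for this single draw (default: the config's
#'   master seed).
#' @return `ds` with permuted `iois$value` and recomputed `ratios$value`.
#' @export
stratified_permute <- function(ds, cfg = inference_config(), seed = NULL) {
  keys <- stratum_keys(ds$iois, cfg$stratum_mode)
  if (cfg$within_bout) keys <- paste(keys, ds$iois$bout, sep = "\r")
  strata <- split(seq_len(nrow(ds$iois)), keys)
  strata <- strata[lengths(strata) > 1L]
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$rng_seed)
  v <- shuffle_within_strata(ds$iois$value, strata)
  ds$iois$value <- v
  ds$ratios$value <- v[ds$ratios$i_cur] /
    (v[ds$ratios$i_cur] + v[ds$ratios$i_prev])
  ds
}

# Empirical order-statistic quantile: the ceiling(q*n)-th smallest value.
# Conservative, unambiguous, exact under enumeration.
order_stat_quantile <- function(x, q) {
  sort(x)[pmin(length(x), pmax(1L, ceiling(q * length(x))))]
}

#' Run the stratified permutation test for rhythmicity
#'
#' Compares the observed IOI-ratio density against the ensemble of densities
#' obtained from `n_permutations` stratified permutations of the IOI
#' sequence. At each of the `grid_size` ratio values, the densities are
#' reduced to a normalized deviation (observed minus permutation mean,
#' divided by permutation SD); the maximal absolute deviation across the
#' grid summarises each curve in a single number. The test statistic is the
#' empirical `1 - alpha` quantile of the permutation maxima; the null
#' hypothesis that IOI order is random (IOIs exchangeable within strata) is
#' rejected when the observed maximum exceeds it. Pointwise confidence
#' bands at `ci_quantiles` of the permutation deviations, plus local peaks
#' of the observed deviation outside those bands, localise the rhythms
#' driving a rejection.
#'
#' Grid points where the permutation SD is numerically zero (below `1e-12`
#' times the largest mean density) are flagged and their deviation set to 0,
#' preventing inflation of the statistic where the null ensemble is
#' degenerate (a known hazard at the extremes of the ratio domain).
#'
#' @param ds a [build_dataset()] result with at least 2 ratios.
#' @param cfg an [inference_config()].
#' @param ratio_subset optional integer vector of row indices into
#'   `ds$ratios` restricting which ratios enter the densities (used by
#'   [pair_subset_test()]); permutations still act on the full IOI sequence.
#' @param keep_densities if `TRUE`, attach the full `grid_size x
#'   n_permutations` matrix of permuted densities as `perm_densities`
#'   (diagnostics; memory grows with the permutation count).
#' @return list of class `"rhythm_test_result"`: `observed_max`,
#'   `test_statistic`, `significant`, `perm_maxima`, `profile` (grid,
#'   observed/mean/SD density, deviation, CI bands, SD-floor mask), `peaks`,
#'   `n_ratios`, `config`, `seed`.
#' @export
run_rhythm_test <- function(ds, cfg = inference_config(),
                            ratio_subset = NULL, keep_densities = FALSE) {
  if (is.null(ratio_subset)) ratio_subset <- seq_len(nrow(ds$ratios))
  if (length(ratio_subset) < 2L) {
    stop("untestable dataset: fewer than 2 ratios")
  }
  v <- ds$iois$value
  ip <- ds$ratios$i_prev[ratio_subset]
  ic <- ds$ratios$i_cur[ratio_subset]
  keys <- stratum_keys(ds$iois, cfg$stratum_mode)
  if (cfg$within_bout) keys <- paste(keys, ds$iois$bout, sep = "\r")
  strata <- split(seq_along(v), keys)
  strata <- strata[lengths(strata) > 1L]

  obs_dens <- kde_density(v[ic] / (v[ic] + v[ip]), cfg)
  grid <- obs_dens$grid
  nperm <- cfg$n_permutations
  seeds <- derive_perm_seeds(cfg$rng_seed, nperm)
  perm_dens <- matrix(0, nrow = cfg$grid_size, ncol = nperm)
  for (j in seq_len(nperm)) {
    set.seed(seeds[j])
    w <- shuffle_within_strata(v, strata)
    perm_dens[, j] <- kde_density(w[ic] / (w[ic] + w[ip]), cfg)$density
  }
  ens <- if (cfg$include_observed) cbind(perm_dens, obs_dens$density)
         else perm_dens
  m <- rowMeans(ens)
  # centred two-pass variance: stable when the ensemble is degenerate
  s <- sqrt(rowMeans((ens - m)^2) * ncol(ens) / (ncol(ens) - 1))
  mask <- s < 1e-12 * max(m)
  safe_s <- ifelse(mask, 1, s)
  dev_obs <- ifelse(mask, 0, (obs_dens$density - m) / safe_s)
  dev_perm <- (perm_dens - m) / safe_s
  dev_perm[mask, ] <- 0
  perm_maxima <- apply(abs(dev_perm), 2L, max)
  observed_max <- max(abs(dev_obs))
  test_statistic <- order_stat_quantile(perm_maxima, 1 - cfg$alpha)
  if (cfg$band_type == "pointwise") {
    kl <- max(1L, ceiling(cfg$ci_quantiles[1L] * nperm))
    kh <- min(nperm, ceiling(cfg$ci_quantiles[2L] * nperm))
    ci <- apply(dev_perm, 1L, function(z) sort(z)[c(kl, kh)])
    ci_low <- ci[1L, ]; ci_high <- ci[2L, ]
  } else {
    ci_low <- rep(-test_statistic, cfg$grid_size)
    ci_high <- rep(test_statistic, cfg$grid_size)
  }
  profile <- structure(list(
    grid = grid, observed_density = obs_dens$density,
    perm_mean = m, perm_sd = s, deviation = dev_obs,
    ci_low = ci_low, ci_high = ci_high, sd_floor_mask = mask
  ), class = "deviation_profile")
  res <- structure(list(
    observed_max = observed_max,
    test_statistic = test_statistic,
    significant = observed_max > test_statistic,
    perm_maxima = perm_maxima,
    profile = profile,
    peaks = call_peaks(profile),
    n_ratios = length(ratio_subset),
    config = cfg,
    seed = cfg$rng_seed
  ), class = "rhythm_test_result")
  if (keep_densities) res$perm_densities <- perm_dens
  res
}

#' Call local peaks of a deviation profile outside its confidence band
#'
#' Excess peaks are strict local maxima of the deviation (a rise followed by
#' a fall in the discrete sequence) whose value exceeds the upper band at
#' that grid point; deficit peaks are local minima below the lower band.
#' Plateaus count as a single extremum attributed to their leftmost grid
#' point; the first and last grid points are never peaks. No minimum
#' prominence or separation is imposed.
#'
#' @param profile a `deviation_profile` (component of a test result).
#' @return data frame with columns `ratio_location`, `deviation_value`,
#'   `sign` (`"excess"`/`"deficit"`); zero rows when nothing escapes the
#'   band.
#' @export
call_peaks <- function(profile) {
  d <- profile$deviation
  find_maxima <- function(y) {
    r <- rle(y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    if (k < 3L) return(integer(0))
    mid <- 2:(k - 1L)
    is_max <- r$values[mid] > r$values[mid - 1L] &
      r$values[mid] > r$values[mid + 1L]
    starts[mid][is_max]  # leftmost point of each (possibly plateau) maximum
  }
  up <- find_maxima(d)
  dn <- find_maxima(-d)
  up <- up[d[up] > profile$ci_high[up]]
  dn <- dn[d[dn] < profile$ci_low[dn]]
  out <- data.frame(
    ratio_location = c(profile$grid[up], profile$grid[dn]),
    deviation_value = c(d[up], d[dn]),
    sign = c(rep("excess", length(up)), rep("deficit", length(dn))),
    stringsAsFactors = FALSE
  )
  out[order(out$ratio_location), , drop = FALSE]
}

#' Pair-restricted rhythm test
#'
#' Restricts the analysed ratios to those whose constituent IOIs carry a
#' given ordered flanking-class pair, e.g. `c("complex_phrase",
#' "complex_phrase")` for C-C. Under the default `subset_rule = "both"` a
#' ratio qualifies only when both of its IOIs are flanked by exactly that
#' pair. Permutations remain stratified over the full IOI sequence; only the
#' density is recomputed on the restricted ratio set.
#'
#' @param ds a [build_dataset()] result with class labels.
#' @param pair length-2 character vector: class of the initiating and the
#'   terminating element of the IOI.
#' @param cfg an [inference_config()].
#' @return A `rhythm_test_result` (see [run_rhythm_test()]).
#' @export
pair_subset_test <- function(ds, pair, cfg = inference_config()) {
  stopifnot(length(pair) == 2L)
  lab <- paste(ds$iois$class_prev, ds$iois$class_next, sep = "\r")
  want <- paste(pair[1L], pair[2L], sep = "\r")
  hit <- lab == want
  qual <- if (cfg$subset_rule == "both") {
    hit[ds$ratios$i_prev] & hit[ds$ratios$i_cur]
  } else {
    hit[ds$ratios$i_prev] | hit[ds$ratios$i_cur]
  }
  idx <- which(qual)
  if (!length(idx)) {
    stop("no ratios qualify for pair (", pair[1L], ", ", pair[2L], ")")
  }
  run_rhythm_test(ds, cfg, ratio_subset = idx)
}

#' Rhythm test after omitting element-class pairs
#'
#' Removes every IOI whose ordered flanking-class pair is in `omit_pairs`
#' *before* ratio computation; ratios are then formed only from surviving,
#' originally adjacent IOI pairs (removed IOIs do not bridge: a ratio
#' between non-contiguous intervals is undefined), and the full test is
#' re-run with permutation strata rebuilt on the surviving IOIs. With an
#' empty omission set the result is identical to [run_rhythm_test()] under
#' the same seed.
#'
#' @param ds a [build_dataset()] result.
#' @param omit_pairs list of length-2 character vectors (ordered pairs).
#' @param cfg an [inference_config()].
#' @return A `rhythm_test_result`.
#' @export
omission_test <- function(ds, omit_pairs, cfg = inference_config()) {
  if (length(omit_pairs) && !is.list(omit_pairs)) omit_pairs <- list(omit_pairs)
  lab <- paste(ds$iois$class_prev, ds$iois$class_next, sep = "\r")
  drop_lab <- vapply(omit_pairs, function(p) paste(p[1L], p[2L], sep = "\r"), "")
  keep <- !(lab %in% drop_lab)
  sub <- ds
  sub$iois <- ds$iois[keep, , drop = FALSE]
  rownames(sub$iois) <- NULL
  new_index <- integer(nrow(ds$iois))
  new_index[keep] <- seq_len(sum(keep))
  rkeep <- keep[ds$ratios$i_prev] & keep[ds$ratios$i_cur]
  sub$ratios <- ds$ratios[rkeep, , drop = FALSE]
  sub$ratios$i_prev <- new_index[sub$ratios$i_prev]
  sub$ratios$i_cur <- new_index[sub$ratios$i_cur]
  rownames(sub$ratios) <- NULL
  if (nrow(sub$ratios) < 2L) {
    stop("untestable dataset: omission leaves fewer than 2 ratios")
  }
  run_rhythm_test(sub, cfg)
}

#' @export
print.rhythm_test_result <- function(x, ...) {
  cat("<rhythm_test_result>\n")
  cat(sprintf("  ratios analysed      : %d\n", x$n_ratios))
  cat(sprintf("  permutations         : %d (stratum: %s, seed %d)\n",
              x$config$n_permutations, x$config$stratum_mode, x$seed))
  cat(sprintf("  observed max |dev|   : %.6f\n", x$observed_max))
  cat(sprintf("  test statistic (%.0f%%) : %.6f\n",
              100 * (1 - x$config$alpha), x$test_statistic))
  cat(sprintf("  significant          : %s\n",
              if (x$significant) "YES (nonrandom IOI ordering)" else "no"))
  if (nrow(x$peaks)) {
    cat("  peaks outside the confidence band:\n")
    for (k in seq_len(nrow(x$peaks))) {
      cat(sprintf("    %-7s at ratio %.3f (deviation %+.2f)\n",
                  x$peaks$sign[k], x$peaks$ratio_location[k],
                  x$peaks$deviation_value[k]))
    }
  } else {
    cat("  no peaks outside the confidence band\n")
  }
  invisible(x)
}
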