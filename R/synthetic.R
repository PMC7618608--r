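#' Specification of a synthetic vocal-sequence dataset
#'
#' Describes the statistical shape of a simulated element-sequence dataset:
#' how many individuals and bouts, the element-class mix, the bout-length
#' and IOI distributions, and an optional planted rhythmic pattern. The
#' defaults emulate a budgerigar-like recording session: heavy-tailed
#' (lognormal) IOIs around 150 ms, bouts of on average 8.9 elements with a
#' long right tail, and the seven warble classes at their average observed
#' frequencies.
#'
#' @param individuals number of individuals.
#' @param classes named numeric vector of element-class sampling weights.
#' @param bout_count bouts per individual.
#' @param elements_per_bout `c(mean, dispersion)`: bout sizes are `1 +`
#'   a negative binomial with mean `mean - 1` and size `dispersion`
#'   (minimum 1, heavy-tailed for small dispersion); a dispersion of `NA`
#'   fixes every bout at `round(mean)` elements.
#' @param ioi_distribution list: `family` (`"lognormal"`, `"gamma"` or
#'   `"uniform"`) and its parameters (`meanlog`/`sdlog`, `shape`/`rate`, or
#'   `min`/`max`). Under `pattern = "none"` it is the i.i.d. IOI law; under
#'   a planted pattern it is the law of each bout's base interval (tempo).
#' @param pattern `"none"`, `"isochronous"`, or `"ratio_grammar"`.
#' @param grammar relative IOI cycle for `"ratio_grammar"`, e.g. `c(1, 2)`.
#' @param mixture_weight fraction of bouts carrying the pattern; the
#'   remainder are null bouts.
#' @param jitter_cv lognormal jitter coefficient of variation applied to
#'   each patterned IOI (0.03 = 3% timing jitter).
#' @param element_duration `c(meanlog, sdlog)` of lognormal element
#'   durations, seconds.
#' @param silence_between_bouts silence inserted between consecutive bouts,
#'   seconds; must exceed `bout_silence_threshold`.
#' @param bout_silence_threshold the bout cut-off the dataset is meant to be
#'   analysed with; element durations are stretched where needed so that
#'   within-bout silences stay below it (durations never enter the IOI
#'   analysis, so this keeps the planned bout structure exact without
#'   touching the IOI law).
#' @param rng_seed master seed for generation.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(individuals = 1L,
                           classes = budgerigar_class_weights(),
                           bout_count = 200L,
                           elements_per_bout = c(mean = 8.9, dispersion = 0.8),
                           ioi_distribution = list(family = "lognormal",
                                                   meanlog = log(0.15),
                                                   sdlog = 0.5),
                           pattern = c("none", "isochronous",
                                       "ratio_grammar"),
                           grammar = c(1, 2),
                           mixture_weight = 1,
                           jitter_cv = 0.03,
                           element_duration = c(meanlog = log(0.06),
                                                sdlog = 0.4),
                           silence_between_bouts = 1.0,
                           bout_silence_threshold = 0.25,
                           rng_seed = 1L) {
  spec <- list(individuals = as.integer(individuals), classes = classes,
               bout_count = as.integer(bout_count),
               elements_per_bout = elements_per_bout,
               ioi_distribution = ioi_distribution,
               pattern = match.arg(pattern), grammar = grammar,
               mixture_weight = mixture_weight, jitter_cv = jitter_cv,
               element_duration = element_duration,
               silence_between_bouts = silence_between_bouts,
               bout_silence_threshold = bout_silence_threshold,
               rng_seed = as.integer(rng_seed))
  if (spec$jitter_cv < 0) stop("jitter_cv must be non-negative")
  if (any(spec$grammar <= 0)) stop("grammar relative IOIs must be positive")
  if (spec$elements_per_bout[[1L]] < 1) {
    stop("mean elements per bout must be at least 1")
  }
  if (spec$silence_between_bouts <= spec$bout_silence_threshold) {
    stop("silence_between_bouts must exceed bout_silence_threshold")
  }
  if (is.null(names(spec$classes)) || any(spec$classes < 0)) {
    stop("classes must be a named vector of non-negative weights")
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Average budgerigar warble element-class frequencies
#'
#' The across-individual average mix of the seven warble classes (alarm,
#' click, complex phrase, long harmonic, noisy, short harmonic, unknown),
#' giving realistically sparse permutation strata in simulations.
#'
#' @return named numeric vector of weights summing to 1.
#' @export
budgerigar_class_weights <- function() {
  w <- c(alarm = 2.30, click = 10.60, complex_phrase = 40.40,
         long_harmonic = 1.99, noisy = 6.17, short_harmonic = 27.6,
         unknown = 11.0)
  w / sum(w)
}

draw_ioi <- function(n, dist) {
  switch(dist$family,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    uniform = stats::runif(n, dist$min, dist$max),
    stop("unknown IOI distribution family: ", dist$family)
  )
}

draw_bout_sizes <- function(n, par) {
  if (is.na(par[[2L]])) return(rep(as.integer(round(par[[1L]])), n))
  mu <- par[[1L]] - 1
  if (mu <= 0) return(rep(1L, n))
  1L + stats::rnbinom(n, size = par[[2L]], mu = mu)
}

# Core generator shared by the null and patterned entry points.
generate_sequences <- function(spec) {
  set.seed(spec$rng_seed)
  recs <- list()
  thr <- spec$bout_silence_threshold
  jsd <- sqrt(log(1 + spec$jitter_cv^2))  # lognormal sdlog for the given CV
  for (i in seq_len(spec$individuals)) {
    ind <- sprintf("ind%02d", i)
    sizes <- draw_bout_sizes(spec$bout_count, spec$elements_per_bout)
    t0 <- 0
    onsets <- offsets <- numeric(0)
    classes <- character(0)
    for (b in seq_len(spec$bout_count)) {
      n <- sizes[b]
      if (spec$pattern == "none" ||
          (spec$mixture_weight < 1 &&
           stats::runif(1) > spec$mixture_weight)) {
        iois <- draw_ioi(max(0L, n - 1L), spec$ioi_distribution)
      } else {
        base <- draw_ioi(1L, spec$ioi_distribution)
        rel <- if (spec$pattern == "isochronous") 1 else spec$grammar
        cyc <- rep_len(rel, max(0L, n - 1L))
        jit <- if (spec$jitter_cv > 0) {
          stats::rlnorm(length(cyc), -jsd^2 / 2, jsd)  # unit-mean jitter
        } else 1
        iois <- base * cyc * jit
      }
      on_b <- t0 + cumsum(c(0, iois))
      dur <- stats::rlnorm(n, spec$element_duration[[1L]],
                           spec$element_duration[[2L]])
      if (n > 1L) {
        # keep within-bout silences under the bout threshold and elements
        # strictly before the next onset; durations are cosmetic for the
        # IOI analysis (onsets alone define IOIs)
        need <- pmax(dur[-n], iois - 0.9 * thr)
        dur[-n] <- pmin(need, 0.95 * iois)
      }
      onsets <- c(onsets, on_b)
      offsets <- c(offsets, on_b + dur)
      classes <- c(classes, sample(names(spec$classes), n, replace = TRUE,
                                   prob = spec$classes))
      t0 <- max(on_b + dur) + spec$silence_between_bouts
    }
    recs[[i]] <- annotation_set(onsets, offsets, classes, individual = ind,
                                recording = paste0("sim_", ind))
  }
  out <- do.call(rbind, recs)
  class(out) <- c("annotation_set", "data.frame")
  validate_annotation_set(out)
}

#' Generate a null (rhythm-free) synthetic dataset
#'
#' Per bout, IOIs are drawn i.i.d. from the configured distribution, so IOI
#' values are exchangeable within every stratum by construction: the
#' permutation null is exactly true and the rhythm test should reject at
#' its nominal rate. Pattern and jitter fields of the spec are ignored.
#'
#' @param spec a [synthetic_spec()] (its `pattern` is forced to `"none"`).
#' @return An [annotation_set()].
#' @export
generate_null_dataset <- function(spec = synthetic_spec()) {
  spec$pattern <- "none"
  generate_sequences(spec)
}

#' Generate a dataset with a planted rhythmic pattern
#'
#' Each patterned bout follows the repeating relative-IOI grammar
#' (`isochronous` is the cycle `1`) scaled by a bout-specific base interval
#' drawn from the IOI distribution, with multiplicative lognormal jitter of
#' the given coefficient of variation. Because tempo varies across bouts
#' while the within-bout grammar is fixed, observed ratios concentrate at
#' the grammar's closed-form values (0.5 for isochrony; alternating 1/3 and
#' 2/3 for the cycle `c(1, 2)`) while stratified permutations mix slow and
#' fast intervals across bouts and spread out — the signature the test
#' detects. With `mixture_weight < 1` the remaining bouts are null bouts.
#'
#' @param spec a [synthetic_spec()] with `pattern != "none"`.
#' @return An [annotation_set()].
#' @export
generate_patterned_dataset <- function(spec) {
  if (spec$pattern == "none") {
    stop("spec$pattern must not be 'none'; use generate_null_dataset()")
  }
  generate_sequences(spec)
}

#' Render an annotation set as synthetic audio
#'
#' Places band-limited tone bursts at the annotated intervals over Gaussian
#' background noise at a requested SNR, so the segmentation front-end can
#' be tested end-to-end against known ground-truth boundaries. Burst edges
#' carry a 0.5 ms cosine ramp to avoid clicks; SNR is burst RMS over noise
#' RMS. Not a vocal-spectrum synthesiser: fixtures are for boundary
#' detection only.
#'
#' @param a an [annotation_set()] with disjoint intervals (single
#'   recording).
#' @param rate sample rate, Hz.
#' @param snr_db signal-to-noise ratio in dB; `Inf` disables noise.
#' @param tone_hz burst carrier frequency (keep inside the analysis band).
#' @param amplitude burst RMS amplitude (linear, < 1).
#' @param pad trailing/leading silence, seconds.
#' @param seed RNG seed for the noise.
#' @return list with `samples` and `rate`.
#' @export
generate_synthetic_audio <- function(a, rate = 32000, snr_db = 20,
                                     tone_hz = 3000, amplitude = 0.3,
                                     pad = 0.5, seed = 1L) {
  validate_annotation_set(a)
  if (nrow(a) > 1L && any(a$onset[-1L] < a$offset[-nrow(a)])) {
    stop("annotation intervals must be disjoint")
  }
  total <- (if (nrow(a)) max(a$offset) else 0) + pad
  n <- ceiling((total + pad) * rate)
  x <- numeric(n)
  ramp_n <- max(2L, round(0.0005 * rate))
  for (k in seq_len(nrow(a))) {
    i0 <- floor(a$onset[k] * rate + pad * rate) + 1L
    i1 <- min(n, floor(a$offset[k] * rate + pad * rate))
    m <- i1 - i0 + 1L
    if (m < 2L) next
    tt <- seq_len(m) / rate
    burst <- sqrt(2) * amplitude * sin(2 * pi * tone_hz * tt)
    r <- min(ramp_n, m %/% 2L)
    win <- rep(1, m)
    win[seq_len(r)] <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
    win[m + 1L - seq_len(r)] <- win[seq_len(r)]
    x[i0:i1] <- x[i0:i1] + burst * win
  }
  if (is.finite(snr_db)) {
    set.seed(seed)
    x <- x + stats::rnorm(n, sd = amplitude * 10^(-snr_db / 20))
  }
  # ground truth shifted by the leading pad
  truth <- a
  truth$onset <- truth$onset + pad
  truth$offset <- truth$offset + pad
  list(samples = x, rate = rate, truth = truth)
}
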