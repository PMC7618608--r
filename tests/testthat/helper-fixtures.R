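# Shared fixtures, built in code at test time.

# A single-bout annotation from explicit onsets (constant 20 ms durations
# clipped below the next onset so intervals never overlap).
toy_annotation <- function(onsets, classes = "x", individual = "i1",
                           recording = "r1", duration = 0.02) {
  n <- length(onsets)
  dur <- rep(duration, n)
  if (n > 1L) dur[-n] <- pmin(dur[-n], diff(onsets) * 0.9)
  annotation_set(onsets, onsets + dur, rep_len(classes, n),
                 individual = individual, recording = recording)
}

# Single-stratum dataset whose IOIs are exactly `iois`, one bout.
single_stratum_dataset <- function(iois) {
  build_dataset(toy_annotation(cumsum(c(0, iois))),
                silence_threshold = max(iois) + 1)
}

# Exhaustive-permutation oracle for a single-stratum dataset: densities,
# exact ensemble moments, and the exact distribution of the maximal
# normalized deviation over all orderings. Independent of the package's
# Monte-Carlo path (it enumerates via pracma::perms).
enumerate_max_deviations <- function(ds, cfg) {
  v <- ds$iois$value
  ip <- ds$ratios$i_prev
  ic <- ds$ratios$i_cur
  P <- pracma::perms(v)
  dens <- apply(P, 1L, function(w) {
    kde_density(w[ic] / (w[ic] + w[ip]), cfg)$density
  })
  m <- rowMeans(dens)
  s <- sqrt(pmax(0, rowMeans(dens^2) - m^2) * nrow(P) / (nrow(P) - 1))
  mask <- s < 1e-12 * max(m)
  s_safe <- ifelse(mask, 1, s)
  dv <- (dens - m) / s_safe
  dv[mask, ] <- 0
  list(maxima = apply(abs(dv), 2L, max), mean = m, sd = s, mask = mask)
}

# Trapezoid integral of a density grid over [0, 1].
trapz_grid <- function(g) {
  sum(diff(g$grid) * (utils::head(g$density, -1) + utils::tail(g$density, -1)) / 2)
}

expect_no_nan <- function(x) {
  testthat::expect_true(all(is.finite(unlist(x))))
}
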