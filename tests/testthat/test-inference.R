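test_that("the fixed-grid KDE matches Gaussian closed forms", {
  cfg <- inference_config(n_permutations = 100)
  # one point at 0.5: peak = 1 / (h * sqrt(2*pi)) up to grid discretisation
  g <- kde_density(0.5, cfg)
  half_step <- 0.5 / (cfg$grid_size - 1)
  lo <- stats::dnorm(half_step, sd = cfg$kde_bandwidth)
  hi <- stats::dnorm(0, sd = cfg$kde_bandwidth)
  expect_gt(max(g$density), lo - 0.5)
  expect_lt(max(g$density), hi + 0.5)
  expect_lt(abs(g$grid[which.max(g$density)] - 0.5), half_step * 2)
  # symmetric sample -> symmetric density
  g2 <- kde_density(rep(c(0.3, 0.7), 25), cfg)
  expect_equal(g2$density, rev(g2$density), tolerance = 1e-6)
  # interior samples integrate to ~1
  set.seed(8)
  g3 <- kde_density(runif(200, 0.1, 0.9), cfg)
  expect_lt(abs(trapz_grid(g3) - 1), 0.01)
  expect_error(kde_density(numeric(0), cfg), "zero ratios")
})

test_that("configuration invariants are enforced", {
  expect_error(inference_config(n_permutations = 50, alpha = 0.01),
               "1/alpha")
  expect_error(inference_config(alpha = 0), "alpha")
  expect_error(inference_config(grid_size = 1), "grid_size")
  expect_error(inference_config(ci_quantiles = c(0.9, 0.1)), "increasing")
})

test_that("stratified permutation conserves per-stratum multisets exactly", {
  spec <- synthetic_spec(individuals = 2, bout_count = 30, rng_seed = 11)
  ds <- build_dataset(generate_null_dataset(spec), 0.25)
  cfg <- inference_config(n_permutations = 100, rng_seed = 2)
  key0 <- paste(ds$iois$individual, ds$iois$class_prev, ds$iois$class_next)
  for (seed in 1:20) {
    p <- stratified_permute(ds, cfg, seed = seed)
    # per-stratum multisets identical (exact equality, no tolerance)
    for (k in unique(key0)) {
      expect_identical(sort(p$iois$value[key0 == k]),
                       sort(ds$iois$value[key0 == k]))
    }
    # labels, positions and bout structure untouched
    expect_identical(p$iois$class_prev, ds$iois$class_prev)
    expect_identical(p$iois$bout, ds$iois$bout)
    # ratios recomputed from the permuted values
    v <- p$iois$value
    expect_equal(p$ratios$value,
                 v[p$ratios$i_cur] / (v[p$ratios$i_cur] + v[p$ratios$i_prev]))
  }
})

test_that("singleton strata are fixed points of the permutation", {
  # every IOI in its own stratum: distinct flanking classes per position
  on <- cumsum(c(0, 0.11, 0.25, 0.17, 0.3))
  a <- annotation_set(on, on + 0.05, element_class = letters[1:5])
  ds <- build_dataset(a, 1)
  p <- stratified_permute(ds, inference_config(n_permutations = 100),
                          seed = 99)
  expect_identical(p$iois$value, ds$iois$value)
})

test_that("individual-only strata shuffle across classes within a subject", {
  spec <- synthetic_spec(individuals = 2, bout_count = 10, rng_seed = 21)
  ds <- build_dataset(generate_null_dataset(spec), 0.25)
  cfg <- inference_config(n_permutations = 100,
                          stratum_mode = "individual_only")
  p <- stratified_permute(ds, cfg, seed = 5)
  for (i in unique(ds$iois$individual)) {
    expect_identical(sort(p$iois$value[ds$iois$individual == i]),
                     sort(ds$iois$value[ds$iois$individual == i]))
  }
  expect_false(identical(p$iois$value, ds$iois$value))
})

test_that("identical seeds give bit-identical results; deviations stay finite", {
  ds <- build_dataset(
    generate_null_dataset(synthetic_spec(bout_count = 40, rng_seed = 6)), 0.25)
  cfg <- inference_config(n_permutations = 200, rng_seed = 17)
  r1 <- run_rhythm_test(ds, cfg)
  r2 <- run_rhythm_test(ds, cfg)
  expect_identical(r1$perm_maxima, r2$perm_maxima)
  expect_identical(r1$profile$deviation, r2$profile$deviation)
  expect_identical(r1$observed_max, r2$observed_max)
  expect_no_nan(r1$profile$deviation)
  expect_no_nan(r1$perm_maxima)
  expect_identical(r1$significant, r1$observed_max > r1$test_statistic)
})

test_that("a permutation-degenerate dataset yields zero deviation everywhere", {
  # all IOIs equal: every permutation reproduces the observed sequence, the
  # ensemble SD is zero, all points are floored -> deviation identically 0
  ds <- single_stratum_dataset(rep(0.2, 8))
  res <- run_rhythm_test(ds, inference_config(n_permutations = 100))
  expect_true(all(res$profile$deviation == 0))
  expect_false(res$significant)
  expect_no_nan(res$profile$deviation)
  expect_true(any(res$profile$sd_floor_mask))
})

test_that("untestable datasets are rejected with a clear error", {
  ds <- build_dataset(toy_annotation(c(0, 0.1, 0.25)), 0.5)  # one ratio
  expect_error(run_rhythm_test(ds, inference_config(n_permutations = 100)),
               "untestable")
})

test_that("peak calling finds band-exceeding local extrema, plateaus leftmost", {
  grid <- seq(0, 1, length.out = 512)
  mk_prof <- function(dev, lo = -2.5, hi = 2.5) {
    structure(list(grid = grid, observed_density = dev, perm_mean = 0 * grid,
                   perm_sd = 1 + 0 * grid, deviation = dev,
                   ci_low = rep(lo, 512), ci_high = rep(hi, 512),
                   sd_floor_mask = rep(FALSE, 512)),
              class = "deviation_profile")
  }
  # a single Gaussian bump of height 6 over a flat band at +/- 2.5
  bump <- 6 * exp(-(grid - 0.5)^2 / (2 * 0.03^2))
  pk <- call_peaks(mk_prof(bump))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$sign, "excess")
  expect_lt(abs(pk$ratio_location - 0.5), 2 / 511)
  # everything inside the bands -> no peaks
  expect_equal(nrow(call_peaks(mk_prof(2 * sin(8 * pi * grid)))), 0L)
  # two bumps separated by a dip below the band -> two excess peaks
  two <- 6 * exp(-(grid - 0.3)^2 / (2 * 0.02^2)) +
    5 * exp(-(grid - 0.7)^2 / (2 * 0.02^2))
  pk2 <- call_peaks(mk_prof(two))
  expect_equal(nrow(pk2), 2L)
  # deficit peaks mirror excess peaks
  pk3 <- call_peaks(mk_prof(-bump))
  expect_identical(pk3$sign, "deficit")
  # plateau ties resolve to the leftmost grid point
  plat <- numeric(512); plat[200:205] <- 4
  pk4 <- call_peaks(mk_prof(plat))
  expect_equal(pk4$ratio_location, grid[200])
})

test_that("peak locations agree with an independent peak finder", {
  skip_if_not_installed("pracma")
  set.seed(33)
  grid <- seq(0, 1, length.out = 512)
  dev <- as.numeric(stats::filter(rnorm(512, sd = 2), rep(1 / 15, 15),
                                  circular = TRUE))
  prof <- structure(list(grid = grid, observed_density = dev,
                         perm_mean = 0 * grid, perm_sd = 1 + 0 * grid,
                         deviation = dev, ci_low = rep(-1.2, 512),
                         ci_high = rep(1.2, 512),
                         sd_floor_mask = rep(FALSE, 512)),
                    class = "deviation_profile")
  ours <- call_peaks(prof)
  fp <- pracma::findpeaks(dev)
  ref_up <- sort(grid[fp[fp[, 1] > 1.2, 2]])
  expect_equal(sort(ours$ratio_location[ours$sign == "excess"]), ref_up)
})

test_that("pair-restricted analyses select exactly the qualifying ratios", {
  # a bout of all complex phrases: every ratio qualifies for (C, C)
  a <- toy_annotation(seq(0, 1.0, by = 0.1), classes = "C")
  ds <- build_dataset(a, 0.25)
  cfg <- inference_config(n_permutations = 100, rng_seed = 3)
  res <- pair_subset_test(ds, c("C", "C"), cfg)
  expect_equal(res$n_ratios, nrow(ds$ratios))
  expect_error(pair_subset_test(ds, c("C", "N"), cfg), "no ratios qualify")
  # alternating classes: no adjacent C-C IOI anywhere, and under the
  # default both-IOIs rule not even (C, N) has two adjacent qualifying IOIs
  b <- toy_annotation(seq(0, 1.0, by = 0.1),
                      classes = rep(c("C", "N"), 6)[1:11])
  dsb <- build_dataset(b, 0.25)
  expect_error(pair_subset_test(dsb, c("C", "C"), cfg), "no ratios qualify")
  expect_error(pair_subset_test(dsb, c("C", "N"), cfg), "no ratios qualify")
  cfg_e <- inference_config(n_permutations = 100, rng_seed = 3,
                            subset_rule = "either")
  expect_gt(pair_subset_test(dsb, c("C", "N"), cfg_e)$n_ratios, 0)
})

test_that("omitting pairs removes IOIs first and never bridges ratios", {
  # bout C,C,C,N: omitting (C,C) drops the IOIs from 3 to 1, ratios 2 -> 0
  toy <- toy_annotation(c(0, 0.2, 0.4, 0.6), classes = c("C", "C", "C", "N"))
  tds <- build_dataset(toy, 0.25)
  expect_equal(nrow(tds$iois), 3L)
  expect_equal(nrow(tds$ratios), 2L)
  cfg <- inference_config(n_permutations = 100, rng_seed = 7)
  expect_error(omission_test(tds, list(c("C", "C")), cfg), "untestable")

  # empty omission set reproduces the plain test bit-for-bit
  spec <- synthetic_spec(bout_count = 30, classes = c(C = 2, S = 1, N = 1),
                         rng_seed = 12)
  ds <- build_dataset(generate_null_dataset(spec), 0.25)
  plain <- run_rhythm_test(ds, cfg)
  noop <- omission_test(ds, list(), cfg)
  expect_identical(noop$perm_maxima, plain$perm_maxima)
  expect_identical(noop$profile$deviation, plain$profile$deviation)

  # omitting every pair present leaves nothing to test
  all_pairs <- unique(Map(c, ds$iois$class_prev, ds$iois$class_next))
  expect_error(omission_test(ds, all_pairs, cfg), "untestable")

  # surviving ratio count matches the brute-force rule: a ratio survives
  # iff both of its originally adjacent IOIs survive
  omit <- list(c("C", "C"))
  lab <- paste(ds$iois$class_prev, ds$iois$class_next)
  keep <- lab != "C C"
  expected <- sum(keep[ds$ratios$i_prev] & keep[ds$ratios$i_cur])
  res <- omission_test(ds, omit, cfg)
  expect_equal(res$n_ratios, expected)
})

test_that("planted isochrony is detected and localised at 0.5", {
  spec <- synthetic_spec(bout_count = 60, pattern = "isochronous",
                         jitter_cv = 0.03, rng_seed = 14)
  ds <- build_dataset(generate_patterned_dataset(spec), 0.25)
  res <- run_rhythm_test(ds, inference_config(n_permutations = 300,
                                              rng_seed = 8))
  expect_true(res$significant)
  ex <- res$peaks[res$peaks$sign == "excess", ]
  expect_lt(abs(ex$ratio_location[which.max(ex$deviation_value)] - 0.5),
            0.02)
})
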