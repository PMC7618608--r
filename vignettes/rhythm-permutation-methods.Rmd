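---
title: "Detecting rhythmicity in vocalization onset sequences: model, permutation null, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rhythmicity in vocalization onset sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmioi)
```

## The quantity: revised IOI-ratios inside bouts

A vocalization is reduced to its element *onsets*. Within a bout (a maximal
run of elements whose silences stay below a species-typical cut-off; 250 ms
is a sensible default for budgerigar warble, 500 ms for human speech), the
inter-onset intervals IOI~1~, ..., IOI~n~ are summarised pairwise by the
revised ratio

$$r_k = \frac{\mathrm{IOI}_k}{\mathrm{IOI}_k + \mathrm{IOI}_{k-1}},
\qquad k = 2, \dots, n .$$

The current interval is compared with the one that *preceded* it, so the
metric reads a rhythm the way a listener or producer experiences it:
relative to what has already happened. $r_k \in (0,1)$; $r_k = 0.5$ is
isochrony (1:1), $2/3$ a short–long (1:2) pair, $1/3$ a long–short (2:1)
pair. The earlier forward-looking convention is the exact mirror
$1 - r_k$ (`mirror_ratio()`), so descriptive results translate between
conventions without recomputation. Ratios are never formed across a bout
boundary or across recordings: an interval interrupted by a long silence is
not an interval of the behaviour.

## The null: stratified exchangeability, not a parametric IOI law

Testing "is there rhythm?" against a uniform-IOI null mostly tests "are
IOIs non-uniform?", which is trivially true of natural behaviour. The
package's null is instead that the *order* of the observed IOIs is random:
IOI values are exchangeable within strata, where a stratum is by default an
individual crossed with the ordered pair of element classes flanking the
interval. Permuting IOI values among positions of the same stratum
preserves each individual's interval inventory, each class pair's interval
distribution, and the entire bout skeleton — only the ordering is
destroyed. Rejection therefore isolates *sequential structure* rather than
distributional shape. Two coarser stratifications are available
(`initiating_class`, and `individual_only` for unlabelled data such as
speech); the pair stratification is the only one consistent with
class-pair-restricted and class-pair-omission re-analyses, which is why it
is the default.

Permutations shuffle across bouts within a stratum (positions, bout sizes
and labels stay fixed). A within-bout mode exists for sensitivity analysis;
across-bout shuffling is the default because the exchangeability claim is
about the individual's behaviour, not about one bout, and because
within-bout spaces are often tiny.

## From densities to one test statistic

Each ratio set (observed, and each of $N$ permutations; $N = 10{,}000$ by
default) is turned into a Gaussian kernel density with fixed bandwidth
0.01 evaluated on the *same* 512-point grid spanning $[0, 1]$
(`stats::density(bw = 0.01, n = 512, from = 0, to = 1)`). A common fixed
grid is required for pointwise moments across permutations; $[0,1]$ is the
ratio's full support. No boundary-reflection correction is applied, so
kernel mass may leak past 0 and 1 and the density of an edge-hugging sample
integrates to slightly less than 1 — the trapezoid integral stays within
$[0.9, 1]$ and equals $1 \pm 0.01$ for interior samples.

At each grid point the observed density is normalized by the permutation
ensemble: deviation $= (\mathrm{obs} - \mathrm{mean}) / \mathrm{SD}$. This
prevents regions that are variable by chance (e.g. around the mean
interval, where isochrony is likely under the null) from dominating. The
single test statistic is the maximal absolute deviation across the grid;
the observed maximum is compared with the empirical $(1-\alpha)$ quantile
of the $N$ permutation maxima ($\alpha = 0.01$), which avoids any multiple
comparison across the 512 points. Following a rejection, pointwise
$(0.5\%, 99.5\%)$ permutation bands localise the effect, and local extrema
of the observed deviation outside the bands are reported as excess/deficit
peaks.

### Numerical choices

* **Ensemble moments.** The mean/SD are taken over the permutation
  densities only; the observed curve can be included via
  `include_observed = TRUE` (at $N = 10^4$ the two conventions differ
  negligibly, and excluding the observed curve from its own null moments is
  the cleaner choice). Variances use the centred two-pass formula — the
  one-pass $E[x^2]-m^2$ form loses all precision exactly in the degenerate
  ensembles where stability matters most.
* **SD floor.** Where the permutation SD is below $10^{-12}$ times the
  largest mean density (near the edges of the ratio domain the ensemble can
  be almost deterministic), the deviation is set to 0 and the point
  flagged, so no statistic is ever inflated by division by a vanishing SD
  and no NaN/Inf can propagate.
* **Quantiles.** All quantiles (test statistic, bands) are empirical order
  statistics, the $\lceil qN \rceil$-th smallest value: conservative,
  unambiguous, and exact under enumeration.
* **Peaks.** A peak is a strict discrete local extremum; plateaus count
  once, attributed to their leftmost grid point; no minimum prominence or
  separation is imposed. The first/last grid points are never peaks.
* **Reproducibility.** One master seed; per-permutation substreams are
  derived from it up front, so a run is bit-reproducible and insensitive to
  evaluation order.
* **Ties at the rejection boundary.** Significance is strict:
  `observed_max > test_statistic`.

### Restricted and omission analyses

`pair_subset_test()` restricts the density to ratios whose constituent IOIs
both carry a given ordered flanking-class pair (an `either` rule is
available; *both* is the default because a ratio is a property of two
intervals, and labelling it by one would blur pairs). Permutations still
act on the full IOI sequence. `omission_test()` instead removes all IOIs of
the named pairs *before* ratio formation; a ratio survives only if both of
its originally adjacent IOIs survive — removed intervals do not bridge,
since a ratio between non-contiguous intervals is undefined. Strata are
rebuilt on the surviving IOIs, and an empty omission set reproduces the
plain analysis bit-for-bit.

## Audio front-end

The segmentation chain reproduces a standard amplitude-envelope pipeline:
zero-phase 5th-order Butterworth bandpass (400 Hz–15 kHz budgerigar,
75 Hz–5 kHz human; forward–backward filtering so group delay cannot bias
onsets), stationary spectral gating (per-frequency noise floor at
mean + $k$·SD of the STFT magnitude over the whole recording, $k = 1/3$ or
1 by species; spectral subtraction plus a lightly smoothed keep-mask), an
RMS envelope (5 ms window, 1 ms step), and thresholding at 1/6 of the
recording's global RMS amplitude on a linear scale — the simplest reading
of an RMS-based criterion, and configurable. An element is a maximal
supra-threshold region; sub-threshold dips shorter than 5 ms do not split
it (the alternative reading — discarding supra-threshold blips shorter
than 5 ms — is available as `gap_mode = "min_seed"`). Because a 5 ms
window starts crossing the threshold while only a sliver overlaps a burst,
raw first-frame boundaries sit systematically early; the front-end
compensates with the closed-form window-overlap correction
$W/2 - W\,(T/A)^2$, which recovers synthetic burst onsets to within about
1.5 ms at 20 dB SNR. Cleaning afterwards only drops too-short elements
(<10 ms budgerigar, <20 ms human) and relabels over-long "noisy" elements
(>70 ms) as "unknown"; it never moves a boundary. Element classification
itself is out of scope — class labels arrive with the annotations.

## What the simulator emulates — and what it does not

`generate_null_dataset()` draws IOIs i.i.d. (lognormal by default:
heavy-tailed and strictly positive, qualitatively like natural inter-call
gaps; gamma and uniform families are available for contrast experiments),
so within-stratum exchangeability holds by construction and the test's
rejection rate must equal $\alpha$. `generate_patterned_dataset()` plants
rhythm as a repeating relative-interval grammar scaled by a *per-bout base
tempo* drawn from the same family, with multiplicative lognormal jitter
(CV 3% by default). The tempo-per-bout construction mirrors how rhythmic
behaviour actually defeats the stratified null: within a bout intervals
follow the grammar, while permutations mix slow and fast intervals across
bouts and disperse the ratios. Defaults emulate the descriptive shape of a
budgerigar recording session: ~8.9 elements per bout with a long right
tail (1 + negative binomial), seven element classes at their average
observed frequencies, 250 ms bout threshold. Element durations are
stretched where necessary so that within-bout silences stay below the bout
threshold; durations never enter the IOI analysis, so this keeps the
planned bout structure exact without touching the IOI law. The simulator
makes no attempt at realistic spectra; its audio twin places tone bursts at
the annotated intervals purely so boundary detection can be tested against
known ground truth.

Passing tests on these simulations therefore demonstrate calibration,
power and localisation under *clean, stationary* conditions; they do not
speak to classifier label noise, overlapping vocalisers, non-stationary
recording noise, or rhythm at lags longer than adjacent intervals — the
ratio is strictly a local (adjacent-interval) description.

## Verification design and problem sizes

The package's own checks run at reduced but statistically meaningful
sizes, chosen as the smallest designs whose pass/fail behaviour is stable:

* *Calibration*: 200 null datasets (1 individual, 3 classes, 200 bouts),
  500 permutations at $\alpha = 0.01$; the rejection count must stay
  within the 99% binomial envelope of the nominal rate.
* *Power*: 50 replicates of planted isochrony and of the 1:2 grammar
  (3% jitter, >500 ratios); rejection in at least 95% with the top excess
  peak within 0.02 of the planted ratio.
* *Exactness*: a single stratum of 6 IOIs, whose 720 orderings are
  enumerated in full. The Monte-Carlo sampling of orderings is compared
  with the enumeration under the enumeration's own normalization
  (Kolmogorov distance), and the Monte-Carlo moment estimates are checked
  against the exact moments separately. The two effects are split because
  the maxima distribution is extremely steep: the ~1% correlated noise of
  a plug-in SD rescales the whole distribution and would otherwise
  dominate a distributional comparison even when both ingredients are
  individually correct.

## Known limitations

* The linear-RMS reading of the segmentation threshold is one of several
  defensible conventions; recordings segmented with a dB-domain criterion
  will differ in marginal elements. The fraction and reference are
  configurable.
* Pointwise confidence bands are diagnostic, not family-wise; only the
  maximal-deviation test is a calibrated decision rule. A global
  (max-envelope) band is available for conservative reading of the peaks.
* Sample size moves both the observed maximum and the permutation
  quantile, so per-individual analyses with few ratios are low-powered
  rather than anticonservative.
* The WAV reader handles PCM 16/24/32-bit and float32 mono/stereo files;
  exotic RIFF variants are out of scope.
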