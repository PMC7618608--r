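# rhythmioi

Nonparametric detection of rhythmicity in vocalization onset sequences, for
bioacousticians and comparative-communication researchers asking whether an
animal's (or a human's) vocal output is *temporally structured* rather than
an exchangeable stream of intervals.

## The method

Element onsets within a vocal bout define inter-onset intervals (IOIs).
Adjacent intervals are summarised by the revised IOI-ratio

    r_k = IOI_k / (IOI_k + IOI_{k-1}),   r_k in (0, 1)

so that 0.5 marks isochrony (1:1), 2/3 a short–long (1:2) pair and 1/3 a
long–short (2:1) pair; the legacy forward-looking convention is the exact
mirror `1 - r`. The null hypothesis is that the *order* of IOIs is random:
IOI values are exchangeable within strata (individual × ordered flanking
element classes). The observed ratio density — a fixed-bandwidth Gaussian
KDE (bw = 0.01) on a fixed 512-point grid over [0, 1] — is compared with
the densities of 10,000 stratified permutations of the IOI sequence via a
pointwise z-score-like normalized deviation. The single test statistic is
the maximal absolute deviation across the grid; significance at α = 0.01
means the observed maximum exceeds the empirical 99% quantile of the
permutation maxima. Pointwise 99% permutation bands plus local peak calls
then localise the rhythms (excess or deficit) on the ratio axis.

Because each permutation preserves every stratum's interval multiset and
the entire bout skeleton, a rejection isolates sequential structure and is
immune to the usual objection against uniform-interval nulls (natural IOI
distributions are nothing like uniform).

The package also ships the audio front-end (zero-phase Butterworth
bandpass, stationary spectral-gate noise reduction, 5 ms/1 ms RMS envelope,
1/6-global-RMS element criterion, duration-based cleaning), Praat
TextGrid/CSV/WAV I/O, class-pair subset and omission re-analyses, and a
synthetic rhythm simulator (null, isochronous, and integer-ratio grammar
datasets with per-bout tempo and timing jitter) that makes every stage
testable without recordings.

## Worked example

```r
library(rhythmioi)

# simulate a budgerigar-like session with planted isochrony
spec <- synthetic_spec(bout_count = 120, pattern = "isochronous",
                       jitter_cv = 0.03, rng_seed = 11)
elements <- generate_patterned_dataset(spec)
dataset <- build_dataset(elements, silence_threshold = 0.25)
print(dataset)
#> <rhythm_dataset> 1021 elements, 120 bouts (mean 8.51 el/bout), 901 IOIs, 793 ratios
#>   bout silence threshold: 0.25 s; individuals: ind01

result <- run_rhythm_test(dataset, inference_config(n_permutations = 2000,
                                                    rng_seed = 5))
print(result)
#> <rhythm_test_result>
#>   ratios analysed      : 793
#>   permutations         : 2000 (stratum: pair, seed 5)
#>   observed max |dev|   : 81.313196
#>   test statistic (99%) : 9.374791
#>   significant          : YES (nonrandom IOI ordering)
#>   peaks outside the confidence band:
#>     deficit at ratio 0.329 (deviation -6.92)
#>     deficit at ratio 0.352 (deviation -7.19)
#>     deficit at ratio 0.438 (deviation -8.79)
#>     excess  at ratio 0.501 (deviation +81.31)
#>     ...
```

The observed maximal normalized deviation (81.3) dwarfs the permutation
99% quantile (9.4): the interval ordering is nonrandom, and the dominant
excess peak at ratio 0.501 localises the planted isochrony; the flanking
deficits show which ratios the rhythm displaces. `plot(result)` draws the
deviation profile with bands, peak markers and integer-ratio annotations;
`write_results(result, "out.json")` serialises everything with companion
CSV tables.

From a shell the same pipeline is:

```sh
inst/cli/rhythm-ioi simulate --preset budgerigar-isochrony --bouts 120 --seed 11 --out sim.csv
inst/cli/rhythm-ioi analyze  --elements sim.csv --species budgerigar --seed 5 --out result.json
inst/cli/rhythm-ioi report   --result result.json --out report.txt
inst/cli/rhythm-ioi segment  --wav song.wav --profile budgerigar --out song.TextGrid
```

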