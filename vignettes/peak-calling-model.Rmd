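---
title: "A constrained three-state HMM for universal peak calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A constrained three-state HMM for universal peak calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmpeaks)
```

## The problem

ChIP-seq and ATAC-seq peaks span three orders of magnitude in length:
transcription-factor binding sites of ~100 bp, promoter marks (H3K4me3)
near 1 kb, and broad domains (H3K36me3, H3K27me3) covering whole gene
bodies. Most peak callers are tuned to one end of this range and fragment
broad domains or merge distinct narrow peaks at the other end. `hmmpeaks`
treats peak calling as a single unsupervised problem: model the genome-wide
binned coverage with a small hidden Markov model and derive peaks from the
model rather than from local windows, with the false discovery rate as the
only routine user parameter.

## The model

Coverage is summarized as integer tag counts in fixed, non-overlapping bins
(default 200 bp). Three hidden states generate the counts:

* **zero** — uncovered genome; a point mass at count 0;
* **noise** — background coverage; negative binomial NB(mean, r);
* **signal** — enriched coverage; a second negative binomial.

The dedicated zero state matters because most of a genome has no reads at
all; forcing the background NB to absorb the zeros distorts its mean and
dispersion. All chromosomes are independent observation sequences sharing
one parameter set — the model is global, which is what lets the same fit
describe both narrow and broad structures.

Fitting is Baum–Welch EM with a projection step after every iteration:

* `noise_min` (default 0.01 counts/bin): floor on the noise mean. Without
  it a near-zero noise state declares the entire genome enriched.
* `noise_max` (default: the genome-wide mean count per bin, computed from
  the track): ceiling on the noise mean. The true background level can
  never exceed the genome-wide average, because peaks only add reads on top
  of the background. This data-dependent boundary is what keeps the noise
  state out of the peaks on very clean tracks (see "Degenerate inputs").
* `snr_min` (default 2): floor on `signal_mean / noise_mean`. This is a
  guard against the two emitting states collapsing onto one another, not an
  enrichment requirement; values much larger than the true
  signal-to-noise ratio project the signal state onto counts it never
  emits and empty the peak set, which is why the default is deliberately
  modest.
* state-swap guard: if EM drifts the states so that the "signal" mean falls
  below the "noise" mean, the two states' parameters, transition rows and
  columns, and initial entries are swapped. The swap is checked before the
  SNR projection — after the SNR projection the condition can never be
  true, so the order matters.

The M-step for each NB uses the posterior-weighted mean (the exact
maximizer) and a profile maximum-likelihood update of the dispersion `r`,
computed on posterior weights aggregated over unique count values. A
weighted method-of-moments `r` update was tried first and measurably
decreased the observed log-likelihood on realistic tracks (EM monotonicity
only holds when the M-step maximizes); the profile-ML update restores a
true M-step at negligible cost. A likelihood decrease after a
projection-free iteration is treated as a bug and raises an error;
decreases caused by a constraint projection are expected and allowed.

EM stops when the relative log-likelihood improvement falls below `1e-3`
(default) or after 20 iterations. On well-initialized tracks 3–5 iterations
suffice.

## Initialization

Initialization is deterministic. Nonzero counts are split into a low and a
high class at the threshold maximizing the between-class variance of
`log1p(count)` (Otsu's rule); each class seeds its state by the method of
moments. A fixed-percentile split was rejected: whenever the signal
population holds more than the chosen tail fraction of nonzero bins, its
lower half leaks into the noise moments and inflates the noise mean by
50–100%.

One degenerate regime needs special handling. On an essentially
background-free track (a maximal-quality simulation: every read falls in a
peak), the nonzero bins *are* the peak bins, and any histogram split puts
the noise state inside the peaks. The guard: if the observed zero-bin
fraction is more than ten times the zero probability the candidate noise
state predicts, the background is deemed empty, the noise state is anchored
at ≤ 1 count/bin, and the signal state gets a heavy (geometric) tail so it
owns the entire enriched range. EM raises the noise level afterwards if the
data support it; the experiments in the test suite show this converges to
the same fit as the standard path on all non-degenerate tracks.

## From posteriors to peaks

Each bin gets a posterior error probability, PEP = P(zero) + P(noise) =
1 − P(signal): the posterior probability that the bin carries no signal.
Candidates at a cutoff are maximal runs of consecutive bins with PEP at or
below the cutoff; there is no gap merging, so merging only happens through
threshold relaxation.

The cutoff is chosen by scanning 40 log-spaced thresholds over
[1e-10, 0.5] and recording candidate counts and mean lengths. The count is
not monotone: relaxing the threshold merges neighbours. The selector finds

1. the first pivotal point — the first threshold with any candidate;
2. the last pivotal point — just before the "noise blow-up", detected as a
   count gain exceeding twice the largest prior gain together with a drop
   in mean candidate length (a flood of new, short noise candidates);
3. the saturation stretch — from the first grid point after the gain
   maximum where the gain falls below 5% of the maximal gain, extended as
   long as essentially no new candidates appear.

The selected threshold is the **end** of that stretch. Taking its first
point instead truncates every peak to its core (on clean simulations the
mean candidate length is half the truth there, with identical counts);
relaxing to the end of the stretch lengthens candidates without admitting
noise. If the gain never saturates (counts strictly linear in grid index),
the midpoint of the pivotal interval is used; the case is degenerate and
deterministic behavior is all that is required.

Candidates are then scored by a block-wise local Poisson model: within a
candidate, bins are ranked by PEP (ties to the leftmost), the most
confident half is kept, maximal consecutive runs of kept bins form blocks,
and each block's observed count total is tested against an upper-tail
Poisson null with rate taken from the scaled control over the block (or
`noise_mean × block length` without a control, floored at
`noise_min × block length`). The candidate log10 p-value is the
block-length-weighted mean of block log10 p-values. P-values are adjusted
by Benjamini–Hochberg (default) or Bonferroni, candidates with q ≤ FDR
survive, boundaries are refined (edge bins below 25% of the in-peak
maximum are clipped, at most 25% of the length per side), and peaks are
written as BED 6+3. The optional summit step reports local maxima of the
zero-padded 3-bin moving average, at least 5 bins apart, at least half the
peak maximum, ties broken by raw count then leftmost position.

## Control correction

A control track is scaled by the library-size ratio and subtracted with a
weight β chosen on the grid {0, 0.01, …, 1} to minimize the absolute
Pearson correlation between `signal − β·scaled control` and the scaled
control, zero-variance cases defined as 0. Corrected counts are rounded and
clamped at zero so the NB emissions still see integers. Whether the
published tool scales the control by the library ratio before fitting β is
not documented; scaling is used here and recorded in the run manifest.

## The synthetic world

The simulator is a deliberately light surrogate of model-based ChIP-seq
read simulators. Its stated world: one 10 Mbp toy chromosome, 500
ground-truth peaks at least 5 kb apart, 1 million single-end reads, a
quality grid of 100/70/50/20/10% (the fraction of reads drawn from peaks),
fragment 150 bp. Peak lengths are log-normal (sd 0.5 in log space) with
expectation 1 kb (narrow), 20 kb (broad), or a 400:100 narrow:broad mix.
Within a peak, fragment midpoints are triangular for narrow peaks
(fragments pile up around a point source) and uniform for broad domains —
a 2×-center-weighted triangle across 20 kb would starve domain edges,
which no broad mark shows; with uniform placement broad domains carry the
flat coverage they have in real data. Background reads are uniform over
the genome. The matched control is pure uniform background from an
independent seed stream.

What the simulator does **not** emulate: PCR duplication families, learned
per-peak shapes and pulldown efficiencies, mappability and GC bias,
chromatin-accessibility background structure, or paired-end libraries. A
green end-to-end test therefore establishes that the model, the threshold
selector, the scoring and the bookkeeping work as specified on data with
the stated statistical structure — not that the caller matches any
particular published benchmark on real tracks.

Known detection limit: in the mixed regime at 10% quality the in-peak
excess is ~8 counts/bin over a background of 18, and the caller finds
almost nothing. This is a property of the stated world (reads spread over
2.4 Mb of peaks), not a tunable defect; the quality-degradation property is
therefore exercised on the narrow regime, where the signal stays above the
noise floor across the whole grid.

## Numerical choices

* Forward–backward runs in log space (C++); all-`-Inf` emission rows
  raise an error naming the first impossible bin.
* The NB dispersion is kept in [1e-3, 1e6]; the upper bound is reported
  when the profile likelihood is flat toward Poisson.
* The EM monotonicity check allows `1e-6 × max(1, |LL|)` of numerical
  slack.
* β grid step 0.01; below any downstream sensitivity.
* Cross-correlation fragment estimation uses 5 bp micro-bins, shifts 0–500,
  and masks ±10 bp around the read length (the "phantom" peak); under
  1000 tags per strand or a flat profile it falls back to 150 bp with a
  warning.
* Model dumps print doubles with `%.17g`, so a reloaded model reproduces
  PEPs bit-identically.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(n_peaks = 500, n_reads = 1e6, quality = 0.5,
                        seed = 1)
dir <- tempfile(); paths <- simulate_experiment(spec, dir)
writeLines("chrS\t10000000", file.path(dir, "genome.chrom.sizes"))

cfg <- run_config(treatment = paths$treatment, control = paths$control,
                  chrom_sizes = file.path(dir, "genome.chrom.sizes"),
                  fragment = 150,
                  peaks_out = file.path(dir, "peaks.bed"))
res <- run_analysis(cfg)
#> treatment: 145690 duplicate(s) removed, 854310 tag(s) kept
#> control: 24391 duplicate(s) removed, 975609 tag(s) kept
#> control correction: beta = 0.00 (scale 0.876)
#> model: noise mean 9.907, signal mean 144.727, 3 EM iteration(s)
#> selected PEP threshold 0.5; 500 peak(s) at FDR 0.05
jaccard_intervals(res$peaks, sample_ground_truth(spec))
#> [1] 0.8426334
```

## Limitations

Bin-level resolution bounds boundary precision at ~one bin; ultra-narrow
features close to the bin size (precise nucleosome positions) are below
the design resolution, which is what the summit option partially
compensates. The HMM shares one emission model genome-wide, so strong
regional coverage trends (copy-number variation) are not modeled;
a control track is the intended remedy. Only a global background rate is
used in scoring — there is no sliding-window local lambda.
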