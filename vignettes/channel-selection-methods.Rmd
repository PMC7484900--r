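---
title: "Resting-state EEG biometrics and evolutionary channel selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG biometrics and evolutionary channel selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`restid` implements a subject-verification pipeline for resting-state EEG:
every enrolled subject gets a one-class model trained only on their own
1-second signal windows, and an intruder is anyone whose windows that model
rejects. On top of the verification pipeline sits a many-objective genetic
search that asks how few electrodes the system actually needs. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic test cohort does and does not demonstrate.

## Signal model and pre-processing

A recording is a channels-by-samples matrix in microvolts with a sampling
rate `fs` (160 Hz for the public resting-state montage this package
targets). Two steps precede feature extraction:

* **Segmentation.** Non-overlapping 1-second windows cut from sample 1; a
  trailing remainder is discarded. A 60-second run yields 60 instances.
* **Common average reference (CAR).** Each channel has the instantaneous
  cross-channel mean subtracted: $V_i' (t) = V_i(t) - \tfrac1n \sum_j V_j(t)$.
  This cancels components shared by every electrode (reference drift, line
  interference). We apply CAR per instance, after segmentation, so that each
  window is self-contained and the instance set is order-independent; because
  CAR acts sample-wise the result is identical to re-referencing the whole
  recording first.

No band-pass filtering, artifact rejection, or resampling is applied; the
pipeline's robustness comes from the one-class models, not from cleaning.

## Sub-band decomposition

Two alternative decompositions turn a 1-second window of one channel into
sub-band series.

**Empirical mode decomposition (EMD).** Sifting with cubic-spline envelopes
through the local maxima and minima (natural splines, mirrored-extrema end
extension, two extrema reflected at each boundary). A sift iteration stops
when the normalised squared change between iterates,
$\sum(h_{prev}-h)^2 / \sum h_{prev}^2$, falls below 0.2 — the classical
Cauchy-type criterion — or after 100 iterations; decomposition stops when the
residual has at most two extrema or after 10 IMFs. These internals are
configurable because the EMD literature offers no single canonical choice;
the defaults are the most common ones. Sifting is subtractive, so
$\sum_k \mathrm{IMF}_k + \mathrm{residual}$ reproduces the input to rounding
error — the test suite checks $10^{-8}$ relative on random signals. From the
IMFs we keep the **two closest to the raw signal in Minkowski distance**
$d_p(x,y) = (\sum_t |x_t-y_t|^p)^{1/p}$; spurious, low-information modes sit
far from the signal, informative oscillatory modes close to it. The order
`p = 2` is a package default (the distance order is not dictated by the
method); if sifting produces fewer than two IMFs the residual is appended so
the feature vector keeps a fixed width.

**Discrete wavelet transform (DWT).** A three-level cascade with the
biorthogonal 2.2 filter pair and symmetric signal extension, keeping the
three detail bands and the final approximation, in the fixed order
`[D1, D2, D3, A3]` — at 160 Hz roughly 40–80, 20–40, 10–20 and 0–10 Hz. The
filter coefficients are the standard published bior2.2 bank; symmetric
extension fixes the coefficient counts (82, 43, 24, 24 for a 160-sample
window), making feature vectors reproducible. bior2.2 is a
perfect-reconstruction pair, and `dwt_reconstruct()` inverts
`dwt_decompose()` to rounding error.

## Per-band features

Each sub-band contributes four numbers, in fixed order:

1. **Instantaneous energy** $\log_{10}(\frac1N \sum_t x_t^2)$ — overall band
   power.
2. **Teager energy** $\log_{10}(\frac1{N-2} \sum_n |x_n^2 - x_{n-1}x_{n+1}|)$
   — sensitive to amplitude *and* frequency modulation.
3. **Higuchi fractal dimension** — the slope of $\ln L(k)$ against
   $\ln(1/k)$, where $L(k)$ averages normalised subsampled curve lengths
   over the $k$ start offsets, $k = 1..k_{max}$ (default $k_{max} = 10$;
   capped at band length − 1 for short bands). A straight line gives 1,
   white noise 2.
4. **Petrosian fractal dimension**
   $\log_{10}N / (\log_{10}N + \log_{10}\frac{N}{N + 0.4 N_\Delta})$ with
   $N_\Delta$ the sign changes in the first differences. Zero differences do
   not break a sign run — a deterministic tie rule. Monotone signals give
   exactly 1.

Both energies are log-scaled so bands of very different power are comparable
on one scale, with a floor of $10^{-12}$ inside the logarithm so silent
bands stay finite. Constant signals return a Higuchi dimension of 1 by
convention. Per channel this yields 8 features (EMD, 2 bands) or 16 (DWT, 4
bands); per-channel blocks are concatenated in mask order, which makes
features **channel-separable**: the full per-channel feature matrix is
computed once per dataset and column-sliced per candidate channel subset —
the optimizer never touches raw signals.

No feature standardisation is applied before modelling; an explicit design
choice to keep the scale information (band energy differences) available to
the density-based classifier.

## One-class models and verification metrics

One model per subject, trained only on that subject's windows.

**Local outlier factor (LOF)**, the primary classifier, scores a query by
the ratio of the average local reachability density of its $k$ training
neighbors to its own. Inliers score near 1. Three exact neighbor-search
backends (ball tree, k-d tree, brute force) are selectable — they are index
structures only and the suite checks score agreement to $10^{-9}$. The
score-to-decision rule is the one genuinely unstated parameter of this
design: we accept a query iff its LOF score is at most 1.5, a widely used
novelty offset, and expose it in `model_spec()`. Boundary ties accept, for
determinism. Degenerate densities (duplicate points) are floored at
$10^{-10}$.

**One-class SVM** (RBF kernel) is included for comparison, delegated to the
established `e1071` solver without feature scaling; `nu` bounds the training
error fraction, `gamma` is the kernel width, and a query is accepted iff the
decision function is non-negative.

**Metrics.** For subject $s$, TAR$_s$ is the accepted fraction of $s$'s
held-out genuine windows, TRR$_s$ the rejected fraction of impostor windows
— the pooled held-out windows of every *other* subject, keeping train/test
hygiene symmetric. Overall TAR/TRR are unweighted (subject-weighted) means.
Validation repeats the whole procedure over independent random 80/20
per-subject splits (default 10 runs), reported as mean ± SD.

## NSGA-III channel selection

The search space is a mixed chromosome: one bit per channel plus two model
genes — for LOF an integer algorithm code (1 ball tree, 2 k-d tree, 3 brute)
and an integer neighbor count 1–10; for OC-SVM two reals in $[0,1]$ decoded
to `nu` (repaired into $(0,1]$) and `gamma` (repaired to $\ge 10^{-6}$).
With 64 channels that is 66 genes. Three objectives are minimized jointly:
the number of selected channels, $1-$TAR, and $1-$TRR.

The optimizer is a from-scratch NSGA-III:

* **Reference points** by the Das–Dennis systematic placement with $p = 5$
  divisions for 3 objectives — 21 points, matched to the population size of
  20. $p$ is configurable.
* **Non-dominated sorting** of the combined parent+offspring population;
  whole fronts are accepted until the population budget is hit.
* **Normalization** by the ideal point and the intercepts of the hyperplane
  through the per-axis extreme points (selected by achievement scalarizing
  functions); if the hyperplane is degenerate the per-axis spread is used,
  and a unit scale when even that vanishes.
* **Association and niching**: each member joins the reference line of
  minimum perpendicular distance; the last, partially accepted front is
  drained by repeatedly picking the reference point of minimum niche count
  (ties uniformly at random), taking the closest associated member when the
  niche is empty and a random one otherwise, and excluding for the rest of
  the generation any reference point with no remaining associated member.
* **Variation**: binary tournaments on (front rank, then association
  distance); uniform crossover (0.9) and per-bit flips at rate 1/66 for the
  channel bits; uniform resampling mutation (0.1) for integer genes;
  simulated binary crossover ($\eta = 30$) and polynomial mutation
  ($\eta = 20$, rate 0.1) for real genes. Offspring with an empty channel
  mask are repaired by setting one random bit. All rate defaults are the
  standard NSGA-II/III settings.
* **Termination**: every 10th generation the ideal and nadir points of the
  current first front are compared with those at the previous check;
  movement of at most $10^{-4}$ in every objective stops the run, with a
  hard cap of 300 generations.

All tie-breaks run through the seeded RNG stream, so a run is bitwise
reproducible from its seed. The per-run 80/20 split is frozen for all
generations of that run — otherwise the objectives would be non-stationary
under the optimizer.

**Front monitoring.** The population's first-front hypervolume is *not*
monotone generation-to-generation: once the first front exceeds the
population size, niching selects for spread along the reference lines, not
for volume, and we observed dips below 0.2%. The package therefore monitors
progress with the hypervolume of the cumulative non-dominated archive of all
evaluated points, which is monotone by construction; the test suite asserts
exactly that, plus a strict overall improvement of the population front on a
small DTLZ1 problem.

**Reporting.** Within each run the final non-dominated set is decoded into
Pareto records. Published-style tables take, per run and channel count, the
best record (highest TAR, ties by TRR) and report mean ± SD across runs —
the "mean of best per run" reading of per-channel-count tables, which we
adopt and document because the alternative (mean over all front members) is
not what a practitioner deciding on a montage would quote. Channel
occurrence counts, stratified by record size, are the tabular form of the
channel-map figures used to propose reduced montages.

## The synthetic cohort

Real multi-subject EEG cannot ship with a package, so end-to-end behavior is
demonstrated on a generated cohort designed to make the planted structure
auditable. Each subject's recording is: on the designated informative
channels, a subject-specific mixture of sinusoids plus 1/f-shaped noise; on
all other channels, the noise alone; plus a common-mode sinusoid (50 Hz,
identical on every channel) that CAR must remove. Signature frequencies are
assigned by seeded permutation of an evenly spaced grid over 5–40 Hz, so no
two subjects share a frequency and the grid spacing directly controls
separability; amplitudes are drawn from 1.5–2.5 against unit-SD noise —
roughly the regime where a 1-second window carries clearly usable but not
trivial subject information. The default test cohort is 12 subjects, 8
channels (2 informative), 60 s at 160 Hz: large enough to exercise niching
with a 21-point reference set, small enough for minutes-scale runs.

What passing tests on this cohort *show*: the full pipeline — CAR,
decomposition, features, per-subject LOF models, TAR/TRR accounting,
chromosome decoding, feature caching, and the NSGA-III loop — is wired
correctly, and the optimizer reliably concentrates its minimal Pareto
records on the planted channels. What they *do not* show: performance on
real EEG. The generator has stationary spectra, no inter-session
variability, no artifacts, no volume-conduction mixing beyond the common
mode, and subject differences located at known frequencies; real
resting-state identity cues are weaker and broader-band. Quantitative rates
on this cohort are therefore qualitative analogues of the published
full-montage and reduced-montage results, not reproductions of them — those
depend on the external 109-subject recordings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the optimizer at population
20 for up to 30 generations over 3 random-split runs on the default cohort
— sizes chosen so a complete desk run takes minutes while still filling the
reference-point set and reproducibly recovering the planted channels; the
full published protocol (10 runs, up to 300 generations, 109 subjects) is a
configuration change, not a code change. Other numerical policies collected
in one place: EDF samples quantize to 16-bit integers with per-channel
linear scaling (round trips are exact to one quantization step); Minkowski
IMF selection breaks distance ties by original IMF order; LOF self-neighbor
removal drops the farthest neighbor when duplicate rows make the self-match
ambiguous; model-fit failures inside the optimizer score as the worst
objectives `(n_channels, 1, 1)` rather than aborting a run; and an all-zero
channel mask is always repaired, never an error, because variation can
legitimately produce it.

## Known limitations

* The LOF accept threshold (1.5) is a convention, not a fitted quantity;
  real deployments should calibrate it on enrollment data.
* EMD mode mixing is untreated (no ensemble/noise-assisted variants), and
  its end effects depend on the envelope extension rule.
* The OC-SVM default `nu`/`gamma` reproduce the known failure mode of an
  unfitted one-class SVM (rejecting roughly everything); they are only
  sensible as genes under optimization.
* `segment_instances()` supports only non-overlapping windows; augmentation
  by overlap is out of scope.
* The EDF reader handles the uniform-rate subset of the format used by the
  target dataset — one sampling rate across signals, no annotation channels.
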