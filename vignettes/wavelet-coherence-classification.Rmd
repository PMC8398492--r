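---
title: "Classifying BOLD fMRI cohorts with wavelet-coherence scalograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying BOLD fMRI cohorts with wavelet-coherence scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI measures spontaneous blood-oxygen-level-dependent (BOLD)
fluctuations across the brain. After parcellation into regions of interest
(nodes, canonically the 116 regions of the AAL atlas), each subject is a
time-by-node matrix of BOLD signals. Static functional connectivity collapses
every node pair into one correlation coefficient; dynamic functional
connectivity keeps the time- and frequency-resolved structure. `boldwct`
implements a dynamic-connectivity classification pipeline for
autism-spectrum cohorts with four diagnostic labels — autistic disorder
(ASD), Asperger's disorder (APD), pervasive developmental disorder not
otherwise specified (PDD-NOS), and neurotypical controls (NC):

1. select the single most group-discriminative node from the power spectra
   of all nodes;
2. compute squared wavelet coherence between that node and every other node,
   giving one time-scale coherence map ("scalogram") per pair — 115 images
   per subject at 116 nodes;
3. train a small convolutional network on the scalogram images, either
   binary (ASD vs. NC) or four-class;
4. evaluate with stratified hold-out, k-fold, or leave-one-site-out
   protocols and macro-averaged metrics.

The package operates on ROI time series plus a cohort manifest; image
preprocessing (realignment, nuisance regression, atlas extraction) is out of
scope, as is retrieval of any clinical dataset. A synthetic multi-site
generator stands in for clinical data so every stage is testable end to end.

## Node ranking: Welch power spectra and one-way ANOVA

For every subject, each node's power spectral density (PSD) is estimated by
Welch's method: the 145-point series (TR = 2 s) is cut into 64-sample
segments with 50% overlap, each segment mean-removed, Hamming-windowed, and
its one-sided periodogram averaged. These defaults are conventional for
series of this length and are configurable (`welch_config()`); three
segments are averaged at the default sizes.

All PSD values of one subject (nodes × frequencies, DC bin excluded) are
then jointly z-scored to zero mean and unit variance, and averaged over
frequency per node, giving one score per node per subject. The joint
z-score is the normalization step that makes multi-site data comparable: a
site-specific affine gain on the raw signal scales the whole PSD matrix by a
constant and hence cancels exactly. Normalizing within subject (rather than
pooling across subjects per site) was a genuinely open choice; we normalize
within subject because it requires no site bookkeeping and removes exactly
the per-recording scale that site gain induces, while preserving
between-node contrasts — which is what the subsequent test compares.

Each node's scores are compared across the four diagnostic groups with a
one-way fixed-effects ANOVA (F on $(k-1, N-k)$ degrees of freedom). Nodes
with raw $p \le 0.05$ form the significant list, sorted ascending by $p$
(ties broken by node index); the first entry is the seed node for the
coherence stage. No multiple-testing correction is applied by default — the
selection is a ranking device, not an inferential claim — but a Bonferroni
option exists. Two degenerate conventions: a node whose scores are all
identical gets $p = 1$ (it carries no group information); groups that are
internally constant but differ in mean get $p = 0$.

The ranking deliberately always uses the full configured group set, even
when the downstream task is binary: the seed node is defined by the
four-group contrast and reused for both tasks.

## Wavelet coherence

The continuous wavelet transform of a signal $x(t)$ is

$$\mathrm{CWT}_x(a, b) = \frac{1}{\sqrt{a}} \int x(t)\,
  \psi^*\!\Big(\frac{t - b}{a}\Big)\, dt$$

with the complex Morlet mother wavelet
$\psi(\eta) = \pi^{-1/4} e^{i\omega_0 \eta} e^{-\eta^2/2}$ at
$\omega_0 = 6$. At this $\omega_0$ the equivalent Fourier period is
$a \cdot 4\pi / (\omega_0 + \sqrt{2 + \omega_0^2}) \approx 1.03\,a$, so
scale and period are nearly interchangeable — the property that makes Morlet
scalograms directly readable in frequency terms. The transform is computed
in the Fourier domain with zero padding to the next power of two; the cone
of influence (the region where edge effects exceed the $e$-folding time
$\sqrt{2}a$ of the wavelet envelope) is recorded per time point.

The squared wavelet coherence of two signals is

$$\mathrm{WCT}_{xy}(a,b) = \frac{|S(C_x^* C_y)|^2}
  {S(|C_x|^2)\; S(|C_y|^2)}$$

where $S$ smooths in time and scale. Without smoothing the ratio is
*identically* 1 — the estimator is only meaningful because $S$ averages
neighboring phases; the package exposes `smoothing = "none"` as a
diagnostic mode that asserts exactly this degeneracy. $S$ follows the
Torrence–Webster construction: in time, a Gaussian whose SD equals the
wavelet scale (`smoothing_time_factor` = 1, in scale units); in scale, a
boxcar of 0.6 decades. Both kernels are renormalized at the boundaries, so
constants are exact fixed points of $S$. Values are clipped to $[0,1]$
after floating point; the denominator is guarded so that jointly vanishing
power yields 0, not NaN. Constant (zero-variance) inputs are rejected:
coherence is undefined for them.

The scale grid runs at 12 voices per octave over Fourier periods from
$2\,\mathrm{TR}$ (Nyquist period) to $(n\,\mathrm{TR})/4$ (a quarter of the
record, above which almost every coefficient sits inside the cone of
influence); at 145 points and TR = 2 s this is 4–72.5 s in 51 scales.

## Scalogram images

Coherence maps are rasterized to fixed-size RGB images (default 224×224):
rows resampled uniformly in log-period (the scale grid is log-uniform, so
this is linear index interpolation), bilinear interpolation, then a fixed
256-level palette anchored to coherence 0 and 1. Anchoring to the
theoretical range rather than the per-image range keeps the mapping
image-independent and byte-deterministic. Rendering choices the source
material leaves open — palette, scale range, cone-of-influence masking — are
configuration fields: we default to a perceptually uniform palette
("Viridis"), the grid above, and no COI masking (full rectangular images),
and none of the package's conclusions depend on them. Phase arrows are not
rendered; only coherence magnitude enters the classifier.

## The classifier

The network is deliberately small: three blocks of (3×3 same-padded
convolution → rectified linear unit → 2×2 max pool) with 8, 16 and 32
filters, then a flatten and a dense softmax. At 224×224×3 input this is
~105k parameters. Filter counts and the dense width are package choices —
only the three-block shape, the input size, and the training regime (batch
32, 20 epochs, learning rate 0.0005, Adam; SGDM momentum 0.9 and RMSprop
decay 0.9 as alternatives) are fixed by the protocol the package
implements. Training is plain minibatch softmax cross-entropy with He
initialization; weight init and shuffling derive from one integer seed, so
identical seed + data reproduce the run bit for bit.

The engine is written in R with im2col matrix-multiplication convolutions.
This keeps the package dependency-free and fully deterministic; it is not a
GPU framework and is sized for the package's scaled-down experiments.
Inputs smaller than 224 (any multiple of 8) preserve every interface
contract and are what the test suite uses.

## Evaluation

Per-class metrics follow the usual confusion-matrix definitions (precision,
sensitivity, specificity, accuracy, F-score, reported in percent, one
decimal in reports). Multi-class reports binarize each class one-vs-rest
and macro-average with equal class weights; classes with zero support are
flagged and excluded from the average by default (scoring them as zero is
available, since published multi-class tables are ambiguous about whether
the control class enters the macro average). Undefined 0/0 ratios are
reported as 0 with an explicit flag.

Three protocols: stratified 0.7/0.15/0.15 hold-out (sizes within ±1 of
exact per class), stratified k-fold (k ∈ {5, 10, 15, 20} in the reference
protocol), and leave-one-site-out, where only sites containing every
required class are eligible test sites and ineligible sites always remain
in training. Splits default to image-level units, mirroring the reference
image counts (4140 images per class at 36 subjects, split 0.7/0.15/0.15);
a subject-level unit is provided and image-level splitting of multi-image
subjects triggers a leakage warning, because images of one subject are
correlated and image-level accuracy overstates subject-level diagnostic
accuracy.

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` emulate the statistical structure the
pipeline exploits, not fMRI physics. Each node signal is a sum of three
sinusoids with random frequencies in the resting-state band 0.01–0.1 Hz and
random phases, plus white Gaussian noise (SD 1). Group structure enters in
two places: the planted node's oscillatory amplitude is multiplied by the
group's power effect (defaults 1.6/1.4/1.2/1.0 for ASD/APD/PDD-NOS/NC,
ordered as observed spectral power across subtypes; no quantitative effect
sizes are published, so these defaults are chosen for testability, not
biological fidelity), and partner nodes mix the planted node's oscillation
with their own in a variance-preserving way
($c z + \sqrt{1-c^2} w$, phase-locking $c$ = 0.9/0.7/0.5/0.3 by group).
Site effects are a linear gain and offset per site (four default sites,
gains 0.9–1.2), the simplest mechanism that makes the z-score normalization
consequential. One master seed derives per-subject streams from
(site, group, index), so generation is order-independent and bit-exact.

The generator does *not* model hemodynamic response, physiological noise,
drift, motion, autocorrelated 1/f noise, or realistic between-site
covariance shifts. Passing tests therefore demonstrate that the pipeline
recovers planted spectral-power and phase-coupling structure under
controlled conditions — not that it attains any particular accuracy on
clinical data.

## Numerical choices and degenerate inputs

* Truncation to the common length keeps the *first* $T_{\min}$ samples
  (earliest samples exist at every site); it is idempotent and never alters
  retained values.
* Group balancing downsamples uniformly at random with a recorded seed,
  preserving subject order (the selection rule in the source protocol is
  unstated).
* Welch requires the signal to be at least one segment long; the PSD grid
  is capped at Nyquist.
* p-value ties in the ranking break toward the lower node index.
* Coherence values are clipped to $[0,1]$; a 0/0 coherence ratio is 0.
* Holdout/fold allocation uses largest-remainder rounding, so per-class
  sizes are within one item of the exact ratios.

## Problem sizes used by the test suite

The suite exercises every contract at desk scale: cohorts of 4–36 subjects
per group with 4–116 nodes and 64–145 time points, 16×16–32×32 rasters for
CNN training, 2–20 training epochs. Monte-Carlo suites use 20 seeded
replicates (planted-node recovery, band-limited coherence contrast,
Parseval mass), 100 replicates for the ranking's type-I error, and 500 for
ANOVA null uniformity; brute-force permutation ANOVA (4000 permutations)
serves as the oracle on small instances. The end-to-end recovery check
trains on cohorts with deliberately strong planted effects
(power ratio 3:1, coupling 0.95 vs 0.05) and requires held-out accuracy at
least 20 points above chance across three seeds.

## Known limitations

* The CNN engine is CPU-bound R; full-scale runs (thousands of 224×224
  images, 20 epochs) are possible but slow. The architecture's filter
  counts are package defaults, so trained weights are not comparable to any
  external implementation — only the architectural shape and training
  regime are.
* Coherence significance testing against red-noise nulls, and phase-lag
  (in-phase/anti-phase) decomposition, are out of scope.
* Image-level splitting, the default because it mirrors the reference
  protocol's counts, leaks subject identity across partitions; use
  `split_unit = "subject"` for diagnostic claims.
* The synthetic generator's group effects are stylized; no claim of
  clinical realism is made.
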