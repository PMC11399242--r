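---
title: "Methods: multi-metric resting-state analysis of pharmacological sedation"
author: "sedconn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-metric resting-state analysis of pharmacological sedation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedconn)
```

# The scientific problem

Benzodiazepine sedation reorganizes spontaneous brain activity in a
characteristic way: long-range functional connectivity (FC) between cortical
regions weakens — connection density, network efficiency and the
interconnection of hub regions (the rich club) all drop — while *local*
synchrony and slow (< 0.05 Hz) BOLD fluctuations in low-level sensory
cortices increase. Placebo-controlled repeated-measures pharmaco-fMRI
studies probe this signature by scanning each subject under several
interventions (baseline, placebo, a sedating drug, a putatively non-sedating
anxiolytic) and comparing, within subject, a battery of complementary
resting-state metrics.

`sedconn` implements that entire analysis battery for surface-sampled BOLD
data, together with the repeated-measures inference layer and a synthetic
study generator with planted effects, so that every stage can be validated
end-to-end against known ground truth.

# The metric battery

## Whole-brain functional connectivity graphs

ROI time courses are unweighted means of vertex time courses over a
parcellation, band-pass filtered to 0.01–0.1 Hz. FC is the Pearson
correlation matrix; binarizing at a threshold $\sigma$ (default grid 0.5,
0.6, 0.7, applied to the *signed* correlation) yields an undirected graph
per session. Graph measures follow the standard conventions:

* **edge density** — realized edges over $N(N-1)/2$ (isolated nodes count in
  the denominator);
* **global efficiency** — mean of $1/d_{ij}$ over distinct pairs, 0 for
  disconnected pairs (no largest-component restriction);
* **local efficiency** — mean over nodes of the global efficiency of the
  neighbour-induced subgraph, 0 for degree < 2;
* **rich-club coefficient** $\phi(k)$ — edge density of the subgraph induced
  by nodes of degree strictly greater than $k$; reported raw (no random-graph
  normalization), undefined (flagged `NA`, not an error) when fewer than two
  nodes survive;
* **nodal degree, efficiency and betweenness** — betweenness uses fractional
  (Brandes) counting, excludes endpoints, and is normalized by
  $(N-1)(N-2)/2$.

Shortest-path machinery is delegated to `igraph`; every metric is verified
in the test suite against an independent brute-force oracle (pure loops over
pairs and paths) on hundreds of small random graphs.

## Surface ReHo

Regional homogeneity at a vertex is the mean Pearson correlation over all
unordered pairs of time courses in its k-hop mesh neighbourhood, centre
vertex included. Inclusion of the centre matches the volumetric ReHo
convention and keeps the statistic well-defined for small neighbourhoods;
the synchrony statistic is the average pairwise correlation (not Kendall's
W of the classic volumetric formulation). The default radii are 2 and 4
hops. ReHo is computed on 0.01–0.1 Hz band-passed data by default; the
unfiltered order is available (`band = NULL`).

## fALFF

The fractional amplitude of low-frequency fluctuations is the ratio of
summed spectral amplitudes (square roots of untapered periodogram power) in
0.01–0.05 Hz to the full band, DC excluded from both sums. The series is
demeaned but *not* linearly detrended by default: subtracting a fitted line
from trend-free data injects $1/f$-shaped broadband leakage that costs a
pure in-band sinusoid several percent of its amplitude fraction, breaking
the metric's analytic anchor (a bin-aligned in-band sinusoid must give
fALFF ≈ 1). Linear detrending remains available (`detrend = "linear"`) for
data with real scanner drift, which is the one situation where it helps.
Band membership is decided by exact frequency comparison with a 1e-12
tolerance; an exactly constant series yields fALFF 0 with a warning.

## Constrained ICA

Subject-level resting-state networks are extracted in the spatial-ICA
orientation (components are vertex maps, mixing over time) from 0.2 Hz
low-passed data. For each reference map the package maximizes a log-cosh
negentropy approximation with one-unit fixed-point updates, subject to the
inequality constraint that the component's spatial correlation with its
reference stays at or above `rho_min` (default 0.2). The constraint enters
as a penalty whose weight doubles whenever it is violated; the weight vector
is sign-aligned to the reference inside the loop (the fixed point is
sign-ambiguous, and a naive signed constraint check would oscillate).
Components are extracted sequentially with Gram–Schmidt decorrelation,
initialized from the reference projected into whitened space (seeded random
fallback), and z-scored across vertices. Dimensionality is reduced to 30
principal components first; for long sessions the top eigenpairs come from
a seeded randomized subspace iteration (Gaussian sketch, two power
iterations), which is accurate to working precision for the well-separated
leading spectrum this reduction needs and keeps the per-session cost low.
Non-convergence after `max_iter` flags the component and returns the best
iterate.

Because the optimizer and exact objective of reference-guided ICA vary
across the literature, the package's validation surface is *simulation
recovery*, not equation fidelity: planted sparse non-Gaussian sources mixed
with smooth time courses at SNR 5, references corrupted to r ≈ 0.8, must be
recovered with truth correlation ≥ 0.95 (averaged over seeds).

## Within-network coherence

For group comparison the package summarizes each fitted component as the
mean correlation between the component's time course and the low-passed
time courses of the vertices in the network's reference mask. This
vertex-level statistic responds to genuine changes in within-network BOLD
synchrony (more shared signal per vertex raises it) while remaining
comparable across subjects; the thresholded mask extent (|z| ≥ 2 by
default) is reported alongside.

# Repeated-measures inference

All condition contrasts are within-subject paired t-tests (two-sided, df =
n−1, Cohen's d = mean/sd of differences), with Benjamini–Hochberg FDR at
q ≤ 0.05 applied within each metric family (global graph; rich-club PCA;
nodal degree/efficiency/betweenness at the middle σ; ReHo per radius;
fALFF; network coherence). Benjamini–Yekutieli is available behind a flag.
Exactly zero differences give t = 0, p = 1 (flagged degenerate); constant
*nonzero* differences are undefined for the t statistic — the low-level
`paired_t()` refuses them, while study-level tables record them as
infinite-t degenerate rows so a single degenerate metric cannot abort a
study comparison.

Rich-club curves are compared via their loadings on the first principal
component of the stacked per-subject curves (computed on the shared degree
grid from `max_common_k()`), because $\phi(k)$ at neighbouring cutoffs is
nearly collinear; the PC1 sign is fixed to a positive mean loading so a
positive t means "higher curves". The PC1 explained-variance fraction is
reported with the test.

Side effects are ordinal 0–3 ratings for 17 symptoms over 5 treatment
days. The paper-level aggregation being unstated, ratings are averaged over
days within subject before testing, and BH-FDR is applied jointly across
all symptom-by-condition-pair tests.

Two pharmacokinetic utilities support study-design reasoning:
`fraction_eliminated()` (single-compartment first-order decay,
$1-2^{-t/t_{1/2}}$) and `accumulate_doses()` (instant-absorption
superposition of repeated doses). Steady-state accumulation percentages
depend on exact intra-day dose times, which are not part of the package's
inputs; only the elimination bound is asserted.

# The synthetic study generator

`make_study()` builds a deterministic desk-scale study: a triangulated
rectangular grid cortex (default 20×30 vertices at 3 mm spacing = 24 square
ROIs of 25 vertices), 8 networks of 3 ROIs, 6 designated sensory ROIs
(networks 1–2), 30 subjects × 4 conditions × 600 timepoints at TR = 1 s,
with ordinal side-effect ratings. Sessions are materialized lazily and
reproducibly from a hierarchical counter-based seed (a fully materialized
study would occupy several gigabytes); subsetting subjects never changes
the data of others. The grid (rather than an icosphere) is the default
because it factors exactly into equal square parcels, which the
configuration contract requires; icosphere meshes are provided for
closed-surface work and are used by the smoothing tests.

Each session is built from four ingredients:

1. **ROI latents** — band-limited (0.008–0.12 Hz) Gaussian processes with a
   block covariance: r = 0.6 within network, 0.2 between, off-diagonals
   multiplied by the condition's `coupling_scale`.
2. **Local fields** — per-ROI band-limited carrier signals mixed through
   smooth zero-mean spatial basis patterns (mean-centred Gaussian bumps at
   the patch corners, per-vertex normalized; amplitude `patch_sd` = 0.4).
   Nearby vertices share field signal, but the exact-zero patch mean keeps
   the ROI average — and therefore every FC quantity — essentially
   unaffected. This separates the spatial scale ReHo sees from the scale FC
   sees.
3. **In-band vertex noise** — independent band-limited noise
   (`inband_noise_sd` = 0.9, synthesized spectrally), modelling
   physiological in-band noise; without it, in-band vertex signals are
   nearly noise-free and baseline ReHo saturates near 1, leaving no dynamic
   range for planted local-coherence effects.
4. **White measurement noise** — per-condition `noise_sd` (default 0.7).

Condition knobs map onto the sedation signature as follows.
`coupling_scale < 1` weakens all inter-ROI correlation — edge density,
efficiency and rich-club interconnection fall. `local_coherence_boost`
multiplies the *entire shared within-patch signal* (latent + field) of
sensory ROIs; since rescaling a region's signal leaves every inter-regional
correlation invariant, this raises vertex-level synchrony (ReHo, coherence
with the network time course) without touching FC — which is exactly the
dissociation the sedation literature describes. `lowfreq_gain` multiplies
the 0.01–0.05 Hz component of sensory ROI latents, raising sensory fALFF
(and, mildly, sensory ReHo) while leaving correlations unchanged.
Side-effect probabilities are per-symptom Binomial(3, p) parameters, with
fatigue, sleepiness, concentration problems, dizziness and confusion
elevated (p = 0.5 vs 0.08) in the sedation profile.

What the generator deliberately does *not* model: hemodynamic response
convolution, motion and physiological artifact spectra, spatially
heterogeneous ROI sizes, inter-subject anatomical variability, and
amplitude non-stationarity. Passing the planted-effect tests therefore
shows that the pipeline's statistics detect the targeted covariance and
spectral structure at realistic noise levels and sample sizes — not that
the pipeline is robust to every artifact of real acquisitions.

# Numerical choices

* **Zero-phase filtering.** Butterworth order 4, applied forward–backward.
  The combined transfer function $|H(\omega)|^2$ is evaluated exactly from
  the digital filter coefficients and applied spectrally after odd-reflection
  end padding (one low-edge period for band-passes; 12 cutoff periods for
  low-passes). This is the same linear response as a time-domain
  forward–backward pass, without startup transients, and filters a whole
  session in a single FFT. In-band sinusoid amplitudes are preserved within
  5% and stop-band amplitudes attenuated below 10% by construction; both are
  asserted in the tests.
* **Smoothing.** Geodesic distances are approximated by shortest edge paths
  (Dijkstra with Euclidean edge weights); the Gaussian kernel
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, truncated at $3\sigma$) is
  normalized by symmetric Sinkhorn balancing, making the operator doubly
  stochastic: weights sum to 1 per vertex *and* the global mean of any map
  is preserved exactly, including on closed meshes, which plain row
  normalization cannot achieve. Row normalization remains available and is
  the mode in which the impulse response equals the truncated kernel
  exactly.
* **Degenerate inputs.** Constant vertices get ReHo/fALFF 0 with a warning
  rather than NaN; empty ROIs, out-of-range labels, vertex-count mismatches
  and rank-deficient ICA inputs raise validation errors naming the culprit.
* **Ties and sign conventions.** Rich-club uses strict degree inequality;
  PCA signs are fixed by positive mean loading; ICA components are
  sign-aligned to positive reference correlation.

# Validation problem sizes

The test suite exercises the full pipeline at the generator's default desk
scale: 30 subjects × 2 conditions × 600 vertices × 600 timepoints per
planted-effect or null run; 5 seeds for planted-effect recovery, 20 seeds
for null calibration, 500 random graphs for the metric oracle, and 5
simulations for ICA recovery at 1320 timepoints. These sizes give stable
detection/false-positive estimates while keeping a full run of the suite
and of `scripts/acceptance.R` in the tens of minutes on a single core.

# Known limitations

* The k-hop neighbourhood radius is a graph-distance proxy for a metric
  radius; on strongly non-uniform meshes the physical neighbourhood size
  varies across the surface.
* Rich-club coefficients are raw; comparisons across graphs of very
  different density conflate density with club structure (the PCA-loading
  test operates within the common defined-k grid, which mitigates but does
  not remove this).
* The constrained-ICA objective is one member of the reference-guided ICA
  family; different penalty schedules or contrast functions can yield
  slightly different component boundaries, which is why validation is by
  source recovery rather than by comparing to a specific published
  optimizer.
* Group inference is limited to paired t-tests with FDR control, matching
  the study design it implements; ordinal alternatives and mixed-effects
  models are out of scope.
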