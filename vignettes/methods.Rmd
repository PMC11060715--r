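---
title: "From raw ROI fluorescence to neural assemblies: the models behind catraces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw ROI fluorescence to neural assemblies: the models behind catraces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catraces)
```

## Scope and data model

`catraces` implements the analysis chain used for awake two-photon calcium
imaging of cortical populations in head-fixed mice: preprocessing of raw
ROI and peri-somatic neuropil fluorescence into ΔF/F, detection of
statistically significant calcium transients, movement-conditioned firing
rates, bootstrap-validated functional connectivity, detection of
overlapping neural assemblies by PCA with an oblique Promax rotation, and
the accompanying widefield sensory-map and behavioral kinematics metrics.
Raw movies are out of scope: the package starts from motion-corrected ROI
trace matrices (neurons × frames), a frame-aligned animal speed trace, and
— for the mesoscale part — trial-stacked widefield images.

Every stage is verifiable by parameter recovery because the package ships
its own synthetic-data generator that plants known structure. The
generator's defaults are the study conditions we validate under:
populations of 100 neurons recorded for 600 s at 25 Hz (pair-averaged to
an effective 12.5 Hz), five planted assemblies of ten neurons each firing
synchronous events at 0.05 Hz, per-neuron Poisson background at 0.05 Hz
(~3 events/min, a realistic rate for quiet cortex), GCaMP6S-like
single-exponential transients with τ = 1.8 s and peak ΔF/F of 1.0,
additive white Gaussian noise of 0.05 ΔF/F, a slow sinusoidal baseline
drift (amplitude 0.05 ΔF/F, period 120 s), and linear neuropil
contamination with coefficient 0.4.

## Trace preprocessing

Frames are group-averaged in pairs (`group_average_frames()`, k = 2),
halving the rate to 12.5 Hz. Neuropil contamination is removed linearly,

$$F_\mathrm{corrected} = F_\mathrm{raw} - \alpha\, F_\mathrm{neuropil},
\qquad \alpha = 0.4,$$

the conventional coefficient for somatic GCaMP recordings. The baseline
$F_0$ is the running 8th percentile of the corrected trace over a centred
30-s window, smoothed by a 30-s running mean; windows are truncated at the
session edges rather than padded, so no data are fabricated at the
boundaries. ΔF/F is $(F - F_0)/F_0$. The synthetic generator applies its
contamination as $+\alpha_\mathrm{true} F_\mathrm{neuropil}$ (uncentred),
so that the correction formula recovers the uncontaminated trace exactly
and planted ΔF/F amplitudes round-trip within 1% — a centred contamination
term would leave a constant offset in the corrected trace that rescales
ΔF/F by a factor of roughly $B/(B - \alpha \bar F_\mathrm{np})$ and make
amplitude recovery impossible.

A note on the double 30-s pass: the running low percentile alone is a
biased (lower-envelope) estimator with step artifacts; the second running
mean smooths it. Both windows share the 30-s scale so the baseline has a
single timescale parameter.

## Noise model and transient detection

The per-neuron noise sd is estimated from sub-median fluctuations only
(negative deviations mirrored): sparse positive transients shift the
median negligibly and do not inflate the estimate, which is exact for a
transient-free Gaussian trace.

Detection uses a *dynamic* threshold. Each ΔF/F trace is first centred on
its 30-s running median — a robust local zero that removes the residual
slow error the percentile baseline leaves behind (a running lower
quantile under-tracks drift crests) while leaving sparse transients
intact. A frame is a candidate iff the centred trace exceeds the
one-sided 98% bound of the noise, $q_{0.98}\,\hat\sigma$. Contiguous
supra-threshold runs (runs separated by less than a quarter of τ are the
same event — noise momentarily dips a decaying transient below threshold)
form candidate events, kept only if their decay is compatible with the
indicator kernel: a decay constant estimated from the event onset must lie
in $[\tau/2,\, 2\tau]$ with τ = 1.8 s for GCaMP6S. Two complementary
estimators are computed and the event is kept if either is in band:

* an initial-slope log-linear fit over the contiguous supra-noise samples
  — insensitive to later burst contamination, but noisy near the floor;
* a mass-to-amplitude ratio — a noiseless exponential of amplitude $A$
  integrates to $\approx A\,\tau f_s$ samples, so
  $\hat\tau = (\sum_t x_t / A - 1/2)/f_s$ with a finite-horizon
  correction; this is insensitive to per-sample noise but biased by
  overlapping events.

Under the study noise (σ = 0.05), this detector leaves ≤ 2.5% of
noise-only frames inside events (measured ≈ 0.3%) and detects planted
5σ-amplitude transients with sensitivity above 0.9 (measured ≈ 0.97).
Raising the confidence level shrinks the candidate set monotonically;
*event counts* are guaranteed monotone only for well-separated transients,
because at permissive thresholds two events can fuse into one run.

Movement is segmented at the 25-Hz tracking rate by a 30 mm/s speed
threshold, with state runs shorter than 6 frames (240 ms) absorbed into
the surrounding state, then resampled to the effective imaging rate by
2-frame majority blocks. Event rates are onset counts divided by minutes
in each state — transients are events, not durations.

## Functional connectivity

Pairwise Pearson correlations are computed between z-scored traces.
Significance comes from the stationary block bootstrap: one member of each
pair is resampled in blocks of geometrically distributed length (mean 23
frames = 1.84 s at 12.5 Hz, matching the indicator decay time) with
uniform random start points and circular wrap-around. This preserves the
trace's autocorrelation while destroying cross-correlation, which is
exactly the null needed for a dependence test between autocorrelated
series. An edge is significant if r exceeds the pair's 99th-percentile
null. Full analyses use 5000 iterations; the calibration checks here use
1000, which already brings the empirical false-positive rate of fresh
independent white-noise pairs to 1.0% ± 0.5%.

One resampling schedule is shared by all neurons within an iteration
(resampling the second pair member), making the cost one matrix
cross-product per iteration instead of one per pair; thresholds stay
per-pair. Whether one or both members should be resampled is not
determined by the construction — resampling both is available by passing
pre-resampled traces, but one-sided resampling is the default since the
null only requires breaking the cross-dependence.

Graph metrics follow the field's conventions: connections per neuron is
total significant edges over neurons; strong edges are significant edges
with r > 0.3; density is significant edges as a percent of
$n(n-1)/2$. Undefined pairs (zero-variance traces) are excluded from
edges but stay in the density denominator.

## Neural assemblies

Assemblies are detected on the z-scored traces by PCA followed by a
Promax oblique rotation (power 4, the conventional default), which lets
components correlate and therefore lets neurons belong to several
assemblies.

**How many components?** The default rule compares the eigenvalues of the
neurons' correlation matrix against a *circular-shift surrogate* bound:
each trace is circularly shifted by an independent random offset —
preserving its autocorrelation, destroying co-activation — and the
largest eigenvalue over 10 shuffles is the cut-off. The analytic
Marchenko–Pastur edge $(1 + \sqrt{n/T})^2$ is available as an option and
is exact for white traces, but calcium traces are strongly autocorrelated
through the indicator kernel, which widens the null spectrum: under the
study conditions the i.i.d. edge (≈ 1.3) admits several noise components
(eigenvalues up to ≈ 1.7) while the shift-surrogate bound (≈ 2.6) cleanly
separates them from planted structure (≥ 3.7). Spurious noise components
are not harmless — their diffuse loadings flood the loading distribution
that the membership threshold is read from.

**Membership.** Each rotated component's loadings are z-scored; a neuron
belongs to a component if its z-scored loading exceeds `z_max`. The
default `z_max` is located automatically on the distribution of each
ROI's maximal z-scored loading, as the deepest trough between the two
highest peaks of its kernel-density estimate — an algorithmic surrogate
for picking the "first clear minimum" by eye, robust to shallow wiggles
inside either mode. A fixed override is available; if the distribution is
unimodal (no separating trough) the mean is used and a warning raised.

**Merging.** Oblique rotation can split one cell group across components,
so memberships whose unit-normalized indicator vectors have dot product
$|A \cap B|/\sqrt{|A||B|} > 0.6$ are merged, greedily from the largest
dot product with ties broken by lower component index.

**Surrogate validation.** Each assembly's peak frame-wise event
co-activation count is compared against surrogates in which every
member's event-onset train is independently circularly shifted; with the
add-one estimator $p = (1 + \#\{\text{surrogate} \ge \text{observed}\})
/(n_\mathrm{surr}+1)$, assemblies with $p \ge 0.05$ or fewer than two
members are dropped. Onset trains (not active-duration rasters) carry the
synchrony information: long supra-threshold durations make peak
co-activation chance-achievable and the test uninformative. The max
statistic is discrete, so the test is conservative under independence
(its null rejection rate is below the nominal 5%); it is not a
calibrated-power test but a validity filter.

**Activation statistics.** The matching index of assembly $a$ at frame
$t$ is the fraction of its members active, $|A \cap \mathrm{active}(t)|
/ |A|$ (a Jaccard-style variant dividing by the union with the active set
is available; the proportion form is the default as the natural reading
of "proportion of neurons within the assembly"). Activation significance
at each frame is the exact hypergeometric upper tail of drawing at least
$k$ members among the $m$ active neurons from the population of $N$ —
the canonical distribution parameterized only by the assembly and
population sizes. Being an exact discrete test it is conservative: its
null rejection rate is the largest attainable tail below the threshold,
≈ 0.03 rather than 0.05 at $N = 100$, $K = 10$ — it never over-rejects.
Assembly–assembly and assembly–speed correlations are computed on the
significance-masked matching-index series with the same stationary
bootstrap as neuron pairs, and means are reported over significant pairs
only.

Under the study conditions the full chain (raw fluorescence → ΔF/F →
transients → assemblies) recovers all five planted assemblies with mean
best-match Jaccard ≥ 0.8 across ten seeds, including a neuron planted in
two assemblies appearing in both detected memberships.

## Widefield response maps

Trial stacks are averaged across trials first; the response map is
$(\overline{\mathrm{post}} - \overline{\mathrm{pre}})
/\overline{\mathrm{pre}}$ over 10-frame (1-s at 10 Hz) windows. The
difference convention is the default so the map is in ΔF/F units
(a pure post/pre ratio is available behind a flag). The baseline sd map
is the per-pixel sd of the pre-stimulus ΔF/F frames of the trial
average, and maps are thresholded at 5 of those sd. Area is mask pixels
times the squared pixel scale; map position is the intensity-weighted
centroid over the supra-threshold mask (the deterministic choice; the
map-displacement statistic needs *some* position summary and the
intensity-weighted one is robust to mask-edge noise). Coordinates are
0-based pixels, x = column, origin top-left. On planted Gaussian
phantoms the thresholded area matches the analytic level-set area
$\pi\sigma^2\,2\ln(A/k\sigma_b)$ within 10% and planted centroid offsets
are recovered to within half a pixel.

## Behavioral kinematics

String-pull metrics: path circuity is total distance travelled over the
start–end chord (≥ 1, 1 iff straight and monotone); movement scaling is
the Pearson correlation between per-event path lengths and peak speeds;
the bimanual correlation is computed after linear least-squares
detrending of each paw's vertical position (the lowest-order "detrending"
consistent with removing postural change). Tapered-beam metrics count
slips by side and report the distance to the first slip; slip-free runs
score the full beam length so that farther-is-better ordering survives
averaging.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed, and the pipeline expands
its master seed into fixed per-stage substreams, so a `(config, seed)`
pair reproduces byte-identical output tables. The packaged validation
uses deliberately economical problem sizes — 1000-iteration bootstraps,
40-neuron calibration batches, 60-neuron pipeline smoke runs, 10-seed
recovery at the full 100-neuron study scale — chosen so the whole
validation suite replays in a few minutes while keeping every Monte Carlo
tolerance at least three standard errors wide.

## What the synthetic data does not emulate

The generator plants the statistical structure the analysis assumes —
Poisson events, exponential kernels, additive white noise, sinusoidal
drift, linear contamination, Gaussian widefield blobs, piecewise paw
paths. Real recordings violate several of these: noise is not white
(shot noise scales with brightness; neuropil residuals are structured),
drift is not periodic, transient amplitudes vary with burst length, and
assemblies in vivo are neither equal-sized nor stationary through a
session. Passing recovery tests therefore certifies the implementation
of the method, not the method's adequacy on any particular real dataset.
Known limitations worth keeping in mind: the detector's τ-band rejects
strongly overlapping event bursts as single distorted events;
the hypergeometric activation test is conservative; and the
shift-surrogate PC rule assumes activity is stationary over the session.
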