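---
title: "Virtual decoupling and sharpening of methyl NMR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual decoupling and sharpening of methyl NMR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Methyl-TROSY spectroscopy gives sharp, interpretable 13C-1H correlation maps
of very large proteins, but classically requires perdeuterated samples with
specifically 13C-1H labelled methyl groups. A uniformly 13C-labelled,
protonated sample is far cheaper and labels every methyl-bearing side chain,
but its spectra are degraded in two ways: one-bond 13C-13C scalar couplings
split each indirect-dimension signal into a doublet (methyl carbons, one
coupling partner) or a triplet (non-methyl CH carbons, two partners), and
the dense proton bath broadens lines in both dimensions through dipolar
relaxation. `fidnetr` implements the computational route around this: two
gated dilated convolutional networks, applied to time-domain vectors inside
an otherwise conventional Fourier processing pipeline, that (i) remove one
cosine coupling modulation per signal and sharpen the 13C dimension and
(ii) sharpen the 1H dimension.

## Signal model

Every synthetic vector is a sum of decaying complex exponentials with
cosine amplitude modulations,

$$ s(t_k) \;=\; \sum_j a_j\, e^{\,i 2\pi f_j t_k}\, e^{-R_{2,j} t_k}
   \prod_{c} \cos(\pi J_c t_k), \qquad t_k = k/\mathrm{SW}, $$

with one coupling $J_c$ for methyl signals and two for non-methyl CH
signals. 1H-1H couplings, cross-correlated relaxation and methyl rotor
dynamics are deliberately outside the model: the networks are trained to
invert exactly this forward model, nothing more. Frequencies convert
between ppm and Hz through the Larmor frequency of the axis
(`hz = ppm * MHz`), and frequencies outside the acquired window alias by
wrap-around, as they do in a real indirect dimension.

## The target map for relaxation rates

Training targets replace each input rate $R_2^{\mathrm{in}}$ by

$$ R_2^{\mathrm{tar}} = \max\!\Big( R_2^{\max}\tanh\tfrac{R_2^{\mathrm{in}}}{R_2^{\max}},\;
   R_2^{\max}\big(1 - \tanh\tfrac{R_2^{\mathrm{in}}}{R_2^{\max}}\big) \Big), $$

with $R_2^{\max} = 25\,\mathrm{s^{-1}}$. Broad signals are sharpened
towards $R_2^{\max}$ from above and already-sharp signals are broadened up
towards it from below, so target linewidths are roughly uniform — sharp
peaks are *not* sharpened further, which avoids truncation artefacts. The
map is continuous, bounded in $[R_2^{\max}/2,\, R_2^{\max}]$, and attains
its minimum exactly at $R_2^{\mathrm{in}} = R_2^{\max}\,\mathrm{atanh}(1/2)$;
the test-suite asserts all three properties against closed forms.

## Network architecture and training

Each network maps a real-valued 4 x L plane to a plane of the same shape.
The packing is fixed across training, inference and dataset headers and is
recorded in every manifest and weight sidecar: rows are Re and Im of the
complex vector, then Re and Im of its one-sample-advanced copy; planes are
normalised by the maximum absolute value of the input plane and the scale
is inverted on exit. The advanced copy gives the first convolutional layer
direct access to a finite-difference of the signal at no cost.

The body is a stack of residual units, one per entry of the dilation
schedule. A unit applies a dilated convolution with kernel 8 (time) x 4
(rows), splits its filters into a sigmoid half and a tanh half whose
elementwise product forms the gated activation, and applies a second
8 x 4 convolution. Each unit's output is added to the unit input (feeding
the next unit) and into a skip aggregate; a 1x1 projection of the skip
aggregate forms the network output. Where the published description leaves
open whether the gated product or the second convolution feeds the skip
sum, this implementation uses the second convolution's output and records
that choice in the weight sidecar. Convolution padding is "same" along
both axes (even-kernel convention: left pad 1 row / 3d time samples), so
the shape contract demanded by the residual and skip sums holds exactly.

The full-scale 13C network uses L = 1024, dilations 1, 2, 4, 6, 8, 10, 12,
14, 16, 20, 24, 28, 32, 40, 48, 56, 64 and 128 filters per layer; the 1H
network L = 512, dilations up to 32, and 64 filters. The training loss is
the mean squared error between the real parts of the discrete Fourier
transforms of predicted and target planes; the optimiser is RMSprop
(rho = 0.9, epsilon = 1e-7) at a learning rate of 1e-4 reduced to 1e-5 at
the first validation plateau and stopped at the second. A plateau is "no
validation improvement greater than 1e-6 for 5 consecutive epochs" — the
published schedule names no tolerance, so this package fixes one. The
engine (forward, backward, update) is implemented in C++; the backward
pass is validated against central finite differences in the test-suite.

### Reduced study conditions

Training the full architecture on 500,000 pairs is accelerator-scale work.
The package therefore defines a *reduced* configuration, which the
test-suite trains end to end on one CPU: L = 256, dilations 1, 2, 4, 8,
8 filters, 2,000 training and 200 validation pairs, mini-batches of 16,
RMSprop at 1e-3 then 1e-4, at most 30 epochs. Reduced training planes use
a fixed 2000 Hz sweep width, 1-4 signals per plane, doublets only,
$R_2 \sim U(20, 80)\,\mathrm{s^{-1}}$, $J \sim N(34, 2)$ Hz, log-uniform
amplitudes over one decade, offsets uniform over the central 80% of the
window, and complex Gaussian noise with sigma equal to 1% of the largest
amplitude. Signals occupy the first 128 points and the remaining 128 are
zero — matching what the enhancement pipeline feeds the network after
zero-filling. These conditions were fixed before training and are the
conditions under which the scaled-down claims (doublet-to-singlet
conversion on held-out planes, loss improvement over the identity
baseline) are evaluated; they are not tuned per run.

Because the reduced 13C network trains on doublets only, non-methyl
triplets in benchmark spectra are only partially collapsed by it, and
their leftover outer components inflate the false-positive count at
reduced scale. The full-scale training distribution includes two-coupling
signals (half the signals, matching the benchmark composition), which is
the configuration a production training run would use.

## The enhancement pipeline

For a 2D plane (1H acquisition axis, 13C indirect axis) the workflow is:
Fourier transform the 1H dimension (first point scaled by 0.5, no
apodization, zero-filled once) and discard imaginaries after phasing;
optionally band-select the methyl region if the dimension is longer than
the 1H network input; pass each 13C interferogram through the decoupling
network (zero-filled to its input length); Fourier transform the 13C
dimension; reconstruct the 1H imaginaries by Hilbert transform and inverse
Fourier transform back to the time domain; pass each 1H vector through the
sharpening network; re-transform the 1H dimension. Every step appends a
provenance entry sufficient to replay the processing. The 3D variant
applies the 13C network along each indirect axis in turn (NOESY axis
first by convention — the order provably does not matter for the linear
steps and is logged) and the 1H network once via the same Hilbert route.

Numerical choices worth knowing:

* **Zero-filling the 1H dimension once before discarding imaginaries makes
  the Hilbert reconstruction exact** (for signals whose first point has no
  imaginary component, which holds for sums of in-phase resonances). In
  consequence the whole pipeline with identity stand-in networks equals
  plain Fourier processing to floating-point accuracy (~1e-15 relative;
  asserted at 1e-10). After a trained, nonlinear network the
  reconstruction is the same approximation the experimental workflow uses.
* **No apodization is applied before either network** — they are trained
  on unapodized decays. A cosine bell is available in the final display
  transforms only (`display_apodize = "cosine"`), where its window spans
  the *signal support* rather than the zero-filled length, so it actually
  reaches zero at the data edge and suppresses the truncation ringing of
  sharpened signals. Peak picking should use it; the identity-property
  test does not.
* ppm axes are descending left to right; display order puts +SW/2 first.
  First-order phase is linear across the displayed spectrum.

## Benchmark protocol

`generate_benchmark_spectrum()` draws realistic correlation maps: 275
signals (HDAC8-like) or 600 (MSG-like); per-spectrum sweep widths uniform
in 2000-5000 Hz in both dimensions (the generator reads the 13C upper
bound as 5000 Hz, matching the MSG column of the published table, where
the printed value is an evident typo); 1H fields from {600, 700, 800,
950} MHz; half methyl signals placed from a shift-statistics table, half
non-methyl CH signals uniform over 2.5-5.5 ppm (1H) x 28-42 ppm (13C);
couplings from N(34, 2) Hz; per-kind normal relaxation-rate
distributions; log-uniform amplitudes over one decade; complex Gaussian
noise at a signal-to-noise of 50 (the published conditions state no noise
level; idealised targets are noise-free). Grid sizes are likewise
unstated in the source conditions; the package uses 256 x 128 complex
points. The shift-statistics table shipped in
`extdata/methyl_shift_stats_synthetic.tsv` contains literature-plausible
means and standard deviations *emulating* aggregate BMRB statistics — it
is a synthetic stand-in, not extracted database values.

Scoring follows the published protocol: truth peaks are *isolated* when
every other truth peak is at least 0.06 1H ppm away, with 13C differences
counted at 4 ppm per 1H ppm (the stated 0.24 13C ppm equivalence) and the
two combined by a Chebyshev maximum for auditability. Picked peaks more
than 1.50 1H ppm from every methyl truth are excluded from accounting,
and scoring is restricted to truths that are doublets in the original
spectrum (a triplet loses only one coupling and cannot become a singlet).
Matching is greedy one-to-one within 0.03 1H-ppm-equivalent; the source
text's "descending order of distance" is read as a slip for closest-first
(the default), with the literal order available via a flag and the order
used recorded in the result. A false positive is a retained pick that
corresponds to *no* truth peak — isolated or not — within the match
radius; the false-positive rate is expressed over retained picks, which
is scale-free across spectra. On instances of up to six peaks with
separations above twice the radius, the greedy matcher is tested to agree
with an exhaustive optimal assignment.

The peak picker is a deliberate re-implementation, not a reproduction of
any external tool: strict 8-neighbourhood local maxima above
`threshold_sigmas` (default 8) times a robust noise estimate — the MAD of
the lowest-|intensity| quartile of points, rescaled by the truncated
half-normal factor 1/(1.4826 qnorm(0.5625)) so that on a Gaussian
background it estimates the true sigma — with positions refined by
3-point parabolic interpolation per axis. The noise estimate is floored at 1e-3 of the
spectrum maximum: on noiseless synthetic spectra the MAD collapses and
every lineshape ripple would otherwise clear any sigma-based threshold,
which no practitioner's threshold would do.

## Training data sets on disk

A dataset directory holds a JSON manifest (counts, configuration, packing
descriptor), a per-signal metadata table (true shifts, couplings, rates,
per-pair noise seed — the full audit trail), and optionally raw float32
plane files. Planes are a deterministic function of the metadata plus the
stored noise seed, so the full-scale configuration (500,000 training and
50,000 test pairs) is written metadata-only and replayed identically at
load time; materialising those planes would cost ~16 GB for information
the metadata already determines. The loader refuses datasets (and the
weight loader refuses checkpoints) whose recorded packing differs from
the pipeline's.

## NOE volume-distance calibration

Cross-peak volumes are box integrals around the nearest grid point,
normalised by the corresponding diagonal-peak volume, and paired with
interproton distances supplied externally (structure parsing is out of
scope). Records are binned in 0.2 Angstrom intervals (bin mean = sum /
count) over the 3.0-5.0 Angstrom window in which methyl-methyl NOEs are
observed, and the power law $V = C\,r^{-b}$ is fitted by least squares on
$\log V$ versus $\log r$ over the individual records — log-space because
it linearises the model and is exactly reproducible. Whether the exponent
should float or be fixed at the theoretical value 6 is left open by the
source figure, so both are reported (`b` and the constrained `C_b6`). The
fit is scale-invariant in the volumes, and on noiseless records generated
with $b = 6$ the floating fit recovers the exponent exactly.

## Problem sizes exercised by the tests

The test-suite trains the reduced 13C network (2,000 pairs, up to 30
epochs) and the reduced 1H network (2,000 pairs, up to 25 epochs) once per
session and reuses them; it scores 10 reduced HDAC8-like spectra end to
end against their unenhanced counterparts; it generates the full 200-
spectrum benchmark suite and the full 550,000-pair metadata-only training
set; and it runs 1,000 random matching instances against the exhaustive
oracle. These sizes are the package's chosen desk-scale demonstration
conditions.

## What passing tests do and do not show

The synthetic generator emulates multiplet structure, exponential decay,
per-methyl-type shift statistics, quadrature detection, aliasing and
additive noise. It does not emulate 1H-1H couplings, cross-correlated
relaxation (the physical basis of the methyl-TROSY effect itself),
solvent artefacts, baseline distortions or non-uniform sampling. Passing
the desk-scale tests therefore demonstrates that the architecture learns
the intended inverse mapping under the stated signal model and that the
pipeline plumbing is exact — not that the reduced networks are adequate
for experimental data. Peak intensities after enhancement are not
quantitative; the networks reshape lines by design, so downstream
analyses should use positions and only coarse intensity estimates.
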