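# fidnetr

Methyl-TROSY NMR gives sharp 13C-1H correlation maps of very large
proteins, but classically demands perdeuterated, specifically methyl-
labelled samples. A uniformly 13C-labelled, *protonated* sample is cheaper
and reports on every methyl-bearing side chain — at the price of spectra
degraded by one-bond 13C-13C scalar couplings (doublets for methyl
carbons, triplets for non-methyl CH) and by heavy dipolar line broadening.
`fidnetr` implements, in R with a compiled C++ core, the deep-learning
route around this: two gated dilated convolutional networks (FID-Net-style
architectures) applied to time-domain vectors inside an otherwise
conventional Fourier pipeline — one network virtually decouples and
sharpens the 13C dimension, a second sharpens the 1H dimension.

The package is a complete toolchain for anyone who wants to study,
retrain, or benchmark this kind of spectral enhancement:

* **Simulation** — FIDs under the signal model
  `s(t) = sum_j a_j exp(i 2 pi f_j t) exp(-R2_j t) prod_c cos(pi J_c t)`;
  training pairs whose targets remove one coupling per signal and replace
  each rate by `R2_tar = max(R2max tanh(R2/R2max), R2max (1 - tanh(R2/R2max)))`
  with `R2max = 25 / s`; and realistic benchmark spectra (275- and
  600-signal classes) with known ground-truth peak lists.
* **Networks** — residual gated dilated convolutions (kernel 8 x 4,
  sigmoid/tanh gating, skip aggregation), trained by RMSprop on a
  frequency-domain mean-squared-error loss with a two-phase
  plateau-driven learning-rate schedule. Forward, backward and update
  steps are hand-written C++ validated against finite differences.
* **Processing** — 2D and 3D enhancement pipelines with nmrPipe-format
  input/output, Fourier/Hilbert machinery, and provenance logging; with
  identity stand-in networks the pipeline reduces exactly to plain
  Fourier processing.
* **Benchmarking** — a local-maximum peak picker, the isolated-peak /
  region / doublet filters, greedy one-to-one matching (0.03 1H-ppm
  radius, 4:1 carbon equivalence), and true/false-positive reports.
* **NOE calibration** — cross-peak volume integration and the
  `V = C / r^6` volume-distance fit in 0.2 Angstrom bins.

## Worked example

```r
library(fidnetr)

# the rate map pushes broad and sharp lines towards a uniform target width
target_r2(c(5, 25, 80), r2_max = 25)
#> [1] 20.06562 19.03985 24.91706

# one realistic HDAC8-like benchmark spectrum with ground truth
set.seed(42)
spec <- generate_benchmark_spectrum(benchmark_config("hdac_like"))
nrow(spec$truth)
#> [1] 275
head(spec$truth[, c("id", "h_ppm", "c_ppm", "amplitude", "multiplicity")], 3)
#>   id     h_ppm    c_ppm amplitude multiplicity
#> 1  1 1.8998043 16.24003  1.351976      doublet
#> 2  2 0.3567212 24.77450  1.125756      doublet
#> 3  3 0.2682780 30.61708  2.311780      doublet

# score the idealised (decoupled, sharpened) target and the conventional
# processing of the coupled, broad spectrum with the same protocol
proc <- proc_config(display_apodize = "cosine")
benchmark_spectrum(process_reference(spec$target, proc), spec$truth)
#> <benchmark_report> 98 isolated truths, 246 picks | TP 99.0%  FP 22.8%  FN 1.0%
benchmark_spectrum(process_reference(spec$coupled, proc), spec$truth)
#> <benchmark_report> 98 isolated truths, 260 picks | TP 87.8%  FP 26.5%  FN 12.2%

# NOE volume-distance records generated under V = C / r^6 are recovered
# exactly by the log-space fit
set.seed(1)
r <- runif(300, 3, 5)
diag_v <- runif(300, 50, 150)
fit <- bin_and_fit(noe_records(diag_v * 200 / r^6, diag_v, r))
c(C = fit$C, b = fit$b)
#>   C   b
#> 200   6
```

The report lines read: of the 98 ground-truth peaks isolated enough to
score reliably, the idealised target recovers 99% (the picker's ceiling
on these crowded spectra), while conventional processing of the coupled,
broad spectrum recovers 88% — the gap the enhancement networks close.
Training a reduced 13C network and running the enhanced-versus-unenhanced
comparison end to end is shown in the test-suite
(`tests/testthat/helper-nets.R`, `test-benchkit.R`).

A thin command-line wrapper is installed at `inst/scripts/fidnetr`
(subcommands `simulate`, `train`, `enhance2d`, `enhance3d`, `benchmark`,
`noe-fit`, `fixtures`); the same dispatcher is callable in-process as
`fidnet_main()`.

See `vignettes/methyl-decoupling.Rmd` for the model, the architecture,
the benchmark protocol, all numerical choices and the known limitations.

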