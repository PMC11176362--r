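#' Target transverse relaxation rate for training data
#'
#' Maps an input decay rate onto the rate used for the training target:
#' `max(r2_max * tanh(r2_in / r2_max), r2_max * (1 - tanh(r2_in / r2_max)))`.
#' Rates above `r2_max` are compressed down towards it and rates below are
#' pushed up towards it, so target linewidths are roughly uniform, similar to
#' the methyl-TROSY spectra of structured residues in deuterated proteins.
#' The result always lies in `[r2_max / 2, r2_max]`, with the minimum
#' attained exactly at `r2_in = r2_max * atanh(1/2)`.
#'
#' @param r2_in Input transverse relaxation rate(s), 1/s (>= 0).
#' @param r2_max Ceiling rate, 1/s (> 0); default 25/s.
#' @return Target rate(s) in 1/s.
#' @export
target_r2 <- function(r2_in, r2_max = 25) {
  if (any(!is.finite(r2_in)) || any(r2_in < 0)) stop("r2_in must be finite and >= 0")
  if (!is.finite(r2_max) || r2_max <= 0) stop("r2_max must be > 0")
  th <- tanh(r2_in / r2_max)
  pmax(r2_max * th, r2_max * (1 - th))
}

#' One resonance of a 13C-1H moiety
#'
#' Bundles the parameters of a single cross-peak: chemical shifts, amplitude,
#' per-dimension transverse relaxation rates, and the one-bond 13C-13C scalar
#' couplings that modulate the 13C dimension. A methyl carbon has exactly one
#' such coupling (doublet); a non-methyl CH carbon has two (triplet).
#'
#' @param shift_h,shift_c Chemical shifts in ppm.
#' @param amplitude Signal amplitude (> 0, arbitrary units).
#' @param r2_h,r2_c Transverse relaxation rates, 1/s (> 0).
#' @param couplings_c Numeric vector (length 0-2) of 13C-13C couplings in Hz.
#' @param is_methyl Logical; methyl signals must carry exactly 1 coupling and
#'   non-methyl CH signals exactly 2.
#' @param residue_type Optional label (e.g. `"Ile"`), or `NA`.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(shift_h, shift_c, amplitude, r2_h, r2_c,
                        couplings_c = numeric(), is_methyl = NA,
                        residue_type = NA_character_) {
  vals <- c(shift_h, shift_c, amplitude, r2_h, r2_c, couplings_c)
  if (any(!is.finite(vals))) stop("signal parameters must be finite")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (r2_h <= 0 || r2_c <= 0) stop("relaxation rates must be > 0")
  if (length(couplings_c) > 2) stop("at most 2 13C-13C couplings supported")
  if (length(couplings_c) && any(couplings_c <= 0)) stop("couplings must be > 0")
  if (isTRUE(is_methyl) && length(couplings_c) != 1) {
    stop("a methyl signal carries exactly 1 coupling (doublet)")
  }
  if (isFALSE(is_methyl) && length(couplings_c) != 2) {
    stop("a non-methyl CH signal carries exactly 2 couplings (triplet)")
  }
  structure(
    list(
      shift_h = shift_h, shift_c = shift_c, amplitude = amplitude,
      r2_h = r2_h, r2_c = r2_c, couplings_c = couplings_c,
      is_methyl = is_methyl, residue_type = residue_type
    ),
    class = "signal_spec"
  )
}

#' Synthesize a 1D complex free induction decay
#'
#' Evaluates the sum-of-resonances signal model on the sampling grid of
#' `axis`:
#' \deqn{s(t_k) = \sum_j a_j e^{i 2\pi f_j t_k} e^{-R_{2,j} t_k}
#'   \prod_c \cos(\pi J_c t_k), \quad t_k = k / \mathrm{SW}.}
#' Each scalar coupling contributes a cosine amplitude modulation, which in
#' the frequency domain splits a line into components at +/- J/2 (doublets,
#' and triplets when two couplings are present). With `decoupled = TRUE`
#' exactly one coupling factor per signal is omitted, so doublets render as
#' singlets and triplets as doublets -- the behaviour a trained decoupling
#' network is meant to reproduce.
#'
#' @param signals List of [signal_spec] objects.
#' @param axis [nmr_axis] for the dimension being sampled; its nucleus selects
#'   which shift/rate of each signal applies.
#' @param decoupled If `TRUE`, drop the first coupling of every signal.
#' @param r2_override Optional numeric vector (one per signal) of relaxation
#'   rates replacing each signal's own rate (used to build sharpened targets).
#' @return Complex vector of `axis$n_complex_points` samples.
#' @export
synthesize_fid <- function(signals, axis, decoupled = FALSE, r2_override = NULL) {
  n <- axis$n_complex_points
  if (length(signals) == 0) {
    warning("empty signal list; returning zero FID")
    return(complex(n))
  }
  if (!is.null(r2_override) && length(r2_override) != length(signals)) {
    stop("r2_override must have one rate per signal")
  }
  t <- (0:(n - 1)) / axis$sweep_width
  s <- complex(n)
  for (j in seq_along(signals)) {
    sg <- signals[[j]]
    if (axis$nucleus == "1H") {
      f <- ppm_to_hz(sg$shift_h, axis); r2 <- sg$r2_h; J <- numeric()
    } else {
      f <- ppm_to_hz(sg$shift_c, axis); r2 <- sg$r2_c; J <- sg$couplings_c
    }
    if (!is.null(r2_override)) r2 <- r2_override[j]
    if (decoupled && length(J) > 0) J <- J[-1]
    contrib <- sg$amplitude * exp((2i * pi * f - r2) * t)
    for (Jc in J) contrib <- contrib * cos(pi * Jc * t)
    s <- s + contrib
  }
  s
}

#' Methyl chemical-shift statistics table
#'
#' Loads a table of per-methyl-site 1H/13C chemical-shift means and standard
#' deviations used to place methyl signals in benchmark spectra. The shipped
#' fixture (`methyl_shift_stats_synthetic.tsv`) contains literature-plausible
#' values emulating aggregate BMRB statistics; it is a synthetic stand-in,
#' not extracted database values.
#'
#' @param path Path to a TSV with columns `residue_type`, `methyl_site`,
#'   `mean_shift_h`, `sd_shift_h`, `mean_shift_c`, `sd_shift_c`. Defaults to
#'   the shipped fixture.
#' @return A `data.frame` with one row per methyl site.
#' @export
load_shift_stats <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "methyl_shift_stats_synthetic.tsv",
                        package = "fidnetr")
  }
  stats <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("residue_type", "methyl_site", "mean_shift_h", "sd_shift_h",
                "mean_shift_c", "sd_shift_c")
  if (!all(required %in% names(stats))) {
    stop("shift stats table missing columns: ",
         paste(setdiff(required, names(stats)), collapse = ", "))
  }
  if (any(stats$sd_shift_h <= 0) || any(stats$sd_shift_c <= 0)) {
    stop("all shift standard deviations must be > 0")
  }
  must_have <- c("Ala.B", "Ile.D1", "Ile.G2", "Leu.D1", "Leu.D2",
                 "Val.G1", "Val.G2", "Thr.G2", "Met.E")
  key <- paste(stats$residue_type, stats$methyl_site, sep = ".")
  missing <- setdiff(must_have, key)
  if (length(missing)) {
    stop("shift stats table missing required methyl sites: ",
         paste(missing, collapse = ", "))
  }
  stats
}

#' Draw one-bond 13C-13C scalar couplings
#'
#' Samples coupling constants from the benchmark distribution, a normal with
#' mean 34 Hz and standard deviation 2 Hz.
#'
#' @param n Number of draws.
#' @param mean,sd Distribution parameters in Hz.
#' @return Numeric vector of couplings (Hz).
#' @export
draw_jcc <- function(n, mean = 34, sd = 2) {
  j <- stats::rnorm(n, mean, sd)
  while (any(j <= 0)) j[j <= 0] <- stats::rnorm(sum(j <= 0), mean, sd)
  j
}
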