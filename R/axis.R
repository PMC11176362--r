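#' Spectral axis metadata
#'
#' An `nmr_axis` describes one dimension of an NMR data set: the number of
#' complex sampling points, the sweep width (Hz), the Larmor (observe)
#' frequency (MHz), the carrier position (ppm) and the nucleus. Conversion
#' between ppm offsets and Hz is `hz = ppm * larmor_frequency` and is exactly
#' invertible.
#'
#' @param n_complex_points Number of complex sampling points (>= 8).
#' @param sweep_width Sweep width in Hz (> 0).
#' @param larmor_frequency Observe frequency in MHz for this nucleus.
#' @param carrier Carrier (transmitter) position in ppm.
#' @param nucleus `"1H"` or `"13C"`.
#' @param domain `"time"` or `"frequency"`.
#' @param quad `"complex"` (points stored interleaved Re,Im along the axis)
#'   or `"real"`.
#' @param larmor_set Optional numeric vector of permitted Larmor frequencies;
#'   when supplied, `larmor_frequency` must be a member (the benchmark
#'   generator restricts 1H fields to 600/700/800/950 MHz).
#' @return An object of class `nmr_axis`.
#' @export
nmr_axis <- function(n_complex_points, sweep_width, larmor_frequency, carrier,
                     nucleus = c("1H", "13C"), domain = c("time", "frequency"),
                     quad = c("complex", "real"), larmor_set = NULL) {
  nucleus <- match.arg(nucleus)
  domain <- match.arg(domain)
  quad <- match.arg(quad)
  if (!is.numeric(n_complex_points) || n_complex_points < 8) {
    stop("n_complex_points must be >= 8")
  }
  if (!is.numeric(sweep_width) || sweep_width <= 0) stop("sweep_width must be > 0")
  if (!is.numeric(larmor_frequency) || larmor_frequency <= 0) {
    stop("larmor_frequency must be > 0")
  }
  if (!is.null(larmor_set) && !(larmor_frequency %in% larmor_set)) {
    stop("larmor_frequency must be one of: ", paste(larmor_set, collapse = ", "))
  }
  structure(
    list(
      n_complex_points = as.integer(n_complex_points),
      sweep_width = sweep_width,
      larmor_frequency = larmor_frequency,
      carrier = carrier,
      nucleus = nucleus,
      domain = domain,
      quad = quad
    ),
    class = "nmr_axis"
  )
}

#' @export
print.nmr_axis <- function(x, ...) {
  cat(sprintf(
    "<nmr_axis> %s  %d cplx pts  SW %.1f Hz  obs %.2f MHz  car %.3f ppm  [%s/%s]\n",
    x$nucleus, x$n_complex_points, x$sweep_width, x$larmor_frequency,
    x$carrier, x$domain, x$quad
  ))
  invisible(x)
}

#' Convert a chemical-shift offset between ppm and Hz
#'
#' Offsets are relative to the carrier: `hz = (ppm - carrier) * larmor`.
#'
#' @param ppm,hz Values to convert.
#' @param axis An [nmr_axis].
#' @return Numeric vector of the converted values.
#' @export
ppm_to_hz <- function(ppm, axis) (ppm - axis$carrier) * axis$larmor_frequency

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, axis) axis$carrier + hz / axis$larmor_frequency

#' Number of stored points along an axis (real-valued storage length)
#' @param axis An [nmr_axis].
#' @return Integer: `2 * n_complex_points` for complex axes, else the point count.
#' @export
axis_storage_length <- function(axis) {
  if (axis$quad == "complex") 2L * axis$n_complex_points else axis$n_complex_points
}

# Frequency offsets (Hz, relative to carrier) of the bins of an n-point
# spectrum along `axis`, in the stored (descending-frequency, NMR display)
# order. Bin k of the raw DFT holds frequency k*SW/n folded into
# (-SW/2, SW/2]; display order is descending.
axis_bin_freqs <- function(axis, n) {
  k <- 0:(n - 1)
  f <- k * axis$sweep_width / n
  f <- ifelse(k >= n / 2, f - axis$sweep_width, f)
  sort(f, decreasing = TRUE)
}

# Permutation taking raw DFT bin order to descending-frequency display order,
# i.e. display[i] = raw[ft_display_order(n)[i]].
ft_display_order <- function(n) {
  k <- 0:(n - 1)
  f <- ifelse(k >= n / 2, k - n, k)
  order(f, decreasing = TRUE)
}

#' ppm scale of a frequency-domain axis
#'
#' @param axis An [nmr_axis] in the frequency domain.
#' @param n Number of points (defaults to the axis storage length).
#' @return Numeric vector of ppm values, descending left to right per NMR
#'   convention.
#' @export
axis_ppm_scale <- function(axis, n = NULL) {
  if (axis$domain != "frequency") stop("axis is not in the frequency domain")
  if (is.null(n)) n <- axis_storage_length(axis)
  hz_to_ppm(axis_bin_freqs(axis, n), axis)
}

# Alias a frequency offset (Hz) into the acquired window (-SW/2, SW/2].
alias_freq <- function(f, sw) {
  g <- f - sw * round(f / sw)
  ifelse(g <= -sw / 2, g + sw, g)
}
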