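#' N-dimensional NMR spectrum container
#'
#' A `spectrum_grid` holds a 1-3 dimensional real-valued array together with
#' one [nmr_axis] per dimension and an append-only provenance log. Complex
#' axes are stored interleaved (Re, Im, Re, Im, ...) along that dimension, so
#' a dimension with `n` complex points occupies `2n` storage points; this is
#' the layout used throughout the processing pipeline and mirrors the
#' interleaved quadrature layout of nmrPipe data.
#'
#' @param data Numeric array (a plain vector is treated as 1D).
#' @param axes List of [nmr_axis] objects, one per dimension of `data`.
#' @param provenance Character vector of processing-log entries.
#' @return An object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(data, axes, provenance = character()) {
  if (is.null(dim(data))) dim(data) <- length(data)
  if (!is.numeric(data)) stop("data must be a real-valued numeric array")
  if (length(axes) != length(dim(data))) {
    stop("need exactly one axis per data dimension")
  }
  for (i in seq_along(axes)) {
    if (!inherits(axes[[i]], "nmr_axis")) stop("axes must be nmr_axis objects")
    if (dim(data)[i] != axis_storage_length(axes[[i]])) {
      stop(sprintf(
        "axis %d storage length (%d) does not match data dim (%d)",
        i, axis_storage_length(axes[[i]]), dim(data)[i]
      ))
    }
  }
  structure(list(data = data, axes = axes, provenance = provenance),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> %s\n", paste(dim(x$data), collapse = " x ")))
  for (ax in x$axes) print(ax)
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat("  -", p, "\n")
  }
  invisible(x)
}

add_provenance <- function(grid, entry) {
  grid$provenance <- c(grid$provenance, entry)
  grid
}

# -- internal reshaping helpers ------------------------------------------------

# Apply fn to the storage matrix of axis i (rows = storage points along axis i,
# columns = all other points). fn may change the number of rows.
apply_along_axis <- function(data, i, fn) {
  d <- dim(data)
  nd <- length(d)
  perm <- c(i, setdiff(seq_len(nd), i))
  x <- aperm(data, perm)
  dim(x) <- c(d[i], prod(d[-i]))
  y <- fn(x)
  dim(y) <- c(nrow(y), d[perm[-1]])
  aperm(y, match(seq_len(nd), perm))
}

interleaved_to_complex <- function(v) {
  v[c(TRUE, FALSE), , drop = FALSE] + 1i * v[c(FALSE, TRUE), , drop = FALSE]
}

complex_to_interleaved <- function(z) {
  out <- matrix(0, 2L * nrow(z), ncol(z))
  out[c(TRUE, FALSE), ] <- Re(z)
  out[c(FALSE, TRUE), ] <- Im(z)
  out
}

resolve_zero_fill <- function(zero_fill, m) {
  if (identical(zero_fill, "none")) return(m)
  if (identical(zero_fill, "double")) return(2L * m)
  zf <- as.integer(zero_fill)
  if (is.na(zf) || zf < m) stop("zero_fill target must be >= current length")
  zf
}

# -- Fourier processing --------------------------------------------------------

#' Fourier transform one axis of a spectrum
#'
#' Applies the standard processing chain along one time-domain axis:
#' first-point scaling by 0.5 (DC-offset convention), optional cosine-bell
#' apodization, zero-filling, complex DFT, zero/first-order phase correction,
#' and reordering to the descending-frequency NMR display convention. With
#' `apodize = "none"`, `zero_fill = "none"` and zero phase, [ift_axis()]
#' inverts the transform to machine precision.
#'
#' @param grid A [spectrum_grid].
#' @param axis_index Which axis to transform (must be time-domain, complex).
#' @param apodize `"none"` or `"cosine"` (half cosine bell).
#' @param zero_fill `"none"`, `"double"`, or an integer number of complex
#'   points to fill to.
#' @param phase Numeric `(p0, p1)` in degrees; first-order phase is linear
#'   across the displayed spectrum.
#' @param keep `"complex"` retains the imaginary part (interleaved storage);
#'   `"real"` discards it after phasing.
#' @param apodize_support Number of points the cosine window spans (the
#'   acquired, signal-bearing region); points beyond it are zeroed. Defaults
#'   to the full axis length. Relevant when apodizing a vector that was
#'   already zero-filled (e.g. network outputs), where the window must reach
#'   zero at the edge of the signal support to suppress truncation ringing.
#' @return The transformed [spectrum_grid].
#' @export
ft_axis <- function(grid, axis_index, apodize = c("none", "cosine"),
                    zero_fill = "none", phase = c(0, 0),
                    keep = c("complex", "real"), apodize_support = NULL) {
  apodize <- match.arg(apodize)
  keep <- match.arg(keep)
  ax <- grid$axes[[axis_index]]
  if (ax$domain != "time") stop("ft_axis: axis is already in the frequency domain")
  if (ax$quad != "complex") stop("ft_axis: axis must be complex (quadrature) data")
  m <- ax$n_complex_points
  mm <- resolve_zero_fill(zero_fill, m)
  ord <- ft_display_order(mm)
  ph <- exp(1i * pi / 180 * (phase[1] + phase[2] * (0:(mm - 1)) / mm))
  s <- as.integer(apodize_support %||% m)
  window <- c(cos(pi / 2 * (0:(min(s, m) - 1)) / s), rep(0, max(0, m - s)))

  grid$data <- apply_along_axis(grid$data, axis_index, function(v) {
    z <- interleaved_to_complex(v)
    z[1, ] <- 0.5 * z[1, ]
    if (apodize == "cosine") z <- z * window
    if (mm > m) z <- rbind(z, matrix(0 + 0i, mm - m, ncol(z)))
    s <- stats::mvfft(z)
    s <- s[ord, , drop = FALSE] * ph
    if (keep == "real") Re(s) else complex_to_interleaved(s)
  })

  ax$domain <- "frequency"
  ax$quad <- if (keep == "real") "real" else "complex"
  ax$n_complex_points <- mm
  grid$axes[[axis_index]] <- ax
  attr(grid$axes[[axis_index]], "applied_phase") <- phase
  add_provenance(grid, sprintf(
    "ft_axis(axis=%d, apodize=%s, zero_fill=%s->%d, phase=[%g,%g], keep=%s)",
    axis_index, apodize, as.character(zero_fill)[1], mm, phase[1], phase[2], keep
  ))
}

#' Inverse Fourier transform one axis
#'
#' Exact inverse of [ft_axis()] for an unapodized transform: undoes the phase
#' recorded on the axis, restores raw DFT bin order, inverse-DFTs and undoes
#' the first-point scaling. The zero-filled length is retained.
#'
#' @param grid A [spectrum_grid].
#' @param axis_index Axis to invert (frequency-domain, complex).
#' @return The time-domain [spectrum_grid].
#' @export
ift_axis <- function(grid, axis_index) {
  ax <- grid$axes[[axis_index]]
  if (ax$domain != "frequency") stop("ift_axis: axis is not in the frequency domain")
  if (ax$quad != "complex") {
    stop("ift_axis: axis has no imaginary part; use hilbert_reconstruct() first")
  }
  m <- ax$n_complex_points
  ord <- ft_display_order(m)
  iord <- order(ord)
  phase <- attr(ax, "applied_phase")
  if (is.null(phase)) phase <- c(0, 0)
  ph <- exp(-1i * pi / 180 * (phase[1] + phase[2] * (0:(m - 1)) / m))

  grid$data <- apply_along_axis(grid$data, axis_index, function(v) {
    s <- interleaved_to_complex(v) * ph
    s <- s[iord, , drop = FALSE]
    z <- stats::mvfft(s, inverse = TRUE) / m
    z[1, ] <- 2 * z[1, ]
    complex_to_interleaved(z)
  })

  ax$domain <- "time"
  grid$axes[[axis_index]] <- ax
  attr(grid$axes[[axis_index]], "applied_phase") <- NULL
  add_provenance(grid, sprintf("ift_axis(axis=%d)", axis_index))
}

#' Reconstruct imaginary data by Hilbert transform
#'
#' Given a frequency-domain axis whose imaginary part was discarded,
#' reconstructs the dispersive component as the Hilbert transform of the
#' absorptive (real) part, via the discrete analytic-signal construction.
#' For data whose underlying time signal occupied at most half the transform
#' length (i.e. the dimension was zero-filled at least once before the real
#' part was taken), the reconstruction is exact; a subsequent [ift_axis()]
#' yields a causal time-domain signal.
#'
#' @param grid A [spectrum_grid].
#' @param axis_index Frequency-domain real axis to reconstruct.
#' @return A [spectrum_grid] with complex data along `axis_index`.
#' @export
hilbert_reconstruct <- function(grid, axis_index) {
  ax <- grid$axes[[axis_index]]
  if (ax$domain != "frequency") stop("hilbert_reconstruct: axis must be frequency domain")
  if (ax$quad == "complex") {
    warning("hilbert_reconstruct: axis already complex; no-op")
    return(grid)
  }
  m <- ax$n_complex_points
  if (m %% 2L != 0L) stop("hilbert_reconstruct: axis length must be even")
  ord <- ft_display_order(m)
  iord <- order(ord)
  w <- c(1, rep(2, m / 2 - 1), 1, rep(0, m / 2 - 1))

  grid$data <- apply_along_axis(grid$data, axis_index, function(v) {
    r <- v[iord, , drop = FALSE]                      # back to raw DFT order
    x <- stats::mvfft(r, inverse = TRUE) / m          # pseudo-time signal
    s <- stats::mvfft(x * w)                          # one-sided -> analytic
    complex_to_interleaved(s[ord, , drop = FALSE])
  })

  ax$quad <- "complex"
  grid$axes[[axis_index]] <- ax
  add_provenance(grid, sprintf("hilbert_reconstruct(axis=%d)", axis_index))
}

#' Extract a frequency sub-region along an axis
#'
#' Keeps the displayed points whose ppm values fall inside `[ppm_min,
#' ppm_max]`, re-deriving the axis sweep width and carrier so downstream
#' processing sees a consistent, narrower window. Used to band-select the
#' methyl region when an acquired dimension is longer than a network's input
#' length.
#'
#' @param grid A [spectrum_grid].
#' @param axis_index Frequency-domain axis to cut.
#' @param ppm_min,ppm_max Region bounds in ppm.
#' @param n_keep Optional forced number of points (trimmed/centred on the
#'   region); useful to match a network input length exactly.
#' @return The extracted [spectrum_grid].
#' @export
extract_region <- function(grid, axis_index, ppm_min, ppm_max, n_keep = NULL) {
  ax <- grid$axes[[axis_index]]
  if (ax$domain != "frequency" || ax$quad != "real") {
    stop("extract_region expects a real frequency-domain axis")
  }
  ppm <- axis_ppm_scale(ax)
  idx <- which(ppm >= ppm_min & ppm <= ppm_max)
  if (length(idx) < 2) stop("extraction region contains fewer than 2 points")
  if (!is.null(n_keep)) {
    if (length(idx) < n_keep) stop("region smaller than n_keep")
    start <- idx[1] + (length(idx) - n_keep) %/% 2
    idx <- start:(start + n_keep - 1)
  }
  step <- ppm[1] - ppm[2]
  grid$data <- apply_along_axis(grid$data, axis_index,
                                function(v) v[idx, , drop = FALSE])
  kept <- ppm[idx]
  ax$n_complex_points <- length(idx)
  ax$sweep_width <- length(idx) * step * ax$larmor_frequency
  # place the carrier so the kept bins reproduce their original ppm values
  f <- axis_bin_freqs(ax, length(idx))
  ax$carrier <- kept[1] - f[1] / ax$larmor_frequency
  grid$axes[[axis_index]] <- ax
  add_provenance(grid, sprintf(
    "extract_region(axis=%d, %.3f..%.3f ppm, n=%d)",
    axis_index, ppm_min, ppm_max, length(idx)
  ))
}
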