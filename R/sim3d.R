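#' Synthesize a 3D time-domain spectrum
#'
#' Builds a 3D HSQC-NOESY-HSQC-like time-domain grid (1H acquisition axis
#' first, two indirect 13C axes) as a sum of separable signals: each signal
#' contributes a complex 1H FID times real cosine/sine States quadrature
#' modulators along each 13C axis, with exponential decay and optional
#' one-bond 13C-13C cosine coupling factors on the 13C evolutions.
#'
#' @param signals `data.frame` with columns `h_ppm`, `c1_ppm`, `c2_ppm`,
#'   `amplitude`, `r2_h`, `r2_c1`, `r2_c2` and optional `j_c1`, `j_c2`
#'   (coupling in Hz, `NA` = none).
#' @param axis_h,axis_c1,axis_c2 Time-domain complex [nmr_axis] objects
#'   (axis order: acquisition, HSQC 13C, NOESY 13C).
#' @param decoupled Drop all couplings (idealised target).
#' @return A time-domain 3D [spectrum_grid].
#' @export
synthesize_3d <- function(signals, axis_h, axis_c1, axis_c2,
                          decoupled = FALSE) {
  axes <- list(axis_h, axis_c1, axis_c2)
  dims <- vapply(axes, axis_storage_length, integer(1))
  data <- array(0, dims)
  t_h <- (0:(axis_h$n_complex_points - 1)) / axis_h$sweep_width

  evol <- function(axis, ppm, r2, j) {
    t <- (0:(axis$n_complex_points - 1)) / axis$sweep_width
    z <- exp((2i * pi * ppm_to_hz(ppm, axis) - r2) * t)
    if (!decoupled && !is.na(j)) z <- z * cos(pi * j * t)
    as.vector(rbind(Re(z), Im(z)))   # interleaved cos/sin modulators
  }

  for (k in seq_len(nrow(signals))) {
    s <- signals[k, ]
    h <- s$amplitude * exp((2i * pi * ppm_to_hz(s$h_ppm, axis_h) - s$r2_h) * t_h)
    vh <- as.vector(rbind(Re(h), Im(h)))
    v1 <- evol(axis_c1, s$c1_ppm, s$r2_c1,
               if ("j_c1" %in% names(signals)) s$j_c1 else NA)
    v2 <- evol(axis_c2, s$c2_ppm, s$r2_c2,
               if ("j_c2" %in% names(signals)) s$j_c2 else NA)
    data <- data + outer(outer(vh, v1), v2)
  }
  spectrum_grid(data, axes, provenance = sprintf(
    "synthesize_3d(%d signals, decoupled=%s)", nrow(signals), decoupled))
}
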