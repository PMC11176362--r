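#' Processing options for the enhancement pipeline
#'
#' @param h1_phase,c13_phase Zero/first-order phase corrections (degrees)
#'   applied with the corresponding Fourier transforms.
#' @param h1_zero_fill Zero-fill policy for the 1H dimension (default
#'   `"double"`; one level of zero-filling makes the later Hilbert
#'   reconstruction of the discarded imaginaries exact).
#' @param apodize Apodization before the transforms feeding the networks;
#'   the networks are trained on unapodized decays, so the default is
#'   `"none"`.
#' @param display_apodize Cosine-bell apodization in the final display
#'   transforms only (after the networks), spanning the signal support;
#'   `"none"` (default, in which case the identity-network pipeline matches
#'   plain Fourier processing exactly) or `"cosine"` (recommended before
#'   peak picking, to suppress truncation ringing of sharpened signals).
#' @param h1_extract Optional `c(ppm_min, ppm_max)` band-selection of the
#'   1H dimension after its first transform (used when the acquired
#'   dimension is longer than the 1H network input).
#' @param batch_size Network inference batch size.
#' @return A list of class `proc_config`.
#' @export
proc_config <- function(h1_phase = c(0, 0), c13_phase = c(0, 0),
                        h1_zero_fill = "double", apodize = "none",
                        display_apodize = "none", h1_extract = NULL,
                        batch_size = 64) {
  structure(list(h1_phase = h1_phase, c13_phase = c13_phase,
                 h1_zero_fill = h1_zero_fill, apodize = apodize,
                 display_apodize = display_apodize, h1_extract = h1_extract,
                 batch_size = batch_size),
            class = "proc_config")
}

# pass every complex vector along one time-domain axis through a network,
# zero-filling to the network input length
net_transform_axis <- function(grid, axis_index, net, batch_size = 64) {
  ax <- grid$axes[[axis_index]]
  if (ax$domain != "time" || ax$quad != "complex") {
    stop("network transforms apply to complex time-domain axes")
  }
  m <- ax$n_complex_points
  L <- if (inherits(net, "fidnet")) net$cfg$input_length else m
  if (m > L) {
    stop(sprintf(
      "axis %d has %d complex points but the network accepts %d; band-extract the dimension first",
      axis_index, m, L
    ))
  }
  grid$data <- apply_along_axis(grid$data, axis_index, function(v) {
    Z <- interleaved_to_complex(v)
    K <- ncol(Z)
    planes <- array(0, c(4, L, K))
    Zs <- rbind(Z[-1, , drop = FALSE], 0)
    planes[1, seq_len(m), ] <- Re(Z)
    planes[2, seq_len(m), ] <- Im(Z)
    planes[3, seq_len(m), ] <- Re(Zs)
    planes[4, seq_len(m), ] <- Im(Zs)
    out <- apply_network(net, planes, batch_size)
    complex_to_interleaved(matrix(out[1, , ] + 1i * out[2, , ], nrow = L))
  })
  ax$n_complex_points <- L
  grid$axes[[axis_index]] <- ax
  label <- if (inherits(net, "fidnet_identity")) "identity" else
    sprintf("%s/%s", net$cfg$network, net$cfg$scale)
  add_provenance(grid, sprintf("apply_network(axis=%d, net=%s, L=%d)",
                               axis_index, label, L))
}

#' Enhance a 2D correlation spectrum with the two-network pipeline
#'
#' Executes the full workflow for a time-domain 2D plane (direct 1H axis
#' first, indirect 13C second): process and Fourier transform the 1H
#' dimension, discarding imaginaries after phasing (optionally band-select
#' the methyl region); pass the 13C interferograms through the decoupling /
#' sharpening network; process and Fourier transform the 13C dimension;
#' inverse Fourier transform the 1H dimension via Hilbert reconstruction;
#' pass the resulting 1H FIDs through the sharpening network; reprocess and
#' Fourier transform the 1H dimension. The provenance log lists every step
#' in order. With [identity_network()] stand-ins the pipeline reduces
#' exactly to conventional Fourier processing.
#'
#' @param grid Time-domain 2D [spectrum_grid], complex in both dimensions,
#'   axis 1 = 1H (acquisition), axis 2 = 13C.
#' @param c13_net,h1_net Trained networks (or [identity_network()]).
#' @param proc A [proc_config()].
#' @return Real 2D frequency-domain [spectrum_grid].
#' @export
enhance_2d <- function(grid, c13_net, h1_net, proc = proc_config()) {
  if (length(grid$axes) != 2) stop("enhance_2d expects 2D data")
  if (grid$axes[[1]]$nucleus != "1H" || grid$axes[[2]]$nucleus != "13C") {
    stop("axis 1 must be 1H (acquisition) and axis 2 13C (indirect)")
  }
  c13_support <- grid$axes[[2]]$n_complex_points
  g <- ft_axis(grid, 1, apodize = proc$apodize, zero_fill = proc$h1_zero_fill,
               phase = proc$h1_phase, keep = "real")
  if (!is.null(proc$h1_extract)) {
    n_keep <- if (inherits(h1_net, "fidnet")) h1_net$cfg$input_length else NULL
    g <- extract_region(g, 1, proc$h1_extract[1], proc$h1_extract[2],
                        n_keep = n_keep)
  }
  g <- net_transform_axis(g, 2, c13_net, proc$batch_size)
  g <- ft_axis(g, 2, apodize = proc$display_apodize, zero_fill = "none",
               phase = proc$c13_phase, keep = "real",
               apodize_support = c13_support)
  g <- hilbert_reconstruct(g, 1)
  g <- ift_axis(g, 1)
  h1_support <- g$axes[[1]]$n_complex_points %/% 2L
  g <- net_transform_axis(g, 1, h1_net, proc$batch_size)
  g <- ft_axis(g, 1, apodize = proc$display_apodize, zero_fill = "none",
               phase = proc$h1_phase, keep = "real",
               apodize_support = h1_support)
  g
}

#' Reference Fourier processing (no networks)
#'
#' Conventional discrete-Fourier processing of the same data: transform the
#' 1H dimension (same zero-fill/phase policy as the pipeline), discard
#' imaginaries, then transform each indirect dimension with zero-filling to
#' `indirect_lengths`. This is the comparison path for the pipeline's
#' identity-network property and for scoring unenhanced spectra (with
#' `display_apodize = "cosine"` the apodization matches what the pipeline
#' applies in its display transforms).
#'
#' @param grid Time-domain [spectrum_grid] (2D or 3D, 1H axis first).
#' @param proc A [proc_config()].
#' @param indirect_lengths Integer vector of final complex lengths for the
#'   indirect axes (defaults to their acquired lengths).
#' @return Real frequency-domain [spectrum_grid].
#' @export
process_reference <- function(grid, proc = proc_config(),
                              indirect_lengths = NULL) {
  nd <- length(grid$axes)
  apod_h <- if (identical(proc$display_apodize, "cosine")) "cosine" else proc$apodize
  g <- ft_axis(grid, 1, apodize = apod_h, zero_fill = proc$h1_zero_fill,
               phase = proc$h1_phase, keep = "real")
  if (!is.null(proc$h1_extract)) {
    g <- extract_region(g, 1, proc$h1_extract[1], proc$h1_extract[2])
  }
  for (i in seq_len(nd)[-1]) {
    support <- g$axes[[i]]$n_complex_points
    zf <- if (is.null(indirect_lengths)) "none" else indirect_lengths[i - 1]
    g <- ft_axis(g, i, apodize = proc$display_apodize, zero_fill = zf,
                 phase = proc$c13_phase, keep = "real",
                 apodize_support = support)
  }
  g
}

#' Enhance a 3D NOESY-type spectrum
#'
#' Plane-wise extension of [enhance_2d()] to a 3D experiment with one 1H
#' acquisition axis (axis 1) and two indirect 13C axes: the decoupling
#' network is applied along each 13C axis in turn (each followed by its
#' Fourier transform), and the 1H axis is sharpened via the Hilbert route.
#' By default the NOESY 13C axis (axis 3) is decoupled first, then the HSQC
#' 13C axis (axis 2); pass a single axis in `c13_axes` to decouple only one.
#'
#' @param grid Time-domain 3D [spectrum_grid].
#' @param c13_net,h1_net Networks (or identity stand-ins).
#' @param proc A [proc_config()].
#' @param c13_axes Order in which the 13C axes are decoupled.
#' @return Real 3D frequency-domain [spectrum_grid].
#' @export
enhance_3d <- function(grid, c13_net, h1_net, proc = proc_config(),
                       c13_axes = c(3, 2)) {
  if (length(grid$axes) != 3) stop("enhance_3d expects 3D data")
  if (grid$axes[[1]]$nucleus != "1H") stop("axis 1 must be the 1H acquisition axis")
  for (i in c13_axes) {
    if (grid$axes[[i]]$nucleus != "13C") stop("c13_axes must index 13C axes")
  }
  g <- ft_axis(grid, 1, apodize = proc$apodize, zero_fill = proc$h1_zero_fill,
               phase = proc$h1_phase, keep = "real")
  if (!is.null(proc$h1_extract)) {
    n_keep <- if (inherits(h1_net, "fidnet")) h1_net$cfg$input_length else NULL
    g <- extract_region(g, 1, proc$h1_extract[1], proc$h1_extract[2],
                        n_keep = n_keep)
  }
  for (i in c13_axes) {
    support <- g$axes[[i]]$n_complex_points
    g <- net_transform_axis(g, i, c13_net, proc$batch_size)
    g <- ft_axis(g, i, apodize = proc$display_apodize, zero_fill = "none",
                 phase = proc$c13_phase, keep = "real",
                 apodize_support = support)
  }
  remaining <- setdiff(2:3, c13_axes)
  for (i in remaining) {
    support <- g$axes[[i]]$n_complex_points
    g <- ft_axis(g, i, apodize = proc$display_apodize, zero_fill = "none",
                 phase = proc$c13_phase, keep = "real",
                 apodize_support = support)
  }
  g <- hilbert_reconstruct(g, 1)
  g <- ift_axis(g, 1)
  h1_support <- g$axes[[1]]$n_complex_points %/% 2L
  g <- net_transform_axis(g, 1, h1_net, proc$batch_size)
  g <- ft_axis(g, 1, apodize = proc$display_apodize, zero_fill = "none",
               phase = proc$h1_phase, keep = "real",
               apodize_support = h1_support)
  g
}
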