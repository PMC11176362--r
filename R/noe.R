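#' NOE cross-peak records
#'
#' Builds the table of normalised NOE cross-peak volumes: each record is a
#' cross-peak volume divided by the corresponding diagonal-peak volume,
#' paired with the interproton distance of the methyl pair.
#'
#' @param cross_volume,diagonal_volume Positive volumes (arbitrary, common
#'   units).
#' @param distance Interproton distances in Angstrom.
#' @param distance_window Admissible distance window (default 3.0-5.0 A, the
#'   range over which methyl-methyl NOEs are observed).
#' @return `data.frame` with class `noe_records` and a `normalised_volume`
#'   column.
#' @export
noe_records <- function(cross_volume, diagonal_volume, distance,
                        distance_window = c(3.0, 5.0)) {
  if (any(cross_volume <= 0) || any(diagonal_volume <= 0)) {
    stop("volumes must be > 0")
  }
  if (any(distance < distance_window[1] | distance > distance_window[2])) {
    stop(sprintf("distances must lie in [%.1f, %.1f] Angstrom",
                 distance_window[1], distance_window[2]))
  }
  structure(
    data.frame(cross_volume = cross_volume,
               diagonal_volume = diagonal_volume,
               normalised_volume = cross_volume / diagonal_volume,
               distance = distance),
    class = c("noe_records", "data.frame")
  )
}

#' Integrate a peak volume over a box
#'
#' Sums intensities over a `box[1]` x `box[2]` bin window centred on the
#' grid point nearest to `center`. Boxes exceeding the grid are clipped
#' with a warning.
#'
#' @param grid Real frequency-domain 2D [spectrum_grid].
#' @param center `c(h_ppm, c_ppm)` of the peak.
#' @param box Odd integer box edge lengths in bins (1H, 13C).
#' @return Scalar volume (intensity sum).
#' @export
integrate_volume <- function(grid, center, box = c(7, 7)) {
  if (length(grid$axes) != 2) stop("integrate_volume expects 2D data")
  ppm1 <- axis_ppm_scale(grid$axes[[1]])
  ppm2 <- axis_ppm_scale(grid$axes[[2]])
  i <- which.min(abs(ppm1 - center[1]))
  j <- which.min(abs(ppm2 - center[2]))
  h1 <- (box[1] - 1) %/% 2
  h2 <- (box[2] - 1) %/% 2
  i0 <- i - h1; i1 <- i + h1
  j0 <- j - h2; j1 <- j + h2
  if (i0 < 1 || i1 > length(ppm1) || j0 < 1 || j1 > length(ppm2)) {
    warning("integration box clipped at the grid edge")
    i0 <- max(1, i0); i1 <- min(length(ppm1), i1)
    j0 <- max(1, j0); j1 <- min(length(ppm2), j1)
  }
  sum(grid$data[i0:i1, j0:j1])
}

#' Bin normalised NOE volumes by distance and fit the power law
#'
#' Averages normalised volumes within `bin_width` distance intervals (mean
#' = sum of volumes / number of cross-peaks per interval), then fits
#' `V = C * r^(-b)` by least squares on `log V` versus `log r` over the
#' individual records. Both the floating-exponent fit and the fit with the
#' exponent constrained to the theoretical value 6 are reported.
#'
#' @param records A [noe_records()] table (>= 5 records spanning >= 3 bins).
#' @param bin_width Distance bin width in Angstrom (default 0.2).
#' @return List with `binned` (data.frame: bin mid, mean volume, count),
#'   `C`, `b` (floating fit), and `C_b6` (constrained b = 6).
#' @export
bin_and_fit <- function(records, bin_width = 0.2) {
  if (nrow(records) < 5) stop("need at least 5 records")
  if (stats::sd(records$distance) == 0) {
    stop("degenerate distance spread; cannot fit a power law")
  }
  lo <- floor(min(records$distance) / bin_width) * bin_width
  breaks <- seq(lo, max(records$distance) + bin_width, by = bin_width)
  bin <- cut(records$distance, breaks, right = FALSE, include.lowest = TRUE)
  counts <- tapply(records$normalised_volume, bin, length)
  means <- tapply(records$normalised_volume, bin, mean)
  keep <- !is.na(counts) & counts > 0
  binned <- data.frame(
    r_mid = (breaks[-length(breaks)] + bin_width / 2)[keep],
    mean_volume = as.numeric(means[keep]),
    count = as.integer(counts[keep])
  )
  if (nrow(binned) < 3) stop("records must span at least 3 distance bins")
  fit <- stats::lm(log(normalised_volume) ~ log(distance), data = records)
  b <- -unname(stats::coef(fit)[2])
  C <- exp(unname(stats::coef(fit)[1]))
  C_b6 <- exp(mean(log(records$normalised_volume) + 6 * log(records$distance)))
  list(binned = binned, C = C, b = b, C_b6 = C_b6)
}

#' Read or write NOE record tables
#'
#' TSV with columns `cross_volume`, `diagonal_volume`, `distance`.
#'
#' @param path File path.
#' @param records A [noe_records()] table.
#' @return `read_noe_records` returns a [noe_records()] table.
#' @export
read_noe_records <- function(path) {
  d <- utils::read.delim(path)
  noe_records(d$cross_volume, d$diagonal_volume, d$distance)
}

#' @rdname read_noe_records
#' @export
write_noe_records <- function(records, path) {
  utils::write.table(
    records[, c("cross_volume", "diagonal_volume", "distance")],
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
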