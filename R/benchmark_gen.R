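#' Benchmark spectrum class configuration
#'
#' Study conditions for the two classes of realistic synthetic 13C-1H
#' correlation maps: `"hdac_like"` spectra carry 275 signals with
#' per-dimension relaxation rates drawn from N(50, 10) / N(50, 10) 1/s, and
#' `"msg_like"` spectra carry 600 signals with rates from N(60, 15) (1H) and
#' N(60, 10) (13C). For every spectrum the sweep widths are drawn uniformly
#' from 2000-5000 Hz in both dimensions and the 1H field uniformly from
#' {600, 700, 800, 950} MHz. Half of the signals are methyl moieties
#' (doublets, shifts drawn from the methyl shift-statistics table); the
#' other half are non-methyl CH moieties (triplets, shifts uniform over a
#' configured region at higher 1H frequencies). One-bond couplings are drawn
#' from N(34, 2) Hz.
#'
#' @param kind `"hdac_like"` or `"msg_like"`.
#' @param ... Named overrides (e.g. fixed `sw_range_h`, smaller `n_h`, for
#'   reduced desk-scale runs).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(kind = c("hdac_like", "msg_like"), ...) {
  kind <- match.arg(kind)
  cfg <- list(
    kind = kind,
    n_signals = if (kind == "hdac_like") 275L else 600L,
    r2_h = if (kind == "hdac_like") c(50, 10) else c(60, 15),   # mean, sd
    r2_c = if (kind == "hdac_like") c(50, 10) else c(60, 10),
    sw_range_h = c(2000, 5000),
    sw_range_c = c(2000, 5000),
    larmor_set = c(600, 700, 800, 950),
    gamma_ratio_c = 0.25144,      # 13C/1H gyromagnetic ratio
    carrier_h = 2.0, carrier_c = 25,
    nonmethyl_h = c(2.5, 5.5), nonmethyl_c = c(28, 42),
    jcc_mean = 34, jcc_sd = 2,
    amp_range = c(1, 10),
    snr = 50,                      # mean amplitude / time-domain noise sigma
    n_h = 256L, n_c = 128L,        # complex points
    r2_max = 25
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "benchmark_config"
  cfg
}

#' Generate one benchmark spectrum with known ground truth
#'
#' Draws the per-spectrum acquisition parameters and per-signal parameters
#' under `cfg`, then synthesizes (i) the coupled, broad time-domain spectrum
#' a uniformly 13C-labelled protonated sample would give, with additive
#' complex Gaussian noise, and (ii) an idealised noise-free target in which
#' all 13C-13C couplings are removed and the relaxation rates are replaced
#' by [target_r2()]. The truth peak list holds the coupling-free positions;
#' shifts that fall outside the acquired window are recorded at their
#' aliased (observed) position, with the nominal shift kept alongside.
#'
#' @param cfg A [benchmark_config()].
#' @param stats Methyl shift-statistics table from [load_shift_stats()].
#' @return List with elements `coupled` ([spectrum_grid], time domain),
#'   `target` ([spectrum_grid]), and `truth` (data.frame peak list with
#'   columns `id`, `h_ppm`, `c_ppm`, `amplitude`, `multiplicity`,
#'   `is_methyl`, `h_ppm_nominal`, `c_ppm_nominal`).
#' @export
generate_benchmark_spectrum <- function(cfg = benchmark_config(), stats = load_shift_stats()) {
  n <- cfg$n_signals
  n_met <- n %/% 2L
  n_non <- n - n_met

  obs_h <- sample(cfg$larmor_set, 1)
  obs_c <- obs_h * cfg$gamma_ratio_c
  sw_h <- stats::runif(1, cfg$sw_range_h[1], cfg$sw_range_h[2])
  sw_c <- stats::runif(1, cfg$sw_range_c[1], cfg$sw_range_c[2])

  site <- sample(nrow(stats), n_met, replace = TRUE)
  met_h <- stats::rnorm(n_met, stats$mean_shift_h[site], stats$sd_shift_h[site])
  met_c <- stats::rnorm(n_met, stats$mean_shift_c[site], stats$sd_shift_c[site])
  non_h <- stats::runif(n_non, cfg$nonmethyl_h[1], cfg$nonmethyl_h[2])
  non_c <- stats::runif(n_non, cfg$nonmethyl_c[1], cfg$nonmethyl_c[2])

  sig <- data.frame(
    id = seq_len(n),
    h_ppm_nominal = c(met_h, non_h),
    c_ppm_nominal = c(met_c, non_c),
    is_methyl = rep(c(TRUE, FALSE), c(n_met, n_non)),
    amplitude = 10^stats::runif(n, log10(cfg$amp_range[1]), log10(cfg$amp_range[2])),
    r2_h = pmax(1, stats::rnorm(n, cfg$r2_h[1], cfg$r2_h[2])),
    r2_c = pmax(1, stats::rnorm(n, cfg$r2_c[1], cfg$r2_c[2])),
    j1 = draw_jcc(n, cfg$jcc_mean, cfg$jcc_sd),
    j2 = NA_real_
  )
  sig$j2[!sig$is_methyl] <- draw_jcc(n_non, cfg$jcc_mean, cfg$jcc_sd)

  axis_h <- nmr_axis(cfg$n_h, sw_h, obs_h, cfg$carrier_h, "1H",
                     larmor_set = cfg$larmor_set)
  axis_c <- nmr_axis(cfg$n_c, sw_c, obs_c, cfg$carrier_c, "13C")

  f_h <- ppm_to_hz(sig$h_ppm_nominal, axis_h)
  f_c <- ppm_to_hz(sig$c_ppm_nominal, axis_c)

  t_h <- (0:(cfg$n_h - 1)) / sw_h
  t_c <- (0:(cfg$n_c - 1)) / sw_c

  build_grid <- function(r2_h, r2_c, couple, noise_sigma) {
    # separable model: data(t2, t1) = sum_j a_j h_j(t2) c_j(t1); the States
    # quadrature components along t1 are Re and Im of the complex evolution
    H <- exp(t_h %o% (2i * pi * f_h - r2_h))        # n_h x n
    H <- sweep(H, 2, sig$amplitude, "*")
    C <- exp(t_c %o% (2i * pi * f_c - r2_c))        # n_c x n
    if (couple) {
      C <- C * cos(pi * t_c %o% sig$j1)
      has2 <- !is.na(sig$j2)
      C[, has2] <- C[, has2] * cos(pi * t_c %o% sig$j2[has2])
    }
    plane_cos <- H %*% t(Re(C))                      # n_h (complex) x n_c
    plane_sin <- H %*% t(Im(C))
    data <- array(0, c(2L * cfg$n_h, 2L * cfg$n_c))
    re_h <- c(TRUE, FALSE)
    data[re_h, c(TRUE, FALSE)] <- Re(plane_cos)
    data[!re_h, c(TRUE, FALSE)] <- Im(plane_cos)
    data[re_h, c(FALSE, TRUE)] <- Re(plane_sin)
    data[!re_h, c(FALSE, TRUE)] <- Im(plane_sin)
    if (noise_sigma > 0) {
      data <- data + stats::rnorm(length(data), 0, noise_sigma)
    }
    spectrum_grid(data, list(axis_h, axis_c),
                  provenance = sprintf("generate_benchmark_spectrum(kind=%s)", cfg$kind))
  }

  noise_sigma <- mean(sig$amplitude) / cfg$snr
  coupled <- build_grid(sig$r2_h, sig$r2_c, couple = TRUE, noise_sigma = noise_sigma)
  target <- build_grid(target_r2(sig$r2_h, cfg$r2_max),
                       target_r2(sig$r2_c, cfg$r2_max),
                       couple = FALSE, noise_sigma = 0)

  truth <- data.frame(
    id = sig$id,
    h_ppm = hz_to_ppm(alias_freq(f_h, sw_h), axis_h),
    c_ppm = hz_to_ppm(alias_freq(f_c, sw_c), axis_c),
    amplitude = sig$amplitude,
    multiplicity = ifelse(sig$is_methyl, "doublet", "triplet"),
    is_methyl = sig$is_methyl,
    h_ppm_nominal = sig$h_ppm_nominal,
    c_ppm_nominal = sig$c_ppm_nominal
  )
  list(coupled = coupled, target = target, truth = truth)
}

#' Generate a suite of benchmark spectra
#'
#' Writes `n_per_kind` spectra of each kind (default 100 each, 200 total) as
#' nmrPipe time-domain files plus TSV truth peak lists and a JSON manifest
#' with per-file MD5 checksums. Re-running with the same seed reproduces the
#' suite exactly.
#'
#' @param n_per_kind Spectra per kind (>= 1); default 100.
#' @param seed Integer seed.
#' @param out_dir Output directory; must be absent or empty unless
#'   `overwrite = TRUE`.
#' @param kinds Character vector of kinds to generate.
#' @param overwrite Allow writing into a non-empty directory.
#' @param ... Passed to [benchmark_config()] (reduced-scale overrides).
#' @return Invisibly, the manifest list.
#' @export
generate_benchmark_suite <- function(n_per_kind = 100, seed = 1, out_dir,
                                     kinds = c("hdac_like", "msg_like"),
                                     overwrite = FALSE, ...) {
  if (n_per_kind < 1) stop("n_per_kind must be >= 1")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("out_dir exists and is not empty; pass overwrite = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  stats <- load_shift_stats()
  entries <- list()
  for (kind in kinds) {
    cfg <- benchmark_config(kind, ...)
    for (i in seq_len(n_per_kind)) {
      stem <- sprintf("%s_%03d", kind, i)
      spec <- generate_benchmark_spectrum(cfg, stats)
      fid_file <- file.path(out_dir, paste0(stem, ".fid"))
      truth_file <- file.path(out_dir, paste0(stem, "_truth.tsv"))
      write_nmrpipe(spec$coupled, fid_file)
      utils::write.table(spec$truth, truth_file, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      entries[[stem]] <- list(
        kind = kind, fid = basename(fid_file), truth = basename(truth_file),
        n_signals = cfg$n_signals,
        md5_fid = unname(tools::md5sum(fid_file)),
        md5_truth = unname(tools::md5sum(truth_file))
      )
    }
  }
  manifest <- list(
    format = "fidnetr-benchmark-suite/1",
    seed = seed, n_per_kind = n_per_kind, kinds = kinds,
    n_spectra = length(entries), spectra = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
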