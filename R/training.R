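#' Pack a complex vector into the 4-row network plane
#'
#' The networks consume real-valued planes of shape 4 x L. The packing used
#' throughout this package (training, inference, and dataset headers) is:
#' row 1 = Re(z), row 2 = Im(z), row 3 = Re(z advanced by one sample),
#' row 4 = Im(z advanced by one sample), where the advanced copy is
#' `c(z[-1], 0)`. Vectors shorter than `L` are zero-filled; longer vectors
#' are rejected.
#'
#' @param z Complex vector of length <= L.
#' @param L Number of columns of the plane.
#' @return A 4 x L numeric matrix.
#' @export
pack_plane <- function(z, L = length(z)) {
  if (length(z) > L) stop("vector longer than plane length; truncate or extract first")
  if (length(z) < L) z <- c(z, complex(L - length(z)))
  zs <- c(z[-1], 0 + 0i)
  rbind(Re(z), Im(z), Re(zs), Im(zs))
}

#' @rdname pack_plane
#' @param plane A 4 x L plane as produced by `pack_plane()`.
#' @export
unpack_plane <- function(plane) {
  if (nrow(plane) != 4) stop("plane must have 4 rows")
  plane[1, ] + 1i * plane[2, ]
}

# canonical description written into dataset manifests and weight sidecars;
# loaders refuse data whose packing string differs.
packing_descriptor <- function() {
  "rows=[Re(z),Im(z),Re(shift1(z)),Im(shift1(z))]; shift1=advance-one-sample-zero-pad; scale=max|input plane|"
}

# fast vectorised synthesis used by the generators: one FID from per-signal
# frequency offsets (Hz), amplitudes, rates and up to two couplings (NA = none)
synth_fid_hz <- function(offset_hz, amplitude, r2, j1 = NULL, j2 = NULL,
                         sw, n, drop_first_coupling = FALSE) {
  t <- (0:(n - 1)) / sw
  M <- exp(outer(t, 2i * pi * offset_hz - r2))
  M <- sweep(M, 2, amplitude, "*")
  use_j1 <- if (is.null(j1)) rep(FALSE, length(offset_hz)) else !is.na(j1)
  use_j2 <- if (is.null(j2)) rep(FALSE, length(offset_hz)) else !is.na(j2)
  if (drop_first_coupling) {
    # remove exactly one coupling per signal: j1 if present, else j2
    drop2 <- use_j2 & !use_j1
    use_j1 <- rep(FALSE, length(use_j1))
    use_j2 <- use_j2 & !drop2
  }
  if (any(use_j1)) M[, use_j1] <- M[, use_j1] * cos(pi * outer(t, j1[use_j1]))
  if (any(use_j2)) M[, use_j2] <- M[, use_j2] * cos(pi * outer(t, j2[use_j2]))
  rowSums(M)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Training-set configuration
#'
#' Parameter ranges for the synthetic training planes. The `"full"` scale
#' mirrors the published study conditions (1024-column 13C planes /
#' 512-column 1H planes, sweep widths 2000-5000 Hz, up to 10 signals per
#' plane); the `"reduced"` scale is the desk-size configuration exercised by
#' the test-suite (256 columns, fixed 2000 Hz sweep width, 1-4 signals,
#' doublets only for the 13C network).
#'
#' @param network `"c13"` (decouple + sharpen) or `"h1"` (sharpen only).
#' @param scale `"full"` or `"reduced"`.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `training_config`.
#' @export
training_config <- function(network = c("c13", "h1"),
                            scale = c("full", "reduced"), ...) {
  network <- match.arg(network)
  scale <- match.arg(scale)
  cfg <- if (scale == "full") {
    list(
      input_length = if (network == "c13") 1024L else 512L,
      # acquired points occupy this fraction of the plane; the rest is the
      # zero-filling the enhancement pipeline applies before the network
      support_frac = if (network == "c13") 0.25 else 0.5,
      sw_range = c(2000, 5000),
      n_signals_range = c(1L, 10L),
      r2_range = c(10, 100),
      offset_frac = 1.0,
      p_triplet = if (network == "c13") 0.5 else 0
    )
  } else {
    list(
      input_length = 256L,
      support_frac = 0.5,
      sw_range = c(2000, 2000),
      n_signals_range = c(1L, 4L),
      r2_range = c(20, 80),
      offset_frac = 0.8,
      p_triplet = 0
    )
  }
  cfg <- c(cfg, list(
    network = network, scale = scale,
    jcc_mean = 34, jcc_sd = 2,
    amp_range = c(1, 10),          # log-uniform over one decade
    noise_rel = 0.01,              # complex Gaussian sigma / max amplitude
    r2_max = 25
  ))
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "training_config"
  cfg
}

#' Build one input/target training pair
#'
#' The input plane packs the coupled, broad FID (plus complex Gaussian
#' noise); the target plane packs the same signals with, for the `"c13"`
#' network, one coupling removed per signal and, for both networks, each
#' relaxation rate replaced by [target_r2()]. Both planes are divided by the
#' same normalisation scale (the maximum absolute value of the input plane).
#'
#' @param signal_params `data.frame` with columns `offset_hz`, `amplitude`,
#'   `r2` and (for the 13C network) `j1`, `j2` in Hz (`NA` = absent).
#' @param sw Sweep width in Hz.
#' @param input_length Plane length L (complex points synthesized).
#' @param network `"c13"` or `"h1"`.
#' @param r2_max Ceiling rate for [target_r2()].
#' @param noise_sigma Absolute standard deviation of the complex noise added
#'   to the input FID (0 = none).
#' @param noise_seed Optional integer seed making the noise draw reproducible.
#' @param support Number of complex points actually synthesized (acquired);
#'   the remaining `input_length - support` columns are the zero-filling the
#'   enhancement pipeline applies before the network. Defaults to the full
#'   plane.
#' @return A list of class `training_pair` with elements `input_plane`,
#'   `target_plane`, `scale`, `sw`, `network`.
#' @export
make_training_pair <- function(signal_params, sw, input_length,
                               network = c("c13", "h1"), r2_max = 25,
                               noise_sigma = 0, noise_seed = NULL,
                               support = input_length) {
  network <- match.arg(network)
  p <- signal_params
  L <- as.integer(input_length)
  support <- as.integer(support)
  if (support < 1 || support > L) stop("support must be in [1, input_length]")
  j1 <- if ("j1" %in% names(p)) p$j1 else NULL
  j2 <- if ("j2" %in% names(p)) p$j2 else NULL
  fid_in <- c(synth_fid_hz(p$offset_hz, p$amplitude, p$r2, j1, j2, sw, support),
              complex(L - support))
  if (noise_sigma > 0) {
    noise_fun <- function() {
      complex(real = stats::rnorm(L, 0, noise_sigma),
              imaginary = stats::rnorm(L, 0, noise_sigma))
    }
    fid_in <- fid_in +
      if (is.null(noise_seed)) noise_fun() else with_seed(noise_seed, noise_fun())
  }
  r2_tar <- target_r2(p$r2, r2_max)
  fid_tar <- c(synth_fid_hz(p$offset_hz, p$amplitude, r2_tar, j1, j2, sw, support,
                            drop_first_coupling = (network == "c13")),
               complex(L - support))
  input <- pack_plane(fid_in, L)
  target <- pack_plane(fid_tar, L)
  scale <- max(abs(input))
  if (scale == 0) scale <- 1
  structure(
    list(input_plane = input / scale, target_plane = target / scale,
         scale = scale, sw = sw, network = network),
    class = "training_pair"
  )
}

# draw the per-pair and per-signal metadata tables for a dataset
draw_training_meta <- function(config, n_pairs, split_labels) {
  nsig <- sample(config$n_signals_range[1]:config$n_signals_range[2],
                 n_pairs, replace = TRUE)
  sw <- stats::runif(n_pairs, config$sw_range[1], config$sw_range[2])
  noise_seed <- sample.int(.Machine$integer.max - 1L, n_pairs, replace = TRUE)
  pair_id <- seq_len(n_pairs)
  rows <- rep.int(pair_id, nsig)
  total <- length(rows)
  half_w <- (sw[rows] / 2) * config$offset_frac
  meta <- data.table::data.table(
    pair_id = rows,
    split = split_labels[rows],
    sw = sw[rows],
    n_signals = nsig[rows],
    noise_seed = noise_seed[rows],
    offset_hz = stats::runif(total, -half_w, half_w),
    amplitude = 10^stats::runif(total, log10(config$amp_range[1]),
                                log10(config$amp_range[2])),
    r2 = stats::runif(total, config$r2_range[1], config$r2_range[2])
  )
  if (config$network == "c13") {
    meta$j1 <- draw_jcc(total, config$jcc_mean, config$jcc_sd)
    triplet <- stats::runif(total) < config$p_triplet
    meta$j2 <- ifelse(triplet, draw_jcc(total, config$jcc_mean, config$jcc_sd),
                      NA_real_)
  }
  meta
}

pair_from_meta <- function(meta_rows, config) {
  sw <- meta_rows$sw[1]
  noise_sigma <- config$noise_rel * max(meta_rows$amplitude)
  support <- max(1L, round(config$input_length * (config$support_frac %||% 1)))
  make_training_pair(meta_rows, sw, config$input_length, config$network,
                     r2_max = config$r2_max, noise_sigma = noise_sigma,
                     noise_seed = meta_rows$noise_seed[1], support = support)
}

#' Generate a training data set on disk
#'
#' Draws `n_train + n_test` training pairs under `config` and writes a
#' dataset directory: `manifest.json` (counts, configuration, packing
#' descriptor), `meta.tsv` (one row per signal with the true shifts,
#' couplings and rates, for auditability), and, when `write_planes = TRUE`,
#' raw float32 plane files `planes_train.bin` / `planes_test.bin` (input
#' plane then target plane per pair, both normalised). Planes are a
#' deterministic function of the metadata (the per-pair noise seed is
#' stored), so large datasets can be stored compactly as metadata only and
#' replayed identically by [load_training_set()].
#'
#' @param config A [training_config()].
#' @param n_train,n_test Pair counts (> 0).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param write_planes Materialise plane files (default `TRUE`; the
#'   full-scale 500k-pair configuration is normally written metadata-only).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
generate_training_set <- function(config, n_train, n_test, seed, out_dir,
                                  write_planes = TRUE, overwrite = FALSE) {
  if (n_train <= 0 || n_test <= 0) stop("n_train and n_test must be positive")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("out_dir exists and is not empty; pass overwrite = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_pairs <- n_train + n_test
  split_labels <- rep(c("train", "test"), c(n_train, n_test))
  meta <- draw_training_meta(config, n_pairs, split_labels)
  data.table::fwrite(meta, file.path(out_dir, "meta.tsv"), sep = "\t")

  if (write_planes) {
    for (sp in c("train", "test")) {
      ids <- unique(meta$pair_id[meta$split == sp])
      con <- file(file.path(out_dir, sprintf("planes_%s.bin", sp)), "wb")
      msub <- meta[meta$split == sp, ]
      grp <- base::split(seq_len(nrow(msub)), msub$pair_id)
      for (id in as.character(ids)) {
        pr <- pair_from_meta(msub[grp[[id]], ], config)
        writeBin(as.numeric(rbind(pr$input_plane, pr$target_plane)),
                 con, size = 4)
      }
      close(con)
    }
  }

  manifest <- list(
    format = "fidnetr-training-set/1",
    network = config$network,
    input_length = config$input_length,
    packing = packing_descriptor(),
    n_train = n_train, n_test = n_test,
    seed = seed,
    planes_materialised = write_planes,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load (or replay) a training data set
#'
#' Reads a dataset directory written by [generate_training_set()]. When plane
#' files were materialised they are read directly; otherwise every pair is
#' regenerated from its stored metadata and noise seed, which reproduces the
#' original planes bit-for-bit.
#'
#' @param dir Dataset directory.
#' @param split `"train"` or `"test"`.
#' @param max_pairs Optionally cap the number of pairs returned.
#' @return List with `input` and `target` arrays of dim `c(4, L, n)`, the
#'   `meta` table and the `manifest`.
#' @export
load_training_set <- function(dir, split = c("train", "test"),
                              max_pairs = Inf) {
  split <- match.arg(split)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$packing, packing_descriptor())) {
    stop("dataset packing convention differs from this pipeline's; refusing to load")
  }
  config <- manifest$config
  class(config) <- "training_config"
  meta <- data.table::fread(file.path(dir, "meta.tsv"))
  msub <- meta[meta$split == split, ]
  ids <- unique(msub$pair_id)
  if (length(ids) > max_pairs) {
    ids <- ids[seq_len(max_pairs)]
    msub <- msub[msub$pair_id %in% ids, ]
  }
  L <- as.integer(manifest$input_length)
  n <- length(ids)
  plane_file <- file.path(dir, sprintf("planes_%s.bin", split))
  input <- array(0, c(4, L, n))
  target <- array(0, c(4, L, n))
  if (isTRUE(manifest$planes_materialised) && file.exists(plane_file)) {
    con <- file(plane_file, "rb")
    on.exit(close(con))
    for (k in seq_len(n)) {
      block <- readBin(con, "numeric", 2 * 4 * L, size = 4)
      block <- matrix(block, 8, L)
      input[, , k] <- block[1:4, ]
      target[, , k] <- block[5:8, ]
    }
  } else {
    grp <- base::split(seq_len(nrow(msub)), msub$pair_id)
    for (k in seq_len(n)) {
      pr <- pair_from_meta(msub[grp[[as.character(ids[k])]], ], config)
      input[, , k] <- pr$input_plane
      target[, , k] <- pr$target_plane
    }
  }
  list(input = input, target = target, meta = msub, manifest = manifest)
}
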