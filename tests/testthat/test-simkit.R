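test_that("target_r2 rejects invalid rates and stays in its band", {
  expect_error(target_r2(-1), "finite and >= 0")
  expect_error(target_r2(10, -5), "> 0")
  r <- seq(0, 500, length.out = 2001)
  v <- target_r2(r, 25)
  expect_true(all(v >= 12.5 & v <= 25))
  # continuity: no jump larger than the local slope bound
  expect_lt(max(abs(diff(v))), 2 * diff(r)[1] + 1e-9)
})

test_that("signal_spec enforces the multiplet structure of methyl and CH moieties", {
  expect_silent(signal_spec(0.8, 18, 1, 30, 30, couplings_c = 34, is_methyl = TRUE))
  expect_error(signal_spec(0.8, 18, 1, 30, 30, couplings_c = numeric(), is_methyl = TRUE),
               "exactly 1 coupling")
  expect_error(signal_spec(3, 35, 1, 30, 30, couplings_c = 34, is_methyl = FALSE),
               "exactly 2 couplings")
  expect_error(signal_spec(0.8, 18, -1, 30, 30), "amplitude")
  expect_error(signal_spec(0.8, 18, 1, 30, 30, couplings_c = -34), "couplings")
  expect_error(signal_spec(Inf, 18, 1, 30, 30), "finite")
})

test_that("synthesize_fid realises the cosine-modulated decaying signal model", {
  ax <- nmr_axis(64, 2000, 600, 1.0, "1H")
  # on-carrier, no coupling, no decay -> constant ones
  s0 <- signal_spec(1.0, 18, 1, 1e-12, 1e-12)
  expect_equal(synthesize_fid(list(s0), ax), rep(1 + 0i, 64), tolerance = 1e-9)
  # first point conserves the amplitude sum
  set.seed(2)
  sigs <- lapply(1:5, function(i) {
    signal_spec(runif(1, 0, 2), runif(1, 15, 25), runif(1, 1, 10),
                runif(1, 20, 80), runif(1, 20, 80),
                couplings_c = rnorm(1, 34, 2), is_methyl = TRUE)
  })
  axc <- nmr_axis(256, 2000, 150.9, 20, "13C")
  fid <- synthesize_fid(sigs, axc)
  expect_equal(Re(fid[1]), sum(vapply(sigs, `[[`, numeric(1), "amplitude")))
  expect_equal(Im(fid[1]), 0)
  # a 34 Hz coupling splits the line into maxima 34 Hz apart (+/- one step)
  axd <- nmr_axis(512, 5000, 150.9, 20, "13C")
  d <- signal_spec(0.8, 20, 1, 15, 15, couplings_c = 34, is_methyl = TRUE)
  spec <- Re(stats::fft(synthesize_fid(list(d), axd)))
  f <- (0:511) * 5000 / 512
  f <- ifelse(f >= 2500, f - 5000, f)
  lm <- local_maxima(spec[order(f)])
  top2 <- sort(sort(f)[lm[order(spec[order(f)][lm], decreasing = TRUE)][1:2]])
  expect_lt(abs(diff(top2) - 34), 5000 / 512 + 1e-9)
  # decoupling removes exactly one coupling: doublet -> singlet
  spec_dec <- Re(stats::fft(synthesize_fid(list(d), axd, decoupled = TRUE)))
  expect_identical(length(local_maxima(spec_dec[order(f)])), 1L)
  expect_warning(z <- synthesize_fid(list(), ax), "empty signal")
  expect_equal(z, complex(64))
})

test_that("decoupling redistributes rather than removes multiplet intensity", {
  # integral over each isolated multiplet is conserved within 1%
  axc <- nmr_axis(512, 4000, 150.9, 20, "13C")
  # rates chosen so the decays are complete within the acquisition (the
  # conservation statement is about redistribution, not truncation ringing)
  sigs <- list(
    signal_spec(0.8, 14, 2.0, 50, 50, couplings_c = 34, is_methyl = TRUE),
    signal_spec(1.2, 26, 1.0, 50, 50, couplings_c = c(34, 35), is_methyl = FALSE)
  )
  spec_of <- function(decoupled) {
    g <- ft_axis(grid_1d(synthesize_fid(sigs, axc, decoupled = decoupled), axc),
                 1, keep = "real")
    list(v = as.vector(g$data), ppm = axis_ppm_scale(g$axes[[1]]))
  }
  a <- spec_of(FALSE); b <- spec_of(TRUE)
  for (centre in c(14, 26)) {
    win <- abs(a$ppm - centre) < 4
    ia <- sum(a$v[win]); ib <- sum(b$v[win])
    expect_lt(abs(ia - ib) / abs(ia), 0.01)
  }
})

test_that("training pairs pair coupled/broad inputs with decoupled/sharp targets", {
  # h1 network at the fixed point of the rate map: input equals target
  fp <- uniroot(function(x) target_r2(x, 25) - x, c(13, 20), tol = 1e-12)$root
  p <- data.frame(offset_hz = 120, amplitude = 1, r2 = fp)
  pair <- make_training_pair(p, sw = 2000, input_length = 128, network = "h1")
  expect_equal(pair$input_plane, pair$target_plane, tolerance = 1e-9)
  # c13 doublet: input spectrum has two maxima, target exactly one
  pd <- data.frame(offset_hz = -200, amplitude = 1, r2 = 30, j1 = 34, j2 = NA)
  pc <- make_training_pair(pd, sw = 2000, input_length = 256, network = "c13")
  expect_gte(length(local_maxima(plane_spectrum(pc$input_plane))), 2L)
  expect_identical(length(local_maxima(plane_spectrum(pc$target_plane))), 1L)
  # both planes share the input-derived scale and are finite
  expect_true(all(is.finite(pc$input_plane)) && all(is.finite(pc$target_plane)))
  expect_equal(max(abs(pc$input_plane)), 1)
})

test_that("training-set generation is seeded, counted, and replayable", {
  cfg <- training_config("c13", "reduced")
  d1 <- file.path(tempdir(), "ts1"); d2 <- file.path(tempdir(), "ts2")
  generate_training_set(cfg, 10, 2, seed = 5, out_dir = d1, overwrite = TRUE)
  generate_training_set(cfg, 10, 2, seed = 5, out_dir = d2, overwrite = TRUE)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"), simplifyVector = TRUE)
  expect_identical(m1$n_train, 10L)
  expect_identical(m1$n_test, 2L)
  expect_identical(tools::md5sum(file.path(d1, "meta.tsv"))[[1]],
                   tools::md5sum(file.path(d2, "meta.tsv"))[[1]])
  expect_identical(tools::md5sum(file.path(d1, "planes_train.bin"))[[1]],
                   tools::md5sum(file.path(d2, "planes_train.bin"))[[1]])
  # loader replays metadata-only datasets identically to materialised planes
  d3 <- file.path(tempdir(), "ts3")
  generate_training_set(cfg, 10, 2, seed = 5, out_dir = d3,
                        write_planes = FALSE, overwrite = TRUE)
  from_file <- load_training_set(d1, "train")
  replayed <- load_training_set(d3, "train")
  expect_equal(from_file$input, replayed$input, tolerance = 1e-6)
  expect_error(generate_training_set(cfg, 0, 2, seed = 1, out_dir = tempfile()),
               "positive")
  # changing the seed changes the data
  d4 <- file.path(tempdir(), "ts4")
  generate_training_set(cfg, 10, 2, seed = 6, out_dir = d4, overwrite = TRUE)
  expect_false(tools::md5sum(file.path(d1, "meta.tsv"))[[1]] ==
                 tools::md5sum(file.path(d4, "meta.tsv"))[[1]])
  unlink(c(d1, d2, d3, d4), recursive = TRUE)
})

test_that("shift statistics fixture covers the required methyl sites", {
  stats <- load_shift_stats()
  expect_true(all(stats$sd_shift_h > 0 & stats$sd_shift_c > 0))
  key <- paste(stats$residue_type, stats$methyl_site, sep = ".")
  expect_true(all(c("Ala.B", "Ile.D1", "Ile.G2", "Leu.D1", "Leu.D2",
                    "Val.G1", "Val.G2", "Thr.G2", "Met.E") %in% key))
  # truncated table rejected
  trunc <- stats[stats$residue_type != "Met", ]
  tmp <- tempfile(fileext = ".tsv")
  write.table(trunc, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_shift_stats(tmp), "Met.E")
})

test_that("benchmark spectra follow the per-kind study conditions", {
  set.seed(9)
  sp <- tiny_benchmark(n_signals = 40L)
  tr <- sp$truth
  expect_identical(nrow(tr), 40L)
  expect_identical(sum(tr$is_methyl), 20L)
  expect_true(all(tr$multiplicity[tr$is_methyl] == "doublet"))
  expect_true(all(tr$multiplicity[!tr$is_methyl] == "triplet"))
  # observed (aliased) positions lie inside the acquired windows
  h_win <- range(axis_ppm_scale(nmr_axis(64, 2000, sp$coupled$axes[[1]]$larmor_frequency,
                                         2.0, "1H", domain = "frequency")))
  expect_true(all(tr$h_ppm >= h_win[1] - 0.01 & tr$h_ppm <= h_win[2] + 0.01))
  # truth positions coincide with target-spectrum maxima (coupling-free)
  tgt <- process_reference(sp$target, proc_config(display_apodize = "cosine"))
  pk <- pick_peaks(tgt, 8)
  iso <- isolated_truth(tr)
  m <- match_peaks(pk, iso, 0.03)
  expect_gte(nrow(m), 0.9 * nrow(iso))
  # suite writer: counts, overwrite guard, reproducible checksums
  dir <- file.path(tempdir(), "mini-suite")
  m1 <- generate_benchmark_suite(n_per_kind = 2, seed = 2, out_dir = dir,
                                 kinds = "hdac_like", overwrite = TRUE,
                                 n_signals = 20L, n_h = 32L, n_c = 16L)
  expect_identical(m1$n_spectra, 2L)
  expect_error(generate_benchmark_suite(n_per_kind = 2, seed = 2, out_dir = dir,
                                        kinds = "hdac_like"), "overwrite")
  unlink(dir, recursive = TRUE)
})
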