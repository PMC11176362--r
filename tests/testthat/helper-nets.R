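# Reduced networks trained once per test session and reused across files.
# Training follows the reduced study conditions: 2000 training + 200
# validation pairs, RMSprop at 1e-3 then 1e-4, mini-batches of 16.

.net_cache <- new.env(parent = emptyenv())

reduced_c13_net <- function() {
  if (!is.null(.net_cache$c13)) return(.net_cache$c13)
  t0 <- Sys.time()
  dir <- file.path(tempdir(), "fidnetr-test-ds-c13")
  generate_training_set(training_config("c13", "reduced"), 2000, 200,
                        seed = 101, out_dir = dir, overwrite = TRUE)
  tr <- load_training_set(dir, "train")
  va <- load_training_set(dir, "test")
  net <- build_network(model_config("c13", "reduced"), seed = 7)
  tc <- train_config(lr_initial = 1e-3, lr_reduced = 1e-4, batch_size = 16,
                     plateau_patience = 4, max_epochs = 30, seed = 7)
  net <- train_network(net, list(input = tr$input, target = tr$target,
                                 val = list(input = va$input, target = va$target)),
                       tc, train_sw = 2000)
  n <- dim(va$input)[3]
  baseline <- mean(vapply(seq_len(n), function(k) {
    spectral_loss(va$input[, , k], va$target[, , k])
  }, numeric(1)))
  .net_cache$c13 <- net
  .net_cache$c13_baseline <- baseline
  .net_cache$c13_minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  net
}

reduced_c13_baseline <- function() {
  reduced_c13_net()
  .net_cache$c13_baseline
}

reduced_c13_train_minutes <- function() {
  reduced_c13_net()
  .net_cache$c13_minutes
}

reduced_h1_net <- function() {
  if (!is.null(.net_cache$h1)) return(.net_cache$h1)
  dir <- file.path(tempdir(), "fidnetr-test-ds-h1")
  generate_training_set(training_config("h1", "reduced"), 2000, 200,
                        seed = 202, out_dir = dir, overwrite = TRUE)
  tr <- load_training_set(dir, "train")
  va <- load_training_set(dir, "test")
  net <- build_network(model_config("h1", "reduced"), seed = 8)
  tc <- train_config(lr_initial = 1e-3, lr_reduced = 1e-4, batch_size = 16,
                     plateau_patience = 4, max_epochs = 25, seed = 8)
  net <- train_network(net, list(input = tr$input, target = tr$target,
                                 val = list(input = va$input, target = va$target)),
                       tc, train_sw = 2000)
  .net_cache$h1 <- net
  net
}

# held-out single-doublet planes matching the reduced study conditions
doublet_eval_plane <- function(k) {
  set.seed(900 + k)
  p <- data.frame(offset_hz = runif(1, -800, 800),
                  amplitude = 10^runif(1, 0, 1),
                  r2 = runif(1, 20, 80),
                  j1 = rnorm(1, 34, 2), j2 = NA_real_)
  pair <- make_training_pair(p, sw = 2000, input_length = 256, network = "c13",
                             noise_sigma = 0.01 * p$amplitude, noise_seed = k,
                             support = 128)
  list(pair = pair, params = p)
}

# TRUE if the network output is a singlet at the true shift: the global
# frequency-domain maximum lies within +/- 1 grid step of the truth and no
# other local maximum beyond the central 2 bins exceeds half its height
doublet_converted <- function(net, plane_info) {
  out <- apply_network(net, plane_info$pair$input_plane)
  spec <- plane_spectrum(out)
  freqs <- display_freqs(2000, length(spec))
  truth_bin <- which.min(abs(freqs - plane_info$params$offset_hz))
  mx <- which.max(spec)
  lm <- local_maxima(spec)
  competing <- lm[spec[lm] > 0.5 * spec[mx] & abs(lm - mx) > 2]
  abs(mx - truth_bin) <= 1 && length(competing) == 0
}
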