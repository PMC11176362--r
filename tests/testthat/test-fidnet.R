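tiny_cfg <- function(L = 32L, dil = c(1L, 2L), F = 4L) {
  model_config("c13", "reduced", input_length = L, dilations = dil, filters = F)
}

test_that("model configurations encode the published architectures", {
  c13 <- model_config("c13")
  expect_identical(length(c13$dilations), 17L)
  expect_identical(c13$filters, 128L)
  expect_identical(c13$input_length, 1024L)
  h1 <- model_config("h1")
  expect_identical(length(h1$dilations), 13L)
  expect_identical(h1$filters, 64L)
  expect_identical(h1$input_length, 512L)
  expect_identical(c13$kernel, c(8L, 4L))
  expect_error(model_config("c13", filters = 7), "even")
  expect_error(model_config("c13", dilations = c(4, 2, 1)), "non-decreasing")
})

test_that("the network preserves shape and the skip projection drives the output", {
  net <- build_network(tiny_cfg(), seed = 3)
  x <- array(rnorm(4 * 32 * 3), c(4, 32, 3))
  y <- apply_network(net, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # zero-initialised final aggregation -> zero output for any input
  net0 <- build_network(tiny_cfg(), seed = 3, zero_output = TRUE)
  expect_true(all(apply_network(net0, x) == 0))
  # batch independence: batch of 1 equals first element of the batch
  y1 <- apply_network(net, x[, , 1])
  expect_equal(y1, y[, , 1], tolerance = 1e-12)
  # longer planes rejected with a truncation instruction
  long <- array(rnorm(4 * 64), c(4, 64, 1))
  expect_error(apply_network(net, long), "band-extract or truncate")
  # shorter planes are zero-filled
  shortp <- array(rnorm(4 * 16), c(4, 16, 1))
  expect_identical(dim(apply_network(net, shortp)), c(4L, 32L, 1L))
})

test_that("spectral_loss is a frequency-domain MSE with Parseval scaling", {
  set.seed(8)
  a <- pack_plane(complex(real = rnorm(64), imaginary = rnorm(64)))
  expect_identical(spectral_loss(a, a), 0)
  # perturbing one time point spreads |delta|^2 over the grid (Parseval):
  # Re(F e_j)_k = cos(2 pi k j / N), so the loss is delta^2 * mean(cos^2)
  delta <- 0.37
  b <- a
  b[1, 11] <- b[1, 11] + delta
  k <- 0:63
  oracle <- delta^2 * mean(cos(2 * pi * k * 10 / 64)^2)
  expect_equal(spectral_loss(b, a), oracle, tolerance = 1e-12)
  # homogeneity of degree 2
  expect_equal(spectral_loss(3 * a, 3 * 0 * a), 9 * spectral_loss(a, 0 * a))
  expect_error(spectral_loss(a, a[, 1:10]), "identical shapes")
})

test_that("the C++ training loss agrees with the R spectral loss", {
  set.seed(5)
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 7)
  x <- array(rnorm(4 * 32 * 3), c(4, 32, 3))
  tgt <- array(rnorm(4 * 32 * 3), c(4, 32, 3))
  pred <- fidnetr:::fidnet_predict_cpp(net$params, x, dim(x), cfg$dilations,
                                       cfg$filters, 3L)
  lcpp <- fidnetr:::fidnet_epoch_cpp(net$params, net$params, x, tgt, dim(x),
                                     1:3, cfg$dilations, cfg$filters,
                                     1e-4, 3, FALSE)
  lr <- mean(vapply(1:3, function(k) spectral_loss(pred[, , k], tgt[, , k]),
                    numeric(1)))
  expect_equal(lcpp, lr, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  cfg <- tiny_cfg(L = 16L)
  net <- build_network(cfg, seed = 5)
  x <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
  tgt <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
  g <- fidnetr:::fidnet_grad_cpp(net$params, x, tgt, dim(x), cfg$dilations,
                                 cfg$filters)
  lossfn <- function(p) {
    fidnetr:::fidnet_epoch_cpp(p, p, x, tgt, dim(x), 1:2, cfg$dilations,
                               cfg$filters, 0, 2, FALSE)
  }
  eps <- 1e-6
  for (pi in seq_along(net$params)) {
    for (k in sample(length(net$params[[pi]]), min(3, length(net$params[[pi]])))) {
      up <- lapply(net$params, identity); up[[pi]][k] <- up[[pi]][k] + eps
      dn <- lapply(net$params, identity); dn[[pi]][k] <- dn[[pi]][k] - eps
      fd <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(g[[pi]][k], fd, tolerance = 1e-4)
    }
  }
})

test_that("training follows the two-phase plateau schedule reproducibly", {
  set.seed(10)
  cfg <- tiny_cfg(L = 64L, dil = 1L, F = 4L)
  mk_data <- function(n, seed) {
    set.seed(seed)
    input <- array(0, c(4, 64, n)); target <- array(0, c(4, 64, n))
    for (k in seq_len(n)) {
      p <- data.frame(offset_hz = runif(1, -800, 800), amplitude = 1,
                      r2 = runif(1, 20, 80))
      pr <- make_training_pair(p, 2000, 64, "h1")
      input[, , k] <- pr$input_plane; target[, , k] <- pr$target_plane
    }
    list(input = input, target = target)
  }
  d <- mk_data(48, 1)
  d$val <- mk_data(12, 2)
  # a plateau tolerance larger than any achievable improvement makes the
  # schedule mechanics deterministic: stall from epoch one, reduce once
  # after `patience` epochs, stop after another `patience`
  tc <- train_config(lr_initial = 1e-3, lr_reduced = 1e-4,
                     plateau_patience = 3, plateau_tol = 1e6,
                     batch_size = 8, max_epochs = 30, seed = 4)
  net <- train_network(build_network(cfg, seed = 2), d, tc)
  expect_identical(net$lr_reductions, 1L)
  expect_identical(sort(unique(net$history$lr)), c(1e-4, 1e-3))
  # first epoch always improves on Inf; the stall then builds over
  # `patience` epochs, the reduction fires with epoch 4, and the second
  # stall stops training after epoch 7
  expect_identical(nrow(net$history), 7L)
  expect_identical(net$history$lr, c(rep(1e-3, 4), rep(1e-4, 3)))
  expect_true(all(is.finite(net$history$val_loss)))
  # the six epochs of updates reduced the training loss
  expect_lt(tail(net$history$train_loss, 1), net$history$train_loss[1])
  # same seed + same data -> identical first-epoch loss
  net2 <- train_network(build_network(cfg, seed = 2), d, tc)
  expect_identical(net2$history$train_loss[1], net$history$train_loss[1])
})

test_that("weights roundtrip through the checkpoint and sidecar", {
  net <- build_network(tiny_cfg(), seed = 11)
  x <- array(rnorm(4 * 32 * 2), c(4, 32, 2))
  base <- file.path(tempdir(), "wtest")
  save_network(net, base)
  net2 <- load_network(base)
  expect_equal(apply_network(net2, x), apply_network(net, x), tolerance = 1e-12)
  # a sidecar with a foreign packing convention is refused
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  side$packing <- "rows=[Im,Re] (incompatible)"
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE)
  expect_error(load_network(base), "packing")
})
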