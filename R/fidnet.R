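#' Network architecture configuration
#'
#' Describes one gated dilated convolutional network. The full-scale 13C
#' network (decouple + sharpen) uses a 1024-column input, dilations cycled
#' through 1, 2, 4, 6, 8, 10, 12, 14, 16, 20, 24, 28, 32, 40, 48, 56, 64 and
#' 128 filters per convolutional layer; the full-scale 1H network (sharpen
#' only) uses 512 columns, dilations up to 32 and 64 filters. Reduced
#' configurations (fewer dilations/filters, shorter planes) are used for
#' desk-scale training demonstrations.
#'
#' @param network `"c13"` or `"h1"` (selects the defaults).
#' @param input_length Plane columns L.
#' @param dilations Ordered (non-decreasing) integer dilation schedule; one
#'   residual unit per entry.
#' @param filters Filters per convolutional layer (even; the gating splits
#'   them 50% sigmoid / 50% tanh).
#' @param scale `"full"` or `"reduced"`.
#' @return A list of class `model_config`. Kernel size is fixed at 8 x 4.
#' @export
model_config <- function(network = c("c13", "h1"), scale = c("full", "reduced"),
                         input_length = NULL, dilations = NULL, filters = NULL) {
  network <- match.arg(network)
  scale <- match.arg(scale)
  defaults <- if (scale == "full") {
    if (network == "c13") {
      list(input_length = 1024L,
           dilations = c(1L, 2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 20L, 24L,
                         28L, 32L, 40L, 48L, 56L, 64L),
           filters = 128L)
    } else {
      list(input_length = 512L,
           dilations = c(1L, 2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 20L, 24L,
                         28L, 32L),
           filters = 64L)
    }
  } else {
    if (network == "c13") {
      list(input_length = 256L, dilations = c(1L, 2L, 4L, 8L), filters = 8L)
    } else {
      list(input_length = 256L, dilations = c(1L, 2L, 4L), filters = 8L)
    }
  }
  cfg <- list(
    network = network, scale = scale,
    input_length = as.integer(input_length %||% defaults$input_length),
    dilations = as.integer(dilations %||% defaults$dilations),
    filters = as.integer(filters %||% defaults$filters),
    n_rows = 4L, kernel = c(8L, 4L), activation_split = 0.5
  )
  if (cfg$filters %% 2L != 0L) stop("filters must be even")
  if (is.unsorted(cfg$dilations)) stop("dilations must be non-decreasing")
  if (cfg$input_length < 8L) stop("input_length too small")
  class(cfg) <- "model_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training schedule configuration
#'
#' Two-phase schedule: the learning rate starts at `lr_initial` until the
#' validation loss plateaus (no improvement greater than `plateau_tol` for
#' `plateau_patience` consecutive epochs), is then reduced to `lr_reduced`
#' until a second plateau, at which point training stops.
#'
#' @param lr_initial,lr_reduced Learning rates (reduced < initial).
#' @param plateau_patience Epochs without improvement defining a plateau.
#' @param plateau_tol Minimum improvement counted as progress.
#' @param batch_size Mini-batch size.
#' @param max_epochs Hard cap on total epochs.
#' @param seed Integer seed for shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr_initial = 1e-4, lr_reduced = 1e-5,
                         plateau_patience = 5, plateau_tol = 1e-6,
                         batch_size = 16, max_epochs = 200, seed = 1) {
  if (lr_reduced >= lr_initial) stop("lr_reduced must be < lr_initial")
  if (plateau_patience < 1) stop("plateau_patience must be >= 1")
  structure(
    list(lr_initial = lr_initial, lr_reduced = lr_reduced,
         plateau_patience = as.integer(plateau_patience),
         plateau_tol = plateau_tol, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
    class = "train_config"
  )
}

# parameter list in the fixed layout the C++ engine expects
init_params <- function(cfg, seed = 1, zero_output = FALSE) {
  set.seed(seed)
  F <- cfg$filters
  half <- F %/% 2L
  taps <- 4L * 8L
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  params <- list(he(F, 1L, 1), numeric(F))
  for (u in seq_along(cfg$dilations)) {
    params <- c(params, list(
      he(F, F * taps, F * taps), numeric(F),
      he(F, half * taps, half * taps), numeric(F)
    ))
  }
  wout <- if (zero_output) matrix(0, 1, F) else he(1L, F, F)
  c(params, list(wout, numeric(1)))
}

zero_like_params <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
}

#' Build a network
#'
#' Initialises the parameters of a gated dilated convolutional network with
#' He-scaled Gaussian weights and zero biases. The returned handle carries
#' the architecture, the packing convention and (after training) the
#' sweep-width the training planes were sampled at.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight initialisation.
#' @param zero_output If `TRUE` the final skip-aggregation projection is
#'   zero-initialised, making the network output identically zero (useful to
#'   verify the skip-sum contract).
#' @return An object of class `fidnet`.
#' @export
build_network <- function(cfg, seed = 1, zero_output = FALSE) {
  if (!inherits(cfg, "model_config")) stop("cfg must be a model_config")
  structure(
    list(cfg = cfg, params = init_params(cfg, seed, zero_output),
         packing = packing_descriptor(), trained = FALSE,
         train_sw = NULL, history = NULL),
    class = "fidnet"
  )
}

#' Identity stand-in network
#'
#' Returns its input unchanged when applied; used as a debugging device (the
#' enhancement pipeline with identity networks reduces exactly to
#' conventional Fourier processing).
#'
#' @param input_length Plane columns the stand-in reports (any length is
#'   accepted on application).
#' @return An object of class `fidnet_identity`.
#' @export
identity_network <- function(input_length = NA_integer_) {
  structure(list(cfg = list(input_length = input_length),
                 packing = packing_descriptor()),
            class = "fidnet_identity")
}

#' @export
print.fidnet <- function(x, ...) {
  cat(sprintf(
    "<fidnet %s/%s> L=%d, %d units (dilations %s), %d filters%s\n",
    x$cfg$network, x$cfg$scale, x$cfg$input_length,
    length(x$cfg$dilations), paste(x$cfg$dilations, collapse = ","),
    x$cfg$filters, if (x$trained) ", trained" else ""
  ))
  invisible(x)
}

#' Frequency-domain mean squared error between two planes
#'
#' Unpacks both planes to complex vectors, Fourier transforms them and
#' returns the mean squared difference of the real frequency-domain points.
#' Non-negative, zero iff the transforms' real parts coincide, and
#' homogeneous of degree 2 in the amplitudes. This is the training cost of
#' both networks.
#'
#' @param predicted_plane,target_plane 4 x L planes (see [pack_plane()]).
#' @return Scalar loss.
#' @export
spectral_loss <- function(predicted_plane, target_plane) {
  if (!all(dim(predicted_plane) == dim(target_plane))) {
    stop("planes must have identical shapes")
  }
  e <- Re(stats::fft(unpack_plane(predicted_plane))) -
    Re(stats::fft(unpack_plane(target_plane)))
  mean(e^2)
}

#' Train a network
#'
#' Runs mini-batch RMSprop on the frequency-domain MSE with the two-phase
#' learning-rate schedule of [train_config()]. Validation loss is evaluated
#' after every epoch on the supplied validation split; plateau detection
#' drives one learning-rate reduction and then the stop.
#'
#' @param net A [build_network()] handle.
#' @param data List with arrays `input` and `target` of dim `c(4, L, n)`
#'   (e.g. from [load_training_set()]); `val` an analogous list for the
#'   validation split.
#' @param tc A [train_config()].
#' @param train_sw Optional sweep width (Hz) of the training planes, recorded
#'   on the handle for provenance.
#' @param verbose Print per-epoch losses.
#' @return The trained `fidnet` handle with a `history` data.frame
#'   (epoch, lr, train_loss, val_loss) and `lr_reductions` count.
#' @export
train_network <- function(net, data, tc = train_config(), train_sw = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(net, "fidnet"))
  cfg <- net$cfg
  L <- cfg$input_length
  if (dim(data$input)[2] != L) {
    stop("training planes do not match the network input length")
  }
  n <- dim(data$input)[3]
  vcache <- zero_like_params(net$params)
  set.seed(tc$seed)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  phase <- 1L
  lr <- tc$lr_initial
  best <- Inf
  stall <- 0L
  reductions <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- fidnet_epoch_cpp(net$params, vcache, data$input, data$target,
                                dim(data$input), ord, cfg$dilations,
                                cfg$filters, lr, tc$batch_size, TRUE)
    val_loss <- fidnet_epoch_cpp(net$params, vcache, data$val$input,
                                 data$val$target, dim(data$val$input),
                                 seq_len(dim(data$val$input)[3]),
                                 cfg$dilations, cfg$filters, lr,
                                 tc$batch_size, FALSE)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = tr_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.1e  train %.4e  val %.4e",
                      epoch, lr, tr_loss, val_loss))
    }
    if (val_loss < best - tc$plateau_tol) {
      best <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= tc$plateau_patience) {
      if (phase == 1L) {
        phase <- 2L
        lr <- tc$lr_reduced
        reductions <- reductions + 1L
        best <- val_loss
        stall <- 0L
      } else {
        break
      }
    }
  }
  net$trained <- TRUE
  net$history <- history
  net$lr_reductions <- reductions
  net$train_sw <- train_sw
  net
}

#' Apply a network to a batch of planes
#'
#' Planes are normalised by their per-plane maximum absolute value on entry
#' and the normalisation is inverted on exit, so inference is amplitude
#' covariant. Planes shorter than the network input length must be
#' zero-filled by the caller ([pack_plane()] does this); longer planes are
#' rejected with instructions to extract or truncate first.
#'
#' @param net A trained [build_network()] handle or [identity_network()].
#' @param planes A single 4 x L plane or an array of dim `c(4, L, n)`.
#' @param batch_size Inference batch size.
#' @return Array of the same shape as `planes`.
#' @export
apply_network <- function(net, planes, batch_size = 64) {
  single <- length(dim(planes)) == 2
  if (single) dim(planes) <- c(dim(planes), 1L)
  if (inherits(net, "fidnet_identity")) {
    if (single) dim(planes) <- dim(planes)[1:2]
    return(planes)
  }
  stopifnot(inherits(net, "fidnet"))
  L <- net$cfg$input_length
  if (dim(planes)[2] > L) {
    stop(sprintf(
      "planes have %d columns but the network accepts %d; band-extract or truncate the dimension first",
      dim(planes)[2], L
    ))
  }
  if (dim(planes)[2] < L) {
    padded <- array(0, c(4L, L, dim(planes)[3]))
    padded[, seq_len(dim(planes)[2]), ] <- planes
    planes <- padded
  }
  scales <- apply(abs(planes), 3, max)
  scales[scales == 0] <- 1
  norm <- sweep(planes, 3, scales, "/")
  out <- fidnet_predict_cpp(net$params, norm, dim(norm), net$cfg$dilations,
                            net$cfg$filters, as.integer(batch_size))
  out <- sweep(out, 3, scales, "*")
  if (single) dim(out) <- dim(out)[1:2]
  out
}

#' Save or load network weights
#'
#' Weights go to `<path>.bin` (raw float64) with a JSON sidecar `<path>.json`
#' recording the architecture and the packing convention. Loading refuses a
#' sidecar whose packing differs from this pipeline's.
#'
#' @param net A `fidnet` handle.
#' @param path Basename (without extension) for the two files.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the reconstructed `fidnet` handle.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "fidnet"))
  sidecar <- list(
    format = "fidnetr-weights/1",
    cfg = unclass(net$cfg),
    packing = net$packing,
    skip_source = "output of the second convolution of each residual unit",
    trained = net$trained,
    train_sw = net$train_sw,
    param_lengths = vapply(net$params, length, integer(1))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (p in net$params) writeBin(as.numeric(p), con, size = 8)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sidecar$packing, packing_descriptor())) {
    stop("weight sidecar uses a different packing convention; refusing to load")
  }
  cfg <- sidecar$cfg
  cfg$dilations <- as.integer(cfg$dilations)
  class(cfg) <- "model_config"
  net <- build_network(cfg, seed = 1)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  for (i in seq_along(net$params)) {
    vals <- readBin(con, "numeric", sidecar$param_lengths[i], size = 8)
    if (is.matrix(net$params[[i]])) {
      net$params[[i]] <- matrix(vals, nrow(net$params[[i]]), ncol(net$params[[i]]))
    } else {
      net$params[[i]] <- vals
    }
  }
  net$trained <- isTRUE(sidecar$trained)
  net$train_sw <- sidecar$train_sw
  net
}
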