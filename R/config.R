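#' Load a YAML run configuration
#'
#' Reads a YAML file whose sections (`benchmark`, `training`, `model`) carry
#' named overrides for [benchmark_config()], [training_config()] and
#' [model_config()]. The shipped default (`inst/config/default.yaml`)
#' mirrors the benchmark parameter names (number of signals, Larmor
#' frequency set, sweep-width ranges, coupling and relaxation
#' distributions).
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return Named list of configuration sections.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("config", "default.yaml", package = "fidnetr")
  }
  yaml::read_yaml(path)
}

#' Derive per-module seeds from one global seed
#'
#' A single run seed fans out to the package's stochastic modules through
#' fixed offsets, keeping cross-module runs reproducible from one integer.
#'
#' @param seed Global integer seed.
#' @return Named list of module seeds (all below 2^31).
#' @export
derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(
    simulate = base * 1000L + 1L,
    benchmark = base * 1000L + 2L,
    train = base * 1000L + 3L,
    noe = base * 1000L + 4L
  )
}
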