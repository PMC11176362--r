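# shared fixtures and small oracles, all generated in code

# wrap a complex vector as a 1D spectrum_grid (interleaved storage)
grid_1d <- function(z, axis) {
  v <- numeric(2 * length(z))
  v[c(TRUE, FALSE)] <- Re(z)
  v[c(FALSE, TRUE)] <- Im(z)
  spectrum_grid(v, list(axis))
}

# complex vector along one axis of a grid (single-vector grids)
grid_complex <- function(grid) {
  v <- grid$data
  v[c(TRUE, FALSE)] + 1i * v[c(FALSE, TRUE)]
}

# display-ordered frequency axis (Hz offsets) of an n-point transform
display_freqs <- function(sw, n) {
  k <- 0:(n - 1)
  f <- ifelse(k >= n / 2, k - n, k) * sw / n
  sort(f, decreasing = TRUE)
}

# real display spectrum of a packed 4 x L plane
plane_spectrum <- function(plane) {
  s <- Re(stats::fft(unpack_plane(plane)))
  k <- 0:(length(s) - 1)
  f <- ifelse(k >= length(s) / 2, k - length(s), k)
  s[order(f, decreasing = TRUE)]
}

# indices of strict local maxima of a vector
local_maxima <- function(v) which(diff(sign(diff(v))) == -2) + 1L

# exhaustive optimal one-to-one assignment (maximum number of matches within
# radius) for small peak sets; oracle for the greedy matcher
optimal_match_count <- function(picked, truth, radius, c_scale = 4) {
  np <- nrow(picked); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  d <- outer(seq_len(np), seq_len(nt), function(a, b) {
    pmax(abs(picked$h_ppm[a] - truth$h_ppm[b]),
         abs(picked$c_ppm[a] - truth$c_ppm[b]) / c_scale)
  })
  admissible <- d <= radius
  best <- 0L
  # branch over picked peaks; nt <= 6 keeps this tiny
  recurse <- function(p, used) {
    if (p > np) return(0L)
    top <- recurse(p + 1L, used)              # leave p unmatched
    for (tt in seq_len(nt)) {
      if (!used[tt] && admissible[p, tt]) {
        used2 <- used; used2[tt] <- TRUE
        top <- max(top, 1L + recurse(p + 1L, used2))
      }
    }
    top
  }
  recurse(1L, rep(FALSE, nt))
}

# random small matching instance with all pairwise separations > min_sep
random_peak_instance <- function(n_max = 6, min_sep) {
  repeat {
    n <- sample(1:n_max, 1)
    h <- runif(n, 0, 2)
    cc <- runif(n, 10, 30)
    if (n == 1) break
    d <- outer(seq_len(n), seq_len(n), function(a, b) {
      pmax(abs(h[a] - h[b]), abs(cc[a] - cc[b]) / 4)
    })
    diag(d) <- Inf
    if (min(d) > min_sep) break
  }
  data.frame(id = seq_len(n), h_ppm = h, c_ppm = cc)
}

# small noiseless benchmark-like 2D plane with isolated signals
tiny_benchmark <- function(n_signals = 12L, n_h = 64L, n_c = 32L, snr = Inf,
                           seed = 5) {
  set.seed(seed)
  cfg <- benchmark_config("hdac_like", n_signals = n_signals, n_h = n_h,
                          n_c = n_c, snr = snr,
                          sw_range_h = c(2000, 2000),
                          sw_range_c = c(2000, 2000))
  generate_benchmark_spectrum(cfg)
}
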