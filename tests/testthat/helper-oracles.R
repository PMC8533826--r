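# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately written as plain loops, independent
# of the package's vectorized implementations.

# Direct Gaussian-mixture kernel sum, normalized on the grid: the KDE
# oracle.
oracle_kde <- function(grid, offsets, bw, step = 1) {
  dens <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (o in offsets) {
      s <- s + exp(-0.5 * ((grid[i] - o) / bw)^2) / (bw * sqrt(2 * pi))
    }
    dens[i] <- s / length(offsets)
  }
  dens / (sum(dens) * step)
}

# Enumerate strict local maxima, apply the relative-height threshold, then
# greedy suppression by descending height (ties to earlier time).
oracle_find_peaks <- function(grid, y, rel_threshold = 0.40,
                              min_distance = 100) {
  cand_t <- numeric(0)
  cand_h <- numeric(0)
  for (i in seq_along(y)) {
    if (i == 1L || i == length(y)) next
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) {
      cand_t <- c(cand_t, grid[i])
      cand_h <- c(cand_h, y[i])
    }
  }
  if (length(cand_h) == 0L) {
    return(data.frame(time_ms = numeric(0), height = numeric(0)))
  }
  keep <- cand_h >= rel_threshold * max(cand_h)
  cand_t <- cand_t[keep]
  cand_h <- cand_h[keep]
  sel_t <- numeric(0)
  sel_h <- numeric(0)
  remaining <- seq_along(cand_t)
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    for (j in remaining) {
      if (cand_h[j] > cand_h[best] ||
          (cand_h[j] == cand_h[best] && cand_t[j] < cand_t[best])) {
        best <- j
      }
    }
    ok <- TRUE
    for (k in seq_along(sel_t)) {
      if (abs(cand_t[best] - sel_t[k]) < min_distance) ok <- FALSE
    }
    if (ok) {
      sel_t <- c(sel_t, cand_t[best])
      sel_h <- c(sel_h, cand_h[best])
    }
    remaining <- setdiff(remaining, best)
  }
  o <- order(sel_t)
  data.frame(time_ms = sel_t[o], height = sel_h[o])
}

# Random multimodal density on a 1 ms grid, wrapped as a tap_density.
random_density <- function(duration = 1000, n_bumps = sample(1:6, 1),
                           window = 120) {
  grid <- seq(-window, duration + window, by = 1)
  y <- rep(1e-8, length(grid))
  centers <- runif(n_bumps, 0, duration)
  widths <- runif(n_bumps, 8, 60)
  heights <- runif(n_bumps, 0.1, 1)
  for (b in seq_len(n_bumps)) {
    y <- y + heights[b] * exp(-0.5 * ((grid - centers[b]) / widths[b])^2)
  }
  y <- y / sum(y)
  structure(list(grid_ms = grid, density = y, bandwidth_ms = NA_real_,
                 n_taps = NA_integer_),
            class = "tap_density")
}

# A tap_density with strict local maxima at prescribed times and heights
# (narrow triangular bumps on an otherwise increasing-then-flat floor).
density_with_modes <- function(times, heights, duration = 500,
                               window = 120) {
  grid <- seq(-window, duration + window, by = 1)
  y <- rep(0, length(grid))
  for (k in seq_along(times)) {
    d <- abs(grid - times[k])
    y <- pmax(y, heights[k] * pmax(1 - d / 30, 0))
  }
  structure(list(grid_ms = grid, density = y / sum(y),
                 bandwidth_ms = NA_real_, n_taps = NA_integer_),
            class = "tap_density")
}

# Minimal sentence fixture: nuclei at given onsets, default loop structure.
make_stimulus <- function(onsets = c(200, 500, 800), duration = 1000,
                          weight = NULL, ntype = NULL, id = "fix01", ...) {
  n <- length(onsets)
  weight <- weight %||% rep(c("strong", "weak"), length.out = n)
  ntype <- ntype %||% rep("vowel", n)
  syl <- data.frame(label = sprintf("syl%02d", seq_len(n)),
                    syllable_onset_ms = onsets - 20,
                    nucleus_onset_ms = onsets,
                    nucleus_end_ms = onsets + 80,
                    weight = weight, nucleus_type = ntype,
                    stringsAsFactors = FALSE)
  sentence_stimulus(id, duration, syl, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raw vector with exactly the requested mean and sample SD.
sample_with_summary <- function(n, m, s) {
  z <- rnorm(n)
  m + s * (z - mean(z)) / sd(z)
}
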