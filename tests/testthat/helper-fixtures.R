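# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

# small random valid cube (raw 10-bit mode)
random_cube <- function(rows = 4, cols = 4, nk = 8, nj = 8, seed = 1,
                        max_count = 50, dwell = 85) {
  set.seed(seed)
  flim_cube(array(sample.int(max_count + 1L, rows * cols * nk * nj,
                             replace = TRUE) - 1L,
                  dim = c(rows, cols, nk, nj)),
            spectral_axis(nk, 500, 760),
            time_axis(nj, 50 / nj),
            chained = FALSE, dwell_time = dwell,
            provenance = list(origin = "test fixture"))
}

# two-fluorophore phantom with spatially disjoint regions and disjoint
# emission bands; the workhorse ground-truth scene
two_region_phantom <- function(rows = 24, cols = 24, nk = 32,
                               tau_short = 1.5, tau_long = 3.5,
                               brightness = 120, dwell = 500, seed = 11,
                               dark_rate = 100, nj = 32) {
  saxis <- spectral_axis(nk, 500, 760)
  taxis <- time_axis(nj, 50 / nj)
  A <- fluorophore("short", 560, 30, tau_short, brightness)
  B <- fluorophore("long", 690, 30, tau_long, brightness)
  wA <- matrix(0, rows, cols); wA[, seq_len(cols %/% 2)] <- 1
  wB <- matrix(0, rows, cols); wB[, (cols %/% 2 + 1):cols] <- 1
  scene <- phantom_scene(list(A, B), list(wA, wB))
  sensor <- sensor_config(dark_count_rate = dark_rate)
  params <- sim_params(dwell_time = dwell, seed = seed, chained = TRUE)
  list(scene = scene, sensor = sensor, saxis = saxis, taxis = taxis,
       params = params,
       cube = simulate_cube(scene, sensor, saxis, taxis, params),
       region_short = wA > 0, region_long = wB > 0)
}

# brute-force windowed-mean oracle for the moving spectral filter
moving_mean_oracle <- function(v, width) {
  n <- length(v)
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  vapply(seq_len(n), function(k) mean(v[max(1, k - left):min(n, k + right)]),
         numeric(1))
}

# dense 3-D grid-search least-squares oracle over (A, tau, B), same tail
# objective as the analytic fitter but minimized by exhaustive enumeration
grid_search_rss <- function(decay, taxis,
                            n_tau = 240, n_a = 80, n_b = 40) {
  t_all <- bin_times(taxis)
  peak <- which.max(decay)
  y <- decay[peak:length(decay)]
  tt <- t_all[peak:length(decay)] - t_all[peak]
  taus <- exp(seq(log(taxis$bin_width / 20), log(taxis$laser_period),
                  length.out = n_tau))
  As <- seq(0, 2 * max(y), length.out = n_a)
  Bs <- seq(0, max(y), length.out = n_b)
  syy <- sum(y^2); sy <- sum(y); n <- length(y)
  best <- Inf
  for (tau in taus) {
    x <- exp(-tt / tau)
    sxx <- sum(x^2); sx <- sum(x); sxy <- sum(x * y)
    # RSS(A, B) from the five sufficient sums, over the full (A, B) grid
    rss <- outer(As^2 * sxx - 2 * As * sxy, numeric(n_b) + 1) +
      outer(2 * As * sx, Bs) +
      matrix(rep(n * Bs^2 - 2 * Bs * sy, each = n_a), n_a, n_b) + syy
    best <- min(best, min(rss))
  }
  best
}

# residual sum of squares of a fitted decay_fit on the same tail objective
fit_rss <- function(fit, decay, taxis) {
  t_all <- bin_times(taxis)
  peak <- which.max(decay)
  y <- decay[peak:length(decay)]
  tt <- t_all[peak:length(decay)] - t_all[peak]
  sum((y - fit$amplitude * exp(-tt / fit$tau) - fit$background)^2)
}
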