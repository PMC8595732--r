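test_that("channel intensity equals exhaustive summation over time bins", {
  zero <- flim_cube(array(0L, c(2, 2, 3, 4)), spectral_axis(3), time_axis(4, 1))
  expect_true(all(channel_intensity(zero) == 0))

  single <- array(0L, c(2, 2, 3, 4)); single[2, 1, 3, 2] <- 1L
  ci <- channel_intensity(flim_cube(single, spectral_axis(3), time_axis(4, 1)))
  expect_equal(sum(ci), 1)
  expect_equal(ci[2, 1, 3], 1)

  cube <- random_cube(seed = 12)
  ci <- channel_intensity(cube)
  for (r in 1:4) for (c in 1:4) for (k in 1:8)
    expect_equal(ci[r, c, k], sum(cube$counts[r, c, k, ]))
  # summing again over channels gives the panchromatic intensity image
  expect_equal(rowSums(ci, dims = 2), rowSums(cube$counts, dims = 2))
})

test_that("moving spectral mean matches the brute-force windowed oracle", {
  expect_equal(moving_spectral_mean(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(moving_spectral_mean(rep(7, 64), 8), rep(7, 64))

  ramp <- 0:511
  expect_equal(moving_spectral_mean(ramp, 8), moving_mean_oracle(ramp, 8))
  set.seed(33)
  for (width in c(2, 3, 8, 15)) {
    v <- rnorm(40)
    expect_equal(moving_spectral_mean(v, width), moving_mean_oracle(v, width))
  }
  # matrix form smooths each row independently
  m <- rbind(ramp[1:20], rev(ramp[1:20]))
  sm <- moving_spectral_mean(m, 5)
  expect_equal(sm[1, ], moving_mean_oracle(ramp[1:20], 5))
  expect_equal(sm[2, ], moving_mean_oracle(rev(ramp[1:20]), 5))

  expect_error(moving_spectral_mean(1:4, 5), "exceeds")
})

test_that("threshold mask applies both rules and is monotone", {
  pol <- threshold_policy(10, 200, smoothing_mode = "off")

  # the 200-count floor: 199 fails, 200 passes (zero background)
  i <- array(c(199, 200), c(1, 2, 1))
  m <- threshold_mask(i, 0, pol)
  expect_identical(as.vector(m), c(FALSE, TRUE))

  # brute-force comparison on a random grid with per-channel background
  set.seed(14)
  intensity <- array(rexp(4 * 5 * 6, 1 / 300), c(4, 5, 6))
  bg <- runif(6, 0, 40)
  m <- threshold_mask(intensity, bg, pol)
  for (r in 1:4) for (c in 1:5) for (k in 1:6)
    expect_identical(m[r, c, k],
                     intensity[r, c, k] >= 10 * bg[k] && intensity[r, c, k] >= 200)

  # monotonicity: tightening either rule never adds entries
  for (mult in c(12, 20)) for (floor_ in c(250, 400)) {
    m2 <- threshold_mask(intensity, bg, threshold_policy(mult, floor_,
                                                         smoothing_mode = "off"))
    expect_true(all(m >= m2))
  }

  # degenerate zero thresholds admit zero intensity (>= holds at 0)
  m0 <- threshold_mask(array(0, c(1, 1, 1)), 0,
                       threshold_policy(1, 0, smoothing_mode = "off"))
  expect_true(m0[1, 1, 1])
  # NA intensity (masked channel) never qualifies
  expect_false(threshold_mask(array(NA_real_, c(1, 1, 1)), 0, pol)[1, 1, 1])
})

test_that("single-exponential fitting recovers exact and degenerate decays", {
  ta <- time_axis(32, 50 / 32)
  t <- bin_times(ta)

  # exact-model input recovers tau to 1e-6 relative, with zero background
  f <- fit_single_exponential(1000 * exp(-t / 2), ta)
  expect_true(f$valid)
  expect_equal(f$tau, 2, tolerance = 1e-6)
  expect_equal(f$background, 0, tolerance = 1e-4)

  # with a constant offset
  f2 <- fit_single_exponential(500 * exp(-t / 3.5) + 7, ta)
  expect_equal(f2$tau, 3.5, tolerance = 1e-6)
  expect_equal(f2$background, 7, tolerance = 1e-3)

  # pure background: no decay component, flagged invalid with tau 0
  f3 <- fit_single_exponential(rep(5, 32), ta)
  expect_false(f3$valid)
  expect_identical(f3$tau, 0)

  # all-zero decay is an invalid result, not an exception
  f4 <- fit_single_exponential(rep(0, 32), ta)
  expect_false(f4$valid)

  # fewer than 3 positive tail bins
  sparse <- rep(0, 32); sparse[30] <- 5; sparse[32] <- 3
  expect_false(fit_single_exponential(sparse, ta)$valid)

  expect_error(fit_single_exponential(rep(1, 10), ta), "does not match")
})

test_that("analytic fitter never loses to the dense grid-search oracle", {
  ta <- time_axis(16, 50 / 16)
  set.seed(77)
  n_worse <- 0
  for (i in 1:100) {
    tau <- runif(1, 0.5, 6)
    amp <- runif(1, 200, 2000)
    bg <- runif(1, 0, 10)
    p <- decay_bin_probabilities(tau, ta, irf_fwhm = 100)
    y <- rpois(16, amp * p + bg)
    fit <- fit_single_exponential(y, ta)
    if (!fit$valid) next
    rss_fit <- fit_rss(fit, y, ta)
    rss_grid <- grid_search_rss(y, ta)
    expect_lte(rss_fit, rss_grid * (1 + 1e-9) + 1e-6)
    if (rss_fit > rss_grid) n_worse <- n_worse + 1
  }
  expect_lte(n_worse, 0)
})

test_that("fitted lifetime bias and spread shrink as the photon budget grows", {
  ta <- time_axis(32, 50 / 32)
  # model-exact (no IRF) Poisson decays: the statistical bias vanishes and the
  # spread contracts as the photon budget grows
  p <- decay_bin_probabilities(2, ta, irf_fwhm = 0)
  err <- sapply(c(500, 5000, 50000), function(n_photons) {
    set.seed(n_photons)
    taus <- replicate(60, fit_single_exponential(rpois(32, n_photons * p), ta)$tau)
    taus <- taus[taus > 0]
    c(bias = mean(taus) - 2, se = stats::sd(taus) / sqrt(length(taus)),
      sd = stats::sd(taus))
  })
  # bias indistinguishable from 0 at every budget, so its magnitude bound
  # (3 SE) contracts with the spread as the budget grows
  expect_true(all(abs(err["bias", ]) <= 3 * err["se", ]))
  expect_true(all(diff(err["sd", ]) < 0))
  expect_lt(abs(err["bias", 3]) + 3 * err["se", 3], 0.01)

  # with a 100 ps IRF the pure-exponential tail fit keeps a small systematic
  # bias floor (the peak bin contains the instrument rise); it stays below 3%
  p_irf <- decay_bin_probabilities(2, ta, irf_fwhm = 100)
  f <- fit_single_exponential(5e5 * p_irf, ta)   # noise-free limit
  expect_lt(abs(f$tau - 2) / 2, 0.03)
})

test_that("cube fitting masks, fits, and zeroes exactly as the policy says", {
  # fully sub-threshold cube: no fits attempted, tau map all zero
  dim4 <- c(3, 3, 4, 8)
  low <- flim_cube(array(1L, dim4), spectral_axis(4), time_axis(8, 50 / 8),
                   dwell_time = 500)
  ltc0 <- fit_cube(low, 0, threshold_policy(10, 200, smoothing_mode = "off"))
  expect_equal(ltc0$n_attempted, 0)
  expect_true(all(ltc0$tau_map == 0))

  # the full-geometry candidate count the thresholding protects against
  expect_equal(candidate_fit_count(256, 256, 512), 33554432)

  # two-region phantom: tau support equals the threshold mask support, and
  # per-region medians recover the simulated lifetimes within 5%
  ph <- two_region_phantom(rows = 16, cols = 16, nk = 16)
  corr <- subtract_dark(ph$cube, ph$sensor)
  bg <- expected_background_level(ph$sensor, 500, 16)
  pol <- threshold_policy(10, 2000, smoothing_mode = "off")
  ltc <- fit_cube(corr, bg, pol)
  mask <- threshold_mask(ltc$intensity_map, bg, pol)
  expect_identical(ltc$tau_map > 0, mask)
  expect_equal(ltc$n_attempted, sum(mask))
  ts <- ltc$tau_map[rep(ph$region_short, 16)]
  tl <- ltc$tau_map[rep(ph$region_long, 16)]
  expect_lt(abs(median(ts[ts > 0]) - 1.5) / 1.5, 0.05)
  expect_lt(abs(median(tl[tl > 0]) - 3.5) / 3.5, 0.05)
})

test_that("edges-only smoothing rescues low-signal channels and full mode is global", {
  # constant cube: smoothing in any mode must not change a constant spectrum
  v <- array(100, c(2, 2, 6, 4))
  cc <- corrected_cube(v, spectral_axis(6), time_axis(4, 1), dwell_time = 500)
  for (mode in c("off", "edges_only", "full")) {
    ltc <- fit_cube(cc, 0, threshold_policy(1, 0, smoothing_width = 3,
                                            smoothing_mode = mode))
    expect_equal(ltc$intensity_map, array(400, c(2, 2, 6)))
  }

  # a spectrum with weak edges: edges_only changes only the weak channels
  set.seed(41)
  v2 <- array(0, c(2, 2, 8, 4))
  v2[, , 3:6, ] <- 200                      # strong core: 800 counts/channel
  v2[, , c(1, 2, 7, 8), ] <- 10             # weak limits: 40 counts/channel
  cc2 <- corrected_cube(v2, spectral_axis(8), time_axis(4, 1), dwell_time = 500)
  pol_e <- threshold_policy(1, 100, smoothing_width = 3, smoothing_mode = "edges_only")
  ltc_e <- fit_cube(cc2, 0, pol_e)
  pol_f <- threshold_policy(1, 100, smoothing_width = 3, smoothing_mode = "full")
  ltc_f <- fit_cube(cc2, 0, pol_f)
  # strong channels untouched by edges_only wherever their window is strong
  expect_equal(ltc_e$intensity_map[, , 4], matrix(800, 2, 2))
  # but changed by full smoothing at the core boundary
  expect_false(isTRUE(all.equal(ltc_f$intensity_map[, , 3], matrix(800, 2, 2))))
  # weak edge channels gain signal from the adjacent strong ones
  expect_gt(ltc_e$intensity_map[1, 1, 2], 40)
})

test_that("lifetime histograms count only valid pixels at one wavelength", {
  ph <- two_region_phantom(rows = 12, cols = 12, nk = 16)
  corr <- subtract_dark(ph$cube, ph$sensor)
  ltc <- fit_cube(corr, expected_background_level(ph$sensor, 500, 16),
                  threshold_policy(10, 2000, smoothing_mode = "off"))
  # a channel where both bands are dark: empty histogram
  dark_ch <- wavelength_to_channel(ph$saxis, 755)
  h0 <- lifetime_histogram(ltc, dark_ch, seq(0, 10, by = 0.25))
  expect_equal(sum(h0$counts), 0)

  # each band's peak channel: total mass = number of valid pixels, single mode
  for (spec in list(list(nm = 560, tau = 1.5), list(nm = 690, tau = 3.5))) {
    ch <- wavelength_to_channel(ph$saxis, spec$nm)
    h <- lifetime_histogram(ltc, ch, seq(0, 10, by = 0.25))
    expect_equal(sum(h$counts), sum(ltc$tau_map[, , ch] > 0))
    expect_gt(sum(h$counts), 0)
    peak_mid <- h$mids[which.max(h$counts)]
    expect_lt(abs(peak_mid - spec$tau), 0.25)  # within one histogram bin
  }

  # single valid pixel lands in the bin containing its lifetime
  one <- ltc; one$tau_map[] <- 0; one$tau_map[3, 3, 2] <- 2
  h1 <- lifetime_histogram(one, 2, seq(0, 10, by = 0.5))
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$counts[findInterval(2, seq(0, 10, by = 0.5))], 1L)

  expect_error(lifetime_histogram(ltc, 99, seq(0, 10, 1)), "out of range")
})

test_that("ROI spectral-lifetime summaries average valid pixels per channel", {
  ph <- two_region_phantom(rows = 12, cols = 12, nk = 16)
  corr <- subtract_dark(ph$cube, ph$sensor)
  ltc <- fit_cube(corr, expected_background_level(ph$sensor, 500, 16),
                  threshold_policy(10, 2000, smoothing_mode = "off"))

  # one-pixel ROI reproduces that pixel's spectral profile
  roi1 <- matrix(FALSE, 12, 12); roi1[2, 3] <- TRUE
  pr1 <- roi_mean_spectral_lifetime(ltc, roi1)
  ch <- which(ltc$tau_map[2, 3, ] > 0)
  expect_equal(pr1$mean_tau_ns[ch], ltc$tau_map[2, 3, ch])
  expect_true(all(is.na(pr1$mean_tau_ns[-ch])))   # missing, never zero

  # identical ROIs difference to exactly zero where defined
  d0 <- roi_difference(pr1, pr1)
  expect_true(all(d0$delta_tau_ns[!is.na(d0$delta_tau_ns)] == 0))

  # two-region phantom: per-channel means within 5% of each region's tau
  ps <- roi_mean_spectral_lifetime(ltc, ph$region_short)
  pl <- roi_mean_spectral_lifetime(ltc, ph$region_long)
  ok_s <- !is.na(ps$mean_tau_ns) & ps$n_valid > 20
  ok_l <- !is.na(pl$mean_tau_ns) & pl$n_valid > 20
  expect_gt(sum(ok_s), 0); expect_gt(sum(ok_l), 0)
  expect_true(all(abs(ps$mean_tau_ns[ok_s] - 1.5) / 1.5 < 0.05))
  expect_true(all(abs(pl$mean_tau_ns[ok_l] - 3.5) / 3.5 < 0.05))

  expect_error(roi_mean_spectral_lifetime(ltc, matrix(FALSE, 12, 12)), "empty")

  # CSV export round-trips the profile
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_csv(ps, path)
  back <- utils::read.csv(path)
  expect_equal(back$mean_tau_ns, ps$mean_tau_ns)

  # ROI masks load from grayscale label images
  mpath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(ifelse(ph$region_short, 1, 0), mpath)
  expect_identical(read_roi_mask(mpath), ph$region_short)
})
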