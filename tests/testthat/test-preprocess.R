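test_that("filterbank tiling matches the closed-form band count", {
  fb <- build_filterbank(4, 40, 4, 2)
  expect_equal(nrow(fb$bands), 17)
  expect_equal(unname(fb$bands[1, ]), c(4, 8))
  expect_equal(unname(fb$bands[17, ]), c(36, 40))
  expect_equal(nrow(build_filterbank(4, 8, 4, 2)$bands), 1)
  expect_equal(nrow(build_filterbank(8, 30, 4, 2)$bands), 10)
  # property: count formula over a parameter grid, bands overlap by width-step
  for (fmin in c(2, 4)) for (width in c(2, 4, 6)) for (step in c(1, 2)) {
    fb <- build_filterbank(fmin, 40, width, step)
    expect_equal(nrow(fb$bands), floor((40 - fmin - width) / step) + 1)
    if (nrow(fb$bands) > 1)
      expect_equal(as.numeric(fb$bands[1, 2] - fb$bands[2, 1]), width - step)
  }
  expect_error(build_filterbank(4, 40, -1, 2), "positive")
  expect_error(build_filterbank(30, 32, 4, 2), "exceed")
})

test_that("band-pass is zero-phase with correct pass/stop behavior", {
  fs <- 250
  tt <- (0:2499) / fs
  x <- sin(2 * pi * 10 * tt)
  attr(x, "sample_rate") <- fs
  inb <- bandpass(x, c(8, 12))
  mid <- 500:2000
  expect_equal(sqrt(mean(inb[mid]^2)), sqrt(0.5), tolerance = 0.05)
  # zero phase: peak cross-correlation at zero lag
  cc <- ccf(as.numeric(inb[mid]), x[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  out <- bandpass(x, c(20, 24))
  expect_lt(sqrt(mean(out[mid]^2)), 0.05 * sqrt(0.5))
  expect_error(bandpass(x, c(120, 130)), "Nyquist")
})

test_that("filter-bank band powers of white noise integrate to the covered range", {
  set.seed(7)
  fs <- 250
  x <- rnorm(fs * 40)
  attr(x, "sample_rate") <- fs
  fb <- build_filterbank(4, 40, 4, 2)
  # overlapping 4 Hz bands stepped by 2 Hz double-cover the interior, so
  # sum(band powers)/2 approximates the [4, 40] spectral mass
  bp <- vapply(seq_len(nrow(fb$bands)), function(b)
    mean(bandpass(x, fb$bands[b, ])^2), numeric(1))
  target <- mean(bandpass(x, c(4, 40))^2)
  expect_equal(sum(bp) / 2, target, tolerance = 0.15)
})

test_that("surface Laplacian rejects common mode, is linear and preserves isolated sources", {
  ts <- noise_trials(n_per_class = 3, C = 10, S = 100, seed = 9)
  ts$montage <- montage_bci2a(strip10)
  dimnames(ts$data)[[2]] <- strip10
  # common-mode rejection: adding a constant offset changes nothing
  ts_off <- ts
  ts_off$data <- ts$data + 5
  expect_equal(surface_laplacian(ts_off)$data, surface_laplacian(ts)$data,
               tolerance = 1e-12)
  # linearity
  a <- ts; b <- ts
  set.seed(10)
  b$data <- array(rnorm(length(ts$data)), dim(ts$data))
  lin <- ts
  lin$data <- 2 * a$data + 3 * b$data
  expect_equal(surface_laplacian(lin)$data,
               2 * surface_laplacian(a)$data + 3 * surface_laplacian(b)$data,
               tolerance = 1e-10)
  # a single active channel among silent neighbors passes through unchanged
  sil <- ts
  sil$data[] <- 0
  sil$data[, 2, ] <- ts$data[, 2, ]   # C3 active only
  expect_equal(surface_laplacian(sil)$data[, 2, ], sil$data[, 2, ])
})

test_that("Laplacian sharpens focal sources relative to broad ones", {
  fs <- 100; S <- 200
  src <- sin(2 * pi * 10 * (0:(S - 1)) / fs)
  mk <- function(weights) {
    dat <- array(0, c(4, 10, S))
    for (ci in 1:10) for (n in 1:4) dat[n, ci, ] <- weights[ci] * src
    eeg_trial_set(dat, rep(c("a", "b"), 2), fs, montage_bci2a(strip10))
  }
  # spatial profiles of equal peak power centered on C3, narrow vs wide
  m <- montage_bci2a(strip10)
  d2 <- (m$x - m$x[2])^2 + (m$y - m$y[2])^2
  focal <- exp(-d2 / 0.05^2)
  broad <- exp(-d2 / 0.8^2)
  pk <- function(ts) {
    pre <- max(apply(ts$data[1, , ]^2, 1, mean))
    l <- surface_laplacian(ts)
    max(apply(l$data[1, , ]^2, 1, mean)) / pre
  }
  expect_gt(pk(mk(focal)), pk(mk(broad)))
})

test_that("window grids follow both endpoint conventions", {
  g <- make_window_grid(NA, 0, T = 7, fs = 250, mode = "per-sample")
  expect_equal(length(g$positions), 1751)
  g2 <- make_window_grid(2, 0, T = 6, fs = 100)
  expect_equal(g2$positions, c(0, 2, 4))
  g3 <- make_window_grid(1, 0.9, T = 7, fs = 250)
  expect_equal(length(g3$positions), 61)   # floor((7-1)/0.1) + 1
  expect_true(all(g3$positions + g3$tau <= 7 + 1e-9))
  expect_true(all(diff(g3$positions) > 0))
  expect_error(make_window_grid(8, 0, T = 7, fs = 250), "exceeds")
})

test_that("the interval registry matches the trial paradigm", {
  iv <- default_intervals()
  expect_equal(iv$dT3, c(2.6, 4.6))
  expect_equal(iv$dT0, c(0.5, 1.5))
  expect_equal(iv$dT1, c(0, 2))
  for (v in iv) expect_true(v[1] >= 0 && v[2] <= 7 && v[1] < v[2])
  # reference precedes the cue onset at 2 s
  expect_lte(iv$dT0[2], 2)
})

test_that("re-referencing zeroes the reference channel and shifts the rest", {
  ts <- noise_trials(C = 10, S = 50, seed = 12)
  ts$montage <- montage_bci2a(strip10)
  dimnames(ts$data)[[2]] <- strip10
  rr <- rereference(ts, "Cz")
  expect_true(all(abs(rr$data[, 4, ]) < 1e-12))
  expect_equal(rr$data[, 2, ], ts$data[, 2, ] - ts$data[, 4, ])
})
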