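test_that("Morlet coefficients track phase and envelope of analytic signals", {
  fs <- 250; S <- 1000; f0 <- 10
  tt <- (0:(S - 1)) / fs
  ts <- signal_trials(function(ci, tt, i) cos(2 * pi * f0 * tt),
                      n_trials = 4, C = 2, S = S, fs = fs)
  co <- wavelet_coefficients(ts, f0, cycles = 7)
  valid <- which(attr(co, "valid"))
  # phase advances 2 pi f per second
  ph <- Arg(co[1, 1, valid])
  dph <- diff(ph); dph <- dph[abs(dph) < pi]      # unwrap
  expect_equal(mean(dph) * fs / (2 * pi), f0, tolerance = 0.01 * f0)
  # unit-amplitude sinusoid -> unit magnitude
  expect_equal(mean(Mod(co[1, 1, valid])), 1, tolerance = 0.02)
  # amplitude-modulated sinusoid: |coefficient| proportional to envelope
  env <- 1 + 0.5 * sin(2 * pi * 0.5 * tt)
  ts2 <- signal_trials(function(ci, tt, i) env * cos(2 * pi * f0 * tt),
                       n_trials = 4, C = 1, S = S, fs = fs)
  co2 <- wavelet_coefficients(ts2, f0, cycles = 7)
  expect_gt(cor(Mod(co2[1, 1, valid]), env[valid]), 0.99)
  # boundary contract and support guard
  expect_false(all(attr(co, "valid")))
  expect_error(wavelet_coefficients(ts, 0.3, cycles = 7), "support")
  expect_error(wavelet_coefficients(ts, 200, cycles = 7), "Nyquist")
  expect_error(wavelet_coefficients(ts, f0, cycles = 2), "cycles")
})

test_that("wPLI attains its analytic limits", {
  set.seed(13)
  ph <- runif(200, 0, 2 * pi)
  ca <- exp(1i * outer(ph, rep(1, 20)))
  # constant pi/2 lag -> 1
  cb <- exp(1i * outer(ph + pi / 2, rep(1, 20)))
  expect_equal(wpli_pair(ca, cb, average_samples = TRUE), 1, tolerance = 1e-12)
  # constant zero lag -> 0
  expect_equal(wpli_pair(ca, ca * 2, average_samples = TRUE), 0)
  # volume-conduction surrogate: shared source, no lag, different gains
  mix1 <- 2 * ca + 0.1 * exp(1i * matrix(runif(4000, 0, 2 * pi), 200))
  mix2 <- 0.7 * ca + 0.1 * exp(1i * matrix(runif(4000, 0, 2 * pi), 200))
  expect_lt(wpli_pair(mix1, mix2, average_samples = TRUE), 0.15)
  expect_error(wpli_pair(ca[1, , drop = FALSE], cb[1, , drop = FALSE]), "trials")
  expect_warning(wpli_pair(ca[1:5, ], cb[1:5, ]), "unstable")
})

test_that("the independent-phase null keeps wPLI small and variance shrinks with trials", {
  set.seed(14)
  null_wpli <- function(n) {
    pa <- matrix(runif(n, 0, 2 * pi), n)
    pb <- matrix(runif(n, 0, 2 * pi), n)
    wpli_pair(exp(1i * pa), exp(1i * pb))
  }
  v200 <- replicate(300, null_wpli(200))
  # the null estimator is approx |N(0, sqrt(.5/n))| / (2/pi): median ~ 0.053,
  # 99th percentile ~ 0.20 at n = 200
  expect_lt(median(v200), 0.08)
  expect_gt(mean(v200 < 0.2), 0.95)
  # convergence on the constant-lag-with-noise model
  est <- function(n) {
    ph <- runif(n, 0, 2 * pi)
    ca <- exp(1i * ph) + 0.8 * exp(1i * runif(n, 0, 2 * pi))
    cb <- exp(1i * (ph + pi / 3)) + 0.8 * exp(1i * runif(n, 0, 2 * pi))
    wpli_pair(matrix(ca), matrix(cb))
  }
  expect_lt(var(replicate(100, est(160))), var(replicate(100, est(20))))
})

test_that("connectivity dynamics recover a planted lagged pair and respect bounds", {
  sp <- small_spec(n_trials = 25, seed = 15,
                   coupling = list(coupling_plant(c("C3", "C4"), c(8, 12),
                                                  c(2.6, 4.6), pi / 2, 1)))
  ts <- generate_subject(sp, 1)
  fb <- build_filterbank(8, 12, 4, 2)
  grid <- make_window_grid(0.1, 0, T = 7, fs = ts$sample_rate)
  cd <- connectivity_dynamics(ts, fb, grid, reference = "Cz")
  expect_true(all(cd$phi >= 0 & cd$phi <= 1))
  # Cz excluded from the pair set after re-referencing
  expect_false("Cz" %in% cd$channels)
  expect_equal(nrow(cd$pairs), choose(9, 2))
  v <- which((cd$pairs$a == "C3" & cd$pairs$b == "C4") |
               (cd$pairs$a == "C4" & cd$pairs$b == "C3"))
  sel <- cd$positions >= 2.8 & cd$positions <= 4.2
  base <- cd$positions >= 0.5 & cd$positions <= 1.5
  expect_gt(mean(cd$phi[v, 1, sel, 1]), 0.9)
  expect_lt(mean(cd$phi[v, 1, base, 1]), 0.5)
})

test_that("baseline normalization highlights task-locked coupling", {
  sp <- small_spec(n_trials = 25, seed = 16,
                   coupling = list(coupling_plant(c("C3", "C4"), c(8, 12),
                                                  c(2.6, 4.6), pi / 2, 1)))
  ts <- generate_subject(sp, 1)
  fb <- build_filterbank(8, 12, 4, 2)
  grid <- make_window_grid(0.1, 0, T = 7, fs = ts$sample_rate)
  cd <- baseline_normalize(connectivity_dynamics(ts, fb, grid), c(0.5, 1.5))
  v <- which((cd$pairs$a == "C3" & cd$pairs$b == "C4") |
               (cd$pairs$a == "C4" & cd$pairs$b == "C3"))
  sel <- cd$positions >= 2.8 & cd$positions <= 4.2
  expect_gt(mean(cd$phi_norm[v, 1, sel, 1]), 2)
  # stationary (null) pairs stay near 1 on average under division
  others <- setdiff(seq_len(nrow(cd$pairs)), v)
  expect_equal(median(cd$phi_norm[others, 1, sel, 1]), 1, tolerance = 0.6)
  expect_error(baseline_normalize(cd, c(10, 12)), "baseline")
})

test_that("node strength marginalizes pairs symmetrically", {
  sp <- small_spec(n_trials = 25, seed = 17,
                   coupling = list(coupling_plant(c("C3", "C4"), c(8, 12),
                                                  c(2.6, 4.6), pi / 2, 1)))
  ts <- generate_subject(sp, 1)
  fb <- build_filterbank(8, 12, 4, 2)
  grid <- make_window_grid(0.1, 0, T = 7, fs = ts$sample_rate)
  cd <- connectivity_dynamics(ts, fb, grid, reference = "Cz")
  ns <- node_strength(cd)
  expect_true(all(ns$theta >= 0 & ns$theta <= 1, na.rm = TRUE))
  sel <- which(cd$positions >= 2.8 & cd$positions <= 4.2)
  s <- rowMeans(ns$phi_hat[, 1, sel, 1])
  top2 <- names(sort(s, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("C3", "C4"))
  # the two coupled endpoints carry comparable strength
  expect_equal(s[["C3"]], s[["C4"]], tolerance = 0.25 * s[["C3"]])
  # manual marginal for one channel equals the reported strength
  vidx <- which(cd$pairs$a == "C3" | cd$pairs$b == "C3")
  expect_equal(ns$phi_hat["C3", 1, sel[1], 1],
               sum(cd$phi[vidx, 1, sel[1], 1]), tolerance = 1e-12)
})
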