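# shared fixture builders: everything is generated in code at test time

# 10-channel sensorimotor strip used by the reduced-size cohorts
strip10 <- c("C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP3", "CPz", "CP4")

# reduced synthetic spec: small C and fs keep the suite fast while retaining
# the trial paradigm (7 s, two classes, plant in the motor-imagery interval)
small_spec <- function(n_subjects = 1, n_trials = 20, seed = 1,
                       erd = list(), coupling = list(), jitter = 0,
                       fs = 128, snr_db = 20) {
  synth_spec(n_subjects = n_subjects, n_trials_per_class = n_trials,
             n_channels = 10, sample_rate = fs, trial_duration = 7,
             montage = montage_bci2a(strip10),
             erd_plants = erd, coupling_plants = coupling,
             subject_jitter = jitter, snr_db = snr_db, seed = seed)
}

# white-noise trial set with a plain grid montage
noise_trials <- function(n_per_class = 10, C = 4, S = 200, fs = 100, seed = 1,
                         sd = 1) {
  set.seed(seed)
  dat <- array(rnorm(2 * n_per_class * C * S, sd = sd), c(2 * n_per_class, C, S))
  eeg_trial_set(dat, rep(c("a", "b"), each = n_per_class), fs, montage_grid(C))
}

# deterministic trial set holding one multichannel signal repeated per trial
signal_trials <- function(make_channel, n_trials = 4, C = 2, S = 400, fs = 100,
                          labels = rep(c("a", "b"), length.out = n_trials)) {
  tt <- (seq_len(S) - 1) / fs
  dat <- array(0, c(n_trials, C, S))
  for (i in seq_len(n_trials)) for (ci in seq_len(C))
    dat[i, ci, ] <- make_channel(ci, tt, i)
  eeg_trial_set(dat, labels, fs, montage_grid(C))
}

# mean band power of one channel/label over a sample window
band_power <- function(ts, band, channel, label, window) {
  tb <- bandpass(ts, band)
  sr <- migroup:::sample_range(window, ts$sample_rate, dim(tb$data)[3])
  X <- tb$data[tb$labels == label, match(channel, channels(tb)), sr[1]:sr[2], drop = FALSE]
  mean(X^2)
}

# brute-force Rayleigh-quotient maximum over the unit sphere: exhaustive
# hyperspherical-angle grid with coarse-to-fine refinement (no gradients,
# independent of the eigen solution). RQ is antipodally symmetric so the
# angle box [0, pi]^(C-1) covers the sphere.
rq_sphere_max <- function(S1, S2, n_per_dim = 14, rounds = 4) {
  C <- ncol(S1)
  Sc <- S1 + S2
  angles_to_w <- function(A) {           # rows of A = angle tuples
    n <- nrow(A); W <- matrix(1, n, C)
    for (j in seq_len(C - 1)) {
      W[, j] <- W[, j] * cos(A[, j])
      for (k in (j + 1):C) W[, k] <- W[, k] * sin(A[, j])
    }
    W
  }
  eval_grid <- function(lo, hi) {
    grids <- lapply(seq_len(C - 1), function(j) seq(lo[j], hi[j], length.out = n_per_dim))
    A <- as.matrix(expand.grid(grids))
    W <- angles_to_w(A)
    J <- rowSums((W %*% S1) * W) / rowSums((W %*% Sc) * W)
    list(A = A, J = J)
  }
  # coarse pass over the full box, then independent refinement around the
  # top candidates (the coarse argmax alone can sit in the wrong basin)
  g <- eval_grid(rep(0, C - 1), rep(pi, C - 1))
  span0 <- pi / (n_per_dim - 1)
  top <- order(g$J, decreasing = TRUE)[seq_len(min(8, length(g$J)))]
  best <- max(g$J)
  for (i in top) {
    lo <- pmax(0, g$A[i, ] - span0); hi <- pmin(pi, g$A[i, ] + span0)
    for (r in seq_len(rounds)) {
      gr <- eval_grid(lo, hi)
      j <- which.max(gr$J)
      best <- max(best, gr$J[j])
      span <- (hi - lo) / (n_per_dim - 1)
      lo <- pmax(0, gr$A[j, ] - span); hi <- pmin(pi, gr$A[j, ] + span)
    }
  }
  best
}
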