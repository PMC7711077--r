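#' Specification of a synthetic motor-imagery cohort
#'
#' Describes a multi-subject two-class cohort of oscillatory EEG trials with
#' planted, fully known ground truth: band-limited rhythms whose power is
#' modulated class-conditionally inside chosen time intervals (emulating
#' event-related desynchronization over the sensorimotor strip), phase-lagged
#' inter-channel coupling, and a 1/f^alpha Gaussian background. Every
#' downstream stage of the package can be validated against this truth.
#'
#' The defaults mirror the standard two-class paradigm the package targets:
#' 9 subjects, 22 channels, 250 Hz, 7 s trials, 72 trials per class.
#'
#' @param n_subjects cohort size M.
#' @param n_trials_per_class trials per class per subject.
#' @param n_channels channel count C.
#' @param sample_rate Hz.
#' @param trial_duration trial span T in seconds.
#' @param montage a montage data.frame, or NULL to pick [montage_bci2a()]
#'   when `n_channels == 22` and [montage_grid()] otherwise.
#' @param erd_plants list of [erd_plant()] entries.
#' @param coupling_plants list of [coupling_plant()] entries.
#' @param subject_jitter log-normal sigma of the per-subject multiplicative
#'   effect-size gain (0 = all subjects identical).
#' @param noise_exponent alpha of the 1/f^alpha background slope.
#' @param snr_db in-band oscillation-to-background power ratio in dB: planted
#'   rhythm power relative to the background power falling inside the
#'   rhythm's own band. The default 20 dB emulates a clear narrowband mu/beta
#'   peak standing well above the 1/f floor.
#' @param labels the two class labels.
#' @param seed master integer seed; the cohort is a pure function of
#'   (spec, seed).
#'
#' @return An object of class `synth_spec`.
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
synth_spec <- function(n_subjects = 9, n_trials_per_class = 72, n_channels = 22,
                       sample_rate = 250, trial_duration = 7, montage = NULL,
                       erd_plants = list(), coupling_plants = list(),
                       subject_jitter = 0.2, noise_exponent = 1, snr_db = 20,
                       labels = c("left", "right"), seed = 1L) {
  if (is.null(montage)) {
    montage <- if (n_channels == 22L) montage_bci2a() else montage_grid(n_channels)
  }
  if (nrow(montage) != n_channels)
    stop("montage has ", nrow(montage), " channels, spec asks for ", n_channels)
  if (length(labels) != 2L || anyDuplicated(labels))
    stop("`labels` must be two distinct values")
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels),
         sample_rate = sample_rate, trial_duration = trial_duration,
         montage = montage, erd_plants = erd_plants,
         coupling_plants = coupling_plants,
         subject_jitter = subject_jitter, noise_exponent = noise_exponent,
         snr_db = snr_db, labels = labels, seed = as.integer(seed)),
    class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

#' Planted class-conditional rhythm power modulation
#'
#' Inside `interval` and for trials of class `label`, the amplitude of the
#' planted rhythm on `channel` is scaled by `sqrt(1 + depth)` so that its
#' band power changes by exactly the fraction `depth` relative to the rest
#' of the trial (negative depth = desynchronization).
#'
#' @param channel channel name.
#' @param band `c(low, high)` Hz; the rhythm sits at the band center.
#' @param interval `c(start, end)` seconds within the trial.
#' @param depth fractional power change, `depth >= -1`.
#' @param label class showing the modulation (the other class keeps a flat
#'   envelope, making the channel discriminative).
#' @return a list describing the plant.
#' @export
erd_plant <- function(channel, band, interval, depth, label = "left") {
  list(type = "erd", channel = channel, band = band, interval = interval,
       depth = depth, label = label)
}

#' Planted phase-lagged inter-channel coupling
#'
#' Both channels of `pair` receive a rhythm at the band center inside
#' `interval`; the second channel's rhythm is the first's shifted by
#' `phase_lag`, mixed with an independent oscillator weighted
#' `(1 - strength)`. At `strength = 1` the phase difference is constant and
#' the weighted phase lag index of the pair approaches 1.
#'
#' @param pair character vector of two channel names.
#' @param band `c(low, high)` Hz.
#' @param interval `c(start, end)` seconds.
#' @param phase_lag radians.
#' @param strength coupling strength in `[0, 1]`.
#' @param label optional class restriction (NULL = both classes).
#' @return a list describing the plant.
#' @export
coupling_plant <- function(pair, band, interval, phase_lag, strength, label = NULL) {
  list(type = "coupling", pair = pair, band = band, interval = interval,
       phase_lag = phase_lag, strength = strength, label = label)
}

validate_synth_spec <- function(spec) {
  T <- spec$trial_duration
  for (p in spec$erd_plants) {
    if (p$depth < -1)
      stop("erd plant depth must be >= -1 (power cannot go below zero), got ", p$depth)
    if (p$interval[1] < 0 || p$interval[2] > T || p$interval[1] >= p$interval[2])
      stop("erd plant interval [", p$interval[1], ", ", p$interval[2],
           "] not inside the trial span [0, ", T, "]")
    if (!p$channel %in% spec$montage$channel)
      stop("erd plant channel not in montage: ", p$channel)
    if (!p$label %in% spec$labels)
      stop("erd plant label not one of the spec labels: ", p$label)
  }
  for (p in spec$coupling_plants) {
    if (p$interval[1] < 0 || p$interval[2] > T || p$interval[1] >= p$interval[2])
      stop("coupling plant interval outside the trial span")
    if (length(p$pair) != 2L || !all(p$pair %in% spec$montage$channel))
      stop("coupling plant pair must name two montage channels")
    if (p$strength < 0 || p$strength > 1)
      stop("coupling strength must lie in [0, 1]")
    if (!is.null(p$label) && !p$label %in% spec$labels)
      stop("coupling plant label not one of the spec labels")
  }
  invisible(spec)
}

# deterministic per-subject seed: fixed counter scheme off the master seed,
# stable under subject re-ordering
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.double(master_seed) + 104729 * as.double(subject_index)) %% 2147483647)
}

# unit-variance 1/f^alpha Gaussian noise, length n (column-wise for a matrix)
one_over_f_noise <- function(n, n_series, alpha) {
  x <- matrix(stats::rnorm(n * n_series), nrow = n)
  X <- stats::mvfft(x)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)            # two-sided frequency index
  shape <- c(0, k[-1]^(-alpha / 2))
  X <- X * shape
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

# fraction of unit-variance 1/f^alpha noise power falling inside [f1, f2] Hz
band_noise_fraction <- function(band, fs, n, alpha) {
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  w <- c(0, f[-1]^(-alpha))
  sum(w[f >= band[1] & f <= band[2]]) / sum(w)
}

# amplitude giving oscillation power = 10^(snr/10) x in-band background power
plant_amplitude <- function(band, spec, n) {
  pb <- band_noise_fraction(band, spec$sample_rate, n, spec$noise_exponent)
  sqrt(2 * 10^(spec$snr_db / 10) * pb)
}

#' Generate one synthetic subject
#'
#' Draws the subject's multiplicative effect-size gain from the log-normal
#' jitter law (mean 1), then synthesizes `2 * n_trials_per_class` labeled
#' trials: independent 1/f^alpha background per channel plus the planted
#' rhythms. Fully deterministic given `(spec, subject_index)`.
#'
#' @param spec a [synth_spec()].
#' @param subject_index 1-based index `<= n_subjects`.
#' @return an [eeg_trial_set()] with attribute `"subject_gain"`.
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "synth_spec"))
  if (subject_index < 1 || subject_index > spec$n_subjects)
    stop("subject_index must lie in 1..n_subjects")
  validate_synth_spec(spec)
  set.seed(subject_seed(spec$seed, subject_index))

  fs <- spec$sample_rate
  S  <- round(spec$trial_duration * fs)
  C  <- spec$n_channels
  N  <- spec$n_trials_per_class
  tt <- (seq_len(S) - 1) / fs

  sj <- spec$subject_jitter
  gain <- if (sj > 0) exp(stats::rnorm(1, 0, sj) - sj^2 / 2) else 1

  labels <- rep(spec$labels, each = N)
  # fixed interleaved presentation order (deterministic, both classes mixed)
  ord <- order(rep(seq_len(N), times = 2), rep(1:2, each = N))
  labels <- labels[ord]
  ntr <- 2L * N

  dat <- array(0, dim = c(ntr, C, S))
  for (n in seq_len(ntr))
    dat[n, , ] <- t(one_over_f_noise(S, C, spec$noise_exponent))

  ch_idx <- function(name) match(name, spec$montage$channel)

  for (p in spec$erd_plants) {
    f0 <- mean(p$band)
    A  <- plant_amplitude(p$band, spec, S)
    ci <- ch_idx(p$channel)
    sr <- sample_range(p$interval, fs, S)
    d  <- max(p$depth * gain, -0.999)
    for (n in seq_len(ntr)) {
      ph  <- stats::runif(1, 0, 2 * pi)
      env <- rep(1, S)
      if (labels[n] == p$label) env[sr[1]:sr[2]] <- sqrt(1 + d)
      dat[n, ci, ] <- dat[n, ci, ] + A * env * cos(2 * pi * f0 * tt + ph)
    }
  }

  for (p in spec$coupling_plants) {
    f0 <- mean(p$band)
    A  <- plant_amplitude(p$band, spec, S)
    ia <- ch_idx(p$pair[1]); ib <- ch_idx(p$pair[2])
    sr <- sample_range(p$interval, fs, S)
    env <- rep(0, S); env[sr[1]:sr[2]] <- 1
    for (n in seq_len(ntr)) {
      ph  <- stats::runif(1, 0, 2 * pi)
      psi <- stats::runif(1, 0, 2 * pi)     # independent component phase
      if (is.null(p$label) || labels[n] == p$label) {
        sa <- cos(2 * pi * f0 * tt + ph)
        sb <- p$strength * cos(2 * pi * f0 * tt + ph + p$phase_lag) +
          (1 - p$strength) * cos(2 * pi * f0 * tt + psi)
        dat[n, ia, ] <- dat[n, ia, ] + A * env * sa
        dat[n, ib, ] <- dat[n, ib, ] + A * env * sb
      }
    }
  }

  ts <- eeg_trial_set(dat, labels, fs, spec$montage,
                      subject_id = sprintf("S%02d", subject_index))
  attr(ts, "subject_gain") <- gain
  ts
}

#' Generate a full synthetic cohort with ground truth
#'
#' @param spec a [synth_spec()].
#' @return list with elements `subjects` (list of [eeg_trial_set()]) and
#'   `truth` (a `synth_truth` list: `erd_map` and `wpli_map` data frames,
#'   `discriminative_channels`, and the per-subject gains).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  subjects <- lapply(seq_len(spec$n_subjects), function(m) generate_subject(spec, m))
  gains <- vapply(subjects, function(s) attr(s, "subject_gain"), numeric(1))

  erd_map <- if (length(spec$erd_plants)) {
    do.call(rbind, lapply(spec$erd_plants, function(p)
      data.frame(channel = p$channel, f_low = p$band[1], f_high = p$band[2],
                 t_start = p$interval[1], t_end = p$interval[2],
                 label = p$label, depth = p$depth, stringsAsFactors = FALSE)))
  } else data.frame()
  wpli_map <- if (length(spec$coupling_plants)) {
    do.call(rbind, lapply(spec$coupling_plants, function(p)
      data.frame(ch_a = p$pair[1], ch_b = p$pair[2],
                 f_low = p$band[1], f_high = p$band[2],
                 t_start = p$interval[1], t_end = p$interval[2],
                 phase_lag = p$phase_lag, strength = p$strength,
                 label = if (is.null(p$label)) NA_character_ else p$label,
                 stringsAsFactors = FALSE)))
  } else data.frame()

  disc <- unique(c(
    vapply(spec$erd_plants, function(p) p$channel, character(1)),
    unlist(lapply(spec$coupling_plants, function(p) if (!is.null(p$label)) p$pair))))

  truth <- structure(
    list(erd_map = erd_map, wpli_map = wpli_map,
         discriminative_channels = disc, subject_gains = gains),
    class = "synth_truth")
  list(subjects = subjects, truth = truth)
}
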