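#' Trial-averaged power time-course of one channel
#'
#' Squares each sample and averages across the trials of one class on the
#' per-sample grid (time resolution = one sample). Smoothing is an explicit
#' optional moving average, not baked into the estimate.
#'
#' @param trials band-passed [eeg_trial_set()].
#' @param channel channel name.
#' @param label class label.
#' @param smooth moving-average width in seconds (default 0.125; 0 disables).
#'   Besides denoising the display, the smoothing lightens the chi-square
#'   tail of instantaneous power, which keeps the bootstrap significance
#'   level accurate.
#' @return numeric vector `xi` over samples with attribute
#'   `"sample_rate"`.
#' @export
power_timecourse <- function(trials, channel, label, smooth = 0.125) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  ci <- match(channel, channels(trials))
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (!label %in% trials$labels) stop("no trials with label ", label)
  X <- trials$data[trials$labels == label, ci, , drop = FALSE]
  xi <- colMeans(matrix(X^2, nrow = dim(X)[1]))
  xi <- smooth_series(xi, smooth, trials$sample_rate)
  attr(xi, "sample_rate") <- trials$sample_rate
  xi
}

# centered moving average with nearest-valid edge fill (length preserved)
smooth_series <- function(xi, smooth, fs) {
  if (smooth <= 0) return(xi)
  w <- max(1L, round(smooth * fs))
  out <- as.numeric(stats::filter(xi, rep(1 / w, w), sides = 2))
  nas <- which(is.na(out))
  if (length(nas)) {
    ok <- which(!is.na(out))
    out[nas] <- out[vapply(nas, function(i) ok[which.min(abs(ok - i))], integer(1))]
  }
  out
}

#' Relative power change versus a reference interval (ERD/S map)
#'
#' `zeta = (xi - xi_bar) / xi_bar` with `xi_bar` the mean power over the
#' reference interval. Negative values are desynchronization (ERD),
#' positive ones synchronization (ERS); the quantity is bounded below by
#' -1 since power is non-negative.
#'
#' @param xi power time-course from [power_timecourse()] (attribute
#'   `"sample_rate"` required).
#' @param dT0 reference interval `c(start, end)` seconds.
#' @return list `zeta` (vector over samples), `xi_bar` (scalar); if
#'   `xi_bar` is 0 the map is flagged undefined (`zeta` all NA).
#' @export
erds_map <- function(xi, dT0 = c(0.5, 1.5)) {
  fs <- attr(xi, "sample_rate")
  if (is.null(fs)) stop("xi must carry a 'sample_rate' attribute")
  sr <- sample_range(dT0, fs, length(xi))
  xi_bar <- mean(xi[sr[1]:sr[2]])
  if (xi_bar == 0) {
    warning("reference power is zero; ERD/S undefined")
    return(list(zeta = rep(NA_real_, length(xi)), xi_bar = 0))
  }
  list(zeta = (as.numeric(xi) - xi_bar) / xi_bar, xi_bar = xi_bar)
}

#' Bootstrap significance mask of the ERD/S time-course
#'
#' Trial-level bootstrap: each resample recomputes the relative power
#' change per sample instant; a cell is significant when the two-sided
#' interval at level `alpha` excludes 0. The default interval is BCa
#' (bias-corrected and accelerated, with an analytic jackknife for the
#' mean-power ratio): the plain percentile interval over-rejects on the
#' skewed power distribution at small `alpha`.
#'
#' @param trials band-passed [eeg_trial_set()].
#' @param channel channel name.
#' @param label class label.
#' @param dT0 reference interval, seconds.
#' @param alpha two-sided level (default 0.01).
#' @param B bootstrap resamples.
#' @param smooth per-trial power smoothing width in seconds (matches
#'   [power_timecourse()]); heavy unsmoothed power tails inflate the level.
#' @param method `"bca"` or `"percentile"`.
#' @param seed resampling seed.
#' @return logical vector per sample instant; attribute `"ci"` holds the
#'   2 x n interval bounds.
#' @export
erds_significance <- function(trials, channel, label, dT0 = c(0.5, 1.5),
                              alpha = 0.01, B = 1000, smooth = 0.125,
                              method = c("bca", "percentile"), seed = 1L) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  method <- match.arg(method)
  ci <- match(channel, channels(trials))
  if (is.na(ci)) stop("unknown channel: ", channel)
  X <- trials$data[trials$labels == label, ci, , drop = FALSE]
  ntr <- dim(X)[1]
  if (ntr < 20) warning("fewer than 20 trials; bootstrap level will be unreliable")
  P <- matrix(X^2, nrow = ntr)                     # trials x samples
  if (smooth > 0)
    P <- t(apply(P, 1, smooth_series, smooth = smooth, fs = trials$sample_rate))
  fs <- trials$sample_rate
  sr <- sample_range(dT0, fs, ncol(P))
  n_t <- ncol(P)
  xi_hat <- colMeans(P)
  xb_hat <- mean(xi_hat[sr[1]:sr[2]])
  zeta_hat <- xi_hat / xb_hat - 1
  set.seed(seed)
  idx <- matrix(sample.int(ntr, ntr * B, replace = TRUE), nrow = B)
  zb <- matrix(0, B, n_t)
  for (b in seq_len(B)) {
    xi <- colMeans(P[idx[b, ], , drop = FALSE])
    xb <- mean(xi[sr[1]:sr[2]])
    zb[b, ] <- if (xb > 0) (xi - xb) / xb else NA_real_
  }
  if (method == "percentile") {
    lo <- apply(zb, 2, stats::quantile, probs = alpha / 2, na.rm = TRUE)
    hi <- apply(zb, 2, stats::quantile, probs = 1 - alpha / 2, na.rm = TRUE)
  } else {
    # analytic leave-one-out values of the mean-power ratio
    r_i <- rowMeans(P[, sr[1]:sr[2], drop = FALSE])
    xi_jk <- (matrix(xi_hat * ntr, ntr, n_t, byrow = TRUE) - P) / (ntr - 1)
    xb_jk <- (xb_hat * ntr - r_i) / (ntr - 1)
    zjk <- xi_jk / xb_jk - 1
    jm <- colMeans(zjk)
    d <- sweep(zjk, 2, jm, "-")
    accel <- -colSums(d^3) / (6 * pmax(colSums(d^2), 1e-300)^1.5)
    # bias correction: fraction of resamples below the point estimate
    frac <- colMeans(sweep(zb, 2, zeta_hat, "<"), na.rm = TRUE)
    z0 <- stats::qnorm(pmin(pmax(frac, 1 / (B + 1)), B / (B + 1)))
    zalo <- stats::qnorm(alpha / 2); zahi <- stats::qnorm(1 - alpha / 2)
    a1 <- stats::pnorm(z0 + (z0 + zalo) / (1 - accel * (z0 + zalo)))
    a2 <- stats::pnorm(z0 + (z0 + zahi) / (1 - accel * (z0 + zahi)))
    lo <- hi <- numeric(n_t)
    for (tt in seq_len(n_t)) {
      lo[tt] <- stats::quantile(zb[, tt], probs = a1[tt], na.rm = TRUE)
      hi[tt] <- stats::quantile(zb[, tt], probs = a2[tt], na.rm = TRUE)
    }
  }
  sig <- (lo > 0) | (hi < 0)
  attr(sig, "ci") <- rbind(lower = lo, upper = hi)
  sig
}

#' ERD/S dynamics across all channels
#'
#' Runs [power_timecourse()] and [erds_map()] for every channel of each
#' class over every filter-bank band, assembling the signed relative-change
#' dynamics plus a magnitude-normalized version for topographic export.
#'
#' @param trials raw [eeg_trial_set()] (band-passed internally per band).
#' @param fb a [build_filterbank()].
#' @param dT0 reference interval.
#' @param smooth moving-average width in seconds for the power time-courses
#'   (default 0.125).
#' @return object of class `tf_dynamics` with signed
#'   `zeta[channel, band, sample, label]`, `theta` its magnitude scaled to
#'   `[0, 1]` per (band, sample, label) cell, `positions` the per-sample
#'   time axis.
#' @export
erds_dynamics <- function(trials, fb, dT0 = c(0.5, 1.5), smooth = 0.125) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  labs <- sort(unique(trials$labels))
  C <- n_channels(trials); nb <- nrow(fb$bands); n <- n_samples(trials)
  zeta <- array(NA_real_, dim = c(C, nb, n, 2),
                dimnames = list(channels(trials), NULL, NULL, labs))
  xi_arr <- zeta
  for (b in seq_len(nb)) {
    tb <- bandpass(trials, fb$bands[b, ])
    for (li in 1:2) for (ci in seq_len(C)) {
      xi <- power_timecourse(tb, channels(trials)[ci], labs[li], smooth = smooth)
      xi_arr[ci, b, , li] <- xi
      zeta[ci, b, , li] <- erds_map(xi, dT0)$zeta
    }
  }
  theta <- abs(zeta)
  mx <- apply(theta, c(2, 3, 4), max)
  for (b in seq_len(nb)) for (li in 1:2) {
    m <- mx[b, , li]
    ok <- which(m > 0)
    if (length(ok)) theta[, b, ok, li] <- sweep(theta[, b, ok, li, drop = FALSE], 3, m[ok], "/")
  }
  structure(list(theta = theta, zeta = zeta, xi = xi_arr, bands = fb$bands,
                 positions = time_axis(trials), channels = channels(trials),
                 extractor = "erds", labeled = TRUE, labels = labs),
            class = "tf_dynamics")
}
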