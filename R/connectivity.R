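#' Complex Morlet wavelet coefficients at one frequency
#'
#' Convolves every (trial, channel) series with a complex Morlet wavelet
#' centered at `f` (Gaussian time s.d. `cycles / (2 pi f)`), normalized to
#' unit passband gain: for a pure sinusoid at `f` the coefficient magnitude
#' equals the amplitude and the phase advances `2 pi f` per second. Samples
#' closer than half the wavelet support to either trial edge are flagged
#' unreliable in the `"valid"` attribute.
#'
#' @param trials an [eeg_trial_set()].
#' @param f center frequency, Hz (below Nyquist).
#' @param cycles wavelet cycles (>= 3; time-frequency resolution floor).
#' @return complex array `[trial, channel, sample]` with attributes
#'   `"valid"` (logical per sample) and `"f"`.
#' @export
wavelet_coefficients <- function(trials, f, cycles = 7) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  fs <- trials$sample_rate
  if (f >= fs / 2) stop("frequency at/above Nyquist")
  if (cycles < 3) stop("cycles must be >= 3")
  n <- n_samples(trials)
  s_t <- cycles / (2 * pi * f)
  half <- floor(3.5 * s_t * fs)
  L <- 2L * half + 1L
  if (L > n) stop("wavelet support (", L, " samples) exceeds the trial length (", n, ")")
  tw <- (seq_len(L) - half - 1) / fs
  g <- exp(-tw^2 / (2 * s_t^2))
  kern <- exp(2i * pi * f * tw) * g * (2 / sum(g))
  nfft <- stats::nextn(n + L - 1L, 2)
  K <- stats::fft(c(kern, rep(0, nfft - L)))
  dm <- dim(trials$data)
  out <- array(0i, dim = dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    x <- trials$data[i, j, ]
    y <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) * K, inverse = TRUE) / nfft
    out[i, j, ] <- y[half + seq_len(n)]
  }
  dimnames(out) <- list(NULL, channels(trials), NULL)
  valid <- rep(TRUE, n)
  if (half > 0) valid[c(seq_len(half), n - half + seq_len(half))] <- FALSE
  attr(out, "valid") <- valid
  attr(out, "f") <- f
  out
}

# wPLI from per-trial imaginary cross-spectra: rows = trials. `scale` is the
# mean cross-spectrum magnitude per column; denominators that are only
# floating-point residue of an exactly-real cross-spectrum (zero lag) count
# as zero.
wpli_from_imag <- function(im, scale = NULL) {
  num <- abs(colMeans(abs(im) * sign(im)))
  den <- colMeans(abs(im))
  tol <- if (is.null(scale)) 0 else 1e-9 * scale
  ifelse(den > tol, num / den, 0)
}

#' Trial-ensemble weighted phase lag index of one channel pair
#'
#' Quantifies the asymmetry of the phase-difference distribution between two
#' channels: `wPLI = |E{|Im S| sgn(Im S)}| / E{|Im S|}` with `S` the
#' per-trial cross-spectrum (coefficients of `c` times the conjugate of
#' `c'`) and the expectation across trials. Insensitive to zero-lag
#' (volume-conduction) coupling; returns 0 where the denominator vanishes.
#'
#' @param coeffs_c,coeffs_cp complex `trials x samples` matrices (or
#'   vectors, treated as single-sample columns) of wavelet coefficients.
#' @param average_samples if TRUE, the imaginary cross-spectrum is averaged
#'   over the sample columns before the trial expectation, returning one
#'   value; otherwise one value per sample column.
#' @return wPLI value(s) in `[0, 1]`.
#' @export
wpli_pair <- function(coeffs_c, coeffs_cp, average_samples = FALSE) {
  if (is.null(dim(coeffs_c))) coeffs_c <- matrix(coeffs_c, ncol = 1)
  if (is.null(dim(coeffs_cp))) coeffs_cp <- matrix(coeffs_cp, ncol = 1)
  stopifnot(all(dim(coeffs_c) == dim(coeffs_cp)))
  ntr <- nrow(coeffs_c)
  if (ntr < 2) stop("the trial-ensemble wPLI needs at least 2 trials")
  if (ntr < 10) warning("fewer than 10 trials; wPLI estimate will be unstable")
  S <- coeffs_c * Conj(coeffs_cp)
  im <- Im(S)
  scale <- colMeans(Mod(S))
  if (average_samples) {
    im <- matrix(rowMeans(im), ncol = 1)
    scale <- mean(scale)
  }
  wpli_from_imag(im, scale = scale)
}

all_pairs <- function(chans) {
  C <- length(chans)
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             a = chans[idx[, 1]], b = chans[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Dynamic functional connectivity over a time-frequency grid
#'
#' Per class label and filter-bank band, computes Morlet coefficients at
#' the band center and the trial-ensemble wPLI of every channel pair per
#' window position (imaginary cross-spectra averaged over the window
#' samples before the trial expectation). Optionally re-references to an
#' electrode first (conventionally Cz), excluding it from the pair set.
#'
#' @param trials an [eeg_trial_set()].
#' @param fb a [build_filterbank()].
#' @param grid a [make_window_grid()] (the 0.1 s fixed-step grid by
#'   convention).
#' @param cycles Morlet cycles.
#' @param reference electrode to re-reference to, or NULL to skip.
#' @param exclude_reference drop the reference channel from the pair set.
#' @return object of class `connectivity_dynamics`: `phi` array
#'   `[pair, band, position, label]` in `[0, 1]`, `pairs` data.frame,
#'   `bands`, `positions`, `labels`, `channels`.
#' @export
connectivity_dynamics <- function(trials, fb, grid, cycles = 7,
                                  reference = "Cz", exclude_reference = TRUE) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (!is.null(reference) && reference %in% channels(trials)) {
    trials <- rereference(trials, reference)
    keep <- if (exclude_reference) setdiff(channels(trials), reference) else channels(trials)
  } else keep <- channels(trials)
  ki <- match(keep, channels(trials))
  labs <- sort(unique(trials$labels))
  pr <- all_pairs(keep)
  nb <- nrow(fb$bands); np <- length(grid$positions); V <- nrow(pr)
  n <- n_samples(trials)
  # window indicator for sample averaging
  Wmat <- matrix(0, n, np)
  for (p in seq_len(np)) {
    srr <- window_samples(grid, grid$positions[p], n)
    Wmat[srr[1]:srr[2], p] <- 1 / (srr[2] - srr[1] + 1)
  }
  phi <- array(NA_real_, dim = c(V, nb, np, 2),
               dimnames = list(NULL, NULL, NULL, labs))
  ctr <- band_centers(fb)
  for (b in seq_len(nb)) {
    co <- wavelet_coefficients(trials, ctr[b], cycles = cycles)
    for (li in 1:2) {
      tidx <- which(trials$labels == labs[li])
      for (v in seq_len(V)) {
        S <- co[tidx, ki[pr$i[v]], ] * Conj(co[tidx, ki[pr$j[v]], ])
        imw <- Im(S) %*% Wmat                 # trials x positions
        scw <- colMeans(Mod(S) %*% Wmat)
        phi[v, b, , li] <- wpli_from_imag(imw, scale = scw)
      }
    }
  }
  structure(list(phi = phi, pairs = pr, bands = fb$bands,
                 positions = grid$positions, labels = labs,
                 channels = keep, reference = reference),
            class = "connectivity_dynamics")
}

#' Baseline-normalize connectivity dynamics
#'
#' Per (pair, band, label), divides (default) or subtracts the mean wPLI
#' over the reference interval. Pairs whose baseline mean is zero are
#' flagged and keep their raw values.
#'
#' @param cd a [connectivity_dynamics()] object.
#' @param dT0 reference interval `c(start, end)` seconds.
#' @param method `"divide"` or `"subtract"`.
#' @return `cd` with `phi_norm` added (same shape as `phi`), plus
#'   `baseline_flagged` (logical `[pair, band, label]`).
#' @export
baseline_normalize <- function(cd, dT0 = c(0.5, 1.5), method = c("divide", "subtract")) {
  stopifnot(inherits(cd, "connectivity_dynamics"))
  method <- match.arg(method)
  sel <- cd$positions >= dT0[1] & cd$positions <= dT0[2]
  if (!any(sel)) stop("no window positions inside the baseline interval")
  base <- apply(cd$phi[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  flagged <- base == 0
  out <- cd$phi
  for (li in seq_along(cd$labels)) for (b in seq_len(dim(out)[2])) {
    bb <- base[, b, li]
    if (method == "divide") {
      ok <- bb > 0
      out[ok, b, , li] <- cd$phi[ok, b, , li, drop = FALSE] / bb[ok]
    } else {
      out[, b, , li] <- sweep(cd$phi[, b, , li, drop = FALSE], 1, bb, "-")
    }
  }
  cd$phi_norm <- out
  cd$baseline <- dT0
  cd$baseline_method <- method
  cd$baseline_flagged <- flagged
  cd
}

#' Node strength and connectivity dynamics per channel
#'
#' Marginalizes the pairwise wPLI to a per-channel strength (sum over the
#' pairs containing the channel) and scales it to `[0, 1]` per
#' (band, position, label) cell.
#'
#' @param cd a [connectivity_dynamics()] object.
#' @param use_normalized use `phi_norm` (if present) instead of raw `phi`.
#' @return object of class `tf_dynamics` with `theta[channel, band,
#'   position, label]` in `[0, 1]` and `phi_hat` the unscaled strengths.
#' @export
node_strength <- function(cd, use_normalized = FALSE) {
  stopifnot(inherits(cd, "connectivity_dynamics"))
  phi <- if (use_normalized && !is.null(cd$phi_norm)) cd$phi_norm else cd$phi
  C <- length(cd$channels)
  dm <- dim(phi)
  strength <- array(0, dim = c(C, dm[2], dm[3], dm[4]),
                    dimnames = list(cd$channels, NULL, NULL, cd$labels))
  for (v in seq_len(nrow(cd$pairs))) {
    strength[cd$pairs$i[v], , , ] <- strength[cd$pairs$i[v], , , , drop = FALSE] + phi[v, , , , drop = FALSE]
    strength[cd$pairs$j[v], , , ] <- strength[cd$pairs$j[v], , , , drop = FALSE] + phi[v, , , , drop = FALSE]
  }
  theta <- strength
  mx <- apply(strength, c(2, 3, 4), max)
  for (b in seq_len(dm[2])) for (p in seq_len(dm[3])) for (li in seq_len(dm[4])) {
    if (mx[b, p, li] > 0) theta[, b, p, li] <- strength[, b, p, li] / mx[b, p, li]
  }
  structure(list(theta = theta, phi_hat = strength, bands = cd$bands,
                 positions = cd$positions, channels = cd$channels,
                 extractor = "wpli", labeled = TRUE, labels = cd$labels),
            class = "tf_dynamics")
}
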