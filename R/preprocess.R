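#' Overlapping band-pass filter bank
#'
#' Tiles `[f_min, f_max]` with bands of `width` Hz advanced by `step` Hz,
#' so consecutive bands overlap by `width - step` Hz. The default grid
#' (4-40 Hz, 4 Hz bands, 2 Hz step) yields 17 bands covering the mu and
#' beta rhythms with 2 Hz overlap.
#'
#' @param f_min,f_max range to cover, Hz.
#' @param width band width, Hz.
#' @param step band advance, Hz.
#' @return object of class `filter_bank`: list with `bands` (n x 2 matrix),
#'   and the generating parameters.
#' @export
build_filterbank <- function(f_min = 4, f_max = 40, width = 4, step = 2) {
  if (width <= 0 || step <= 0) stop("width and step must be positive")
  if (f_min + width > f_max) stop("f_min + width must not exceed f_max")
  n <- floor((f_max - f_min - width) / step) + 1
  lows <- f_min + step * (seq_len(n) - 1)
  bands <- cbind(low = lows, high = lows + width)
  structure(list(bands = bands, f_min = f_min, f_max = f_max,
                 width = width, step = step),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands of %g Hz stepped by %g Hz over [%g, %g] Hz\n",
              nrow(x$bands), x$width, x$step, x$f_min, x$f_max))
  invisible(x)
}

#' Centers of the filter-bank bands
#' @param fb a `filter_bank`.
#' @return numeric vector of band center frequencies, Hz.
#' @export
band_centers <- function(fb) rowMeans(fb$bands)

#' Reporting sub-bands of the beta rhythm
#'
#' The beta oscillation is conventionally split into three 4-Hz sub-bands
#' for topographic reporting.
#'
#' @return 3 x 2 matrix of (low, high) Hz.
#' @export
beta_subbands <- function() {
  cbind(low = c(16, 20, 24), high = c(20, 24, 28))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward-backward (`signal::filtfilt`), so the
#' composed response has zero group delay and the effective attenuation
#' order is doubled.
#'
#' @param trials an [eeg_trial_set()] (or a plain numeric vector for one
#'   signal).
#' @param band `c(low, high)` Hz, inside the Nyquist range.
#' @param order per-pass Butterworth order.
#' @return filtered object of the same shape/class.
#' @export
bandpass <- function(trials, band, order = 4) {
  fs <- if (inherits(trials, "eeg_trial_set")) trials$sample_rate else attr(trials, "sample_rate")
  if (is.null(fs)) stop("sample rate unavailable; pass an eeg_trial_set or set attr 'sample_rate'")
  if (band[2] >= fs / 2) stop("band upper edge ", band[2], " Hz at/above Nyquist ", fs / 2, " Hz")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  if (!inherits(trials, "eeg_trial_set")) {
    out <- signal::filtfilt(bf, as.numeric(trials))
    attr(out, "sample_rate") <- fs
    return(out)
  }
  d <- trials$data
  dm <- dim(d)
  # filter along the sample axis for every (trial, channel) series
  flat <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  flat <- apply(flat, 2, function(v) signal::filtfilt(bf, v))
  trials$data <- aperm(array(flat, dim = c(dm[3], dm[1], dm[2])), c(2, 3, 1))
  dimnames(trials$data) <- list(NULL, trials$montage$channel, NULL)
  trials
}

# nearest-neighbor sets on the montage graph: channels within
# radius_factor x (median nearest-neighbor distance), at most max_neighbors
montage_neighbors <- function(montage, radius_factor = 1.35, max_neighbors = 4) {
  xy <- as.matrix(montage[, c("x", "y")])
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  radius <- radius_factor * stats::median(nn)
  lapply(seq_len(nrow(D)), function(i) {
    j <- which(D[i, ] <= radius)
    if (length(j) > max_neighbors) j <- j[order(D[i, j])][seq_len(max_neighbors)]
    j
  })
}

#' Small surface-Laplacian spatial filter
#'
#' Replaces each channel by itself minus the mean of its nearest montage
#' neighbors, sharpening focal sources and rejecting common-mode activity.
#' Channels without neighbors under the radius scheme are passed through
#' unchanged and reported via the `"laplacian_flagged"` attribute.
#'
#' @param trials an [eeg_trial_set()] with at least 5 channels.
#' @param radius_factor neighbor search radius as a multiple of the median
#'   nearest-neighbor distance.
#' @param max_neighbors cap on the neighborhood size.
#' @return filtered [eeg_trial_set()].
#' @export
surface_laplacian <- function(trials, radius_factor = 1.35, max_neighbors = 4) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  C <- n_channels(trials)
  if (C < 5) stop("surface Laplacian needs at least 5 channels")
  nb <- montage_neighbors(trials$montage, radius_factor, max_neighbors)
  flagged <- character(0)
  # linear operator L: identity minus neighbor-averaging
  L <- diag(C)
  for (i in seq_len(C)) {
    if (!length(nb[[i]])) {
      flagged <- c(flagged, trials$montage$channel[i])
      next
    }
    L[i, nb[[i]]] <- -1 / length(nb[[i]])
  }
  if (length(flagged))
    message("surface_laplacian: no neighbors for ", paste(flagged, collapse = ", "),
            "; passed through unchanged")
  d <- trials$data
  dm <- dim(d)
  flat <- matrix(aperm(d, c(2, 1, 3)), nrow = dm[2])   # C x (trials*samples)
  flat <- L %*% flat
  trials$data <- aperm(array(flat, dim = c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  dimnames(trials$data) <- list(NULL, trials$montage$channel, NULL)
  attr(trials, "laplacian_flagged") <- flagged
  trials
}

#' Re-reference all channels to one electrode
#'
#' Subtracts the reference channel's signal from every channel; used before
#' the connectivity stage (conventionally Cz). The reference channel itself
#' becomes identically zero.
#'
#' @param trials an [eeg_trial_set()].
#' @param reference channel name, default `"Cz"`.
#' @return re-referenced [eeg_trial_set()] with attribute `"reference"`.
#' @export
rereference <- function(trials, reference = "Cz") {
  stopifnot(inherits(trials, "eeg_trial_set"))
  ri <- match(reference, channels(trials))
  if (is.na(ri)) stop("reference channel not in montage: ", reference)
  ref <- trials$data[, ri, , drop = FALSE]
  trials$data <- trials$data - ref[, rep(1, n_channels(trials)), , drop = FALSE]
  attr(trials, "reference") <- reference
  trials
}

#' Sliding-window grid over a trial
#'
#' Two conventions: `"fixed-step"` places windows of length `tau` starting
#' at 0 and advancing by `tau * (1 - overlap)`, keeping every window fully
#' inside `[0, T]`; `"per-sample"` puts one position at every sample
#' instant, both endpoints inclusive, giving `round(T * fs) + 1` positions
#' (1751 for a 7 s trial at 250 Hz).
#'
#' @param tau window length, seconds (ignored for per-sample grids).
#' @param overlap fraction in `[0, 1)`.
#' @param T trial span, seconds.
#' @param fs sample rate, Hz.
#' @param mode `"fixed-step"` or `"per-sample"`.
#' @return object of class `window_grid`: `positions` (start times, s),
#'   `tau`, `overlap`, `T`, `fs`, `mode`.
#' @export
make_window_grid <- function(tau, overlap = 0, T, fs, mode = c("fixed-step", "per-sample")) {
  mode <- match.arg(mode)
  if (mode == "fixed-step") {
    if (tau > T) stop("window length tau exceeds the trial span")
    if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
    step <- tau * (1 - overlap)
    k <- floor((T - tau) / step + 1e-9)
    positions <- step * (0:k)
    tau_out <- tau
  } else {
    positions <- (0:round(T * fs)) / fs
    tau_out <- 1 / fs
  }
  structure(list(positions = positions, tau = tau_out, overlap = overlap,
                 T = T, fs = fs, mode = mode),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %s: %d positions, tau = %g s over [0, %g] s\n",
              x$mode, length(x$positions), x$tau, x$T))
  invisible(x)
}

# sample indices [i0, i1] of one window of a grid
window_samples <- function(grid, position, n) {
  i0 <- round(position * grid$fs) + 1L
  i1 <- min(n, i0 + max(1L, round(grid$tau * grid$fs)) - 1L)
  c(i0, i1)
}

#' Registry of the analysis intervals of the trial paradigm
#'
#' Named segments of the 7 s two-class trial: `dT0` the pre-cue reference
#' interval, `dT1` the task-negative interval prior to cue onset, `dT2` the
#' cue-onset interval, `dT3` the motor-imagery interval, `dT4` the decaying
#' motor-imagery interval and `dT5` the break period.
#'
#' @return named list of `c(start, end)` pairs in seconds.
#' @export
default_intervals <- function() {
  list(dT0 = c(0.5, 1.5),
       dT1 = c(0.0, 2.0),
       dT2 = c(0.8, 2.0),
       dT3 = c(2.6, 4.6),
       dT4 = c(3.8, 5.8),
       dT5 = c(4.4, 6.4))
}
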