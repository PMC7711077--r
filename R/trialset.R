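#' Labeled multi-trial EEG container
#'
#' The universal input of the package: a `trial x channel x sample` numeric
#' array with class labels, sampling metadata and a 2-D montage. Both classes
#' must be present with at least two trials each.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]` (microvolts
#'   or any consistent amplitude unit).
#' @param labels character/factor of length `n_trials`; exactly two distinct
#'   values (e.g. `"left"`, `"right"`).
#' @param sample_rate sampling frequency in Hz.
#' @param montage data.frame with columns `channel`, `x`, `y` (2-D scalp
#'   projection); row order defines channel order and must match `dim(data)[2]`.
#' @param subject_id optional identifier stored with the set.
#'
#' @return An object of class `eeg_trial_set`.
#' @export
eeg_trial_set <- function(data, labels, sample_rate, montage, subject_id = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, sample]")
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials")
  ul <- unique(labels)
  if (length(ul) != 2L)
    stop("exactly two classes are required, got: ", paste(ul, collapse = ", "))
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 trials")
  if (!is.data.frame(montage) || !all(c("channel", "x", "y") %in% names(montage)))
    stop("`montage` must be a data.frame with columns channel, x, y")
  if (nrow(montage) != dim(data)[2L])
    stop("montage has ", nrow(montage), " channels but data has ", dim(data)[2L])
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be a positive number")
  dimnames(data) <- list(NULL, montage$channel, NULL)
  structure(
    list(data = data, labels = labels, sample_rate = sample_rate,
         montage = montage, subject_id = subject_id),
    class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(x$labels)
  cat(sprintf("<eeg_trial_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$sample_rate))
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_trial_set <- function(x) dim(x$data)

n_trials   <- function(ts) dim(ts$data)[1L]
n_channels <- function(ts) dim(ts$data)[2L]
n_samples  <- function(ts) dim(ts$data)[3L]

#' Channel names of a trial set
#' @param ts an `eeg_trial_set`.
#' @return character vector of channel names in data order.
#' @export
channels <- function(ts) ts$montage$channel

#' Subset trials by class label
#' @param ts an `eeg_trial_set`.
#' @param label one of the two class labels.
#' @return array `[trial, channel, sample]` of that class.
#' @export
class_trials <- function(ts, label) {
  idx <- which(ts$labels == label)
  if (!length(idx)) stop("no trials with label ", label)
  ts$data[idx, , , drop = FALSE]
}

#' Time axis of a trial set
#' @param ts an `eeg_trial_set`.
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(ts) (seq_len(n_samples(ts)) - 1L) / ts$sample_rate

# sample index range [i0, i1] for a time interval (seconds, inclusive)
sample_range <- function(interval, fs, n) {
  i0 <- max(1L, round(interval[1] * fs) + 1L)
  i1 <- min(n, round(interval[2] * fs) + 1L)
  if (i1 < i0) stop("interval outside the trial span")
  c(i0, i1)
}

#' Standard 22-channel motor-imagery montage
#'
#' The 10-20 style layout used by the BCI Competition IV-2a recordings
#' (central sensorimotor strip plus fronto-central, centro-parietal and
#' midline parietal electrodes). Coordinates are a schematic 2-D head
#' projection: x grows to the right, y to the front.
#'
#' @param channels optional subset of channel names (order preserved as given).
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_bci2a <- function(channels = NULL) {
  m <- data.frame(
    channel = c("Fz",
                "FC3", "FC1", "FCz", "FC2", "FC4",
                "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                "CP3", "CP1", "CPz", "CP2", "CP4",
                "P1", "Pz", "P2",
                "POz"),
    x = c(0,
          -0.4, -0.2, 0, 0.2, 0.4,
          -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6,
          -0.4, -0.2, 0, 0.2, 0.4,
          -0.2, 0, 0.2,
          0),
    y = c(0.5,
          rep(0.25, 5),
          rep(0, 7),
          rep(-0.25, 5),
          rep(-0.5, 3),
          -0.7),
    stringsAsFactors = FALSE)
  if (!is.null(channels)) {
    miss <- setdiff(channels, m$channel)
    if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
    m <- m[match(channels, m$channel), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Generic rectangular montage
#'
#' Fallback layout for synthetic channel counts with no named standard:
#' channels are placed on a near-square grid with unit spacing.
#'
#' @param n_channels number of channels.
#' @param prefix channel-name prefix.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_grid <- function(n_channels, prefix = "ch") {
  ncol <- ceiling(sqrt(n_channels))
  idx <- seq_len(n_channels) - 1L
  data.frame(
    channel = sprintf("%s%02d", prefix, seq_len(n_channels)),
    x = (idx %% ncol) * 0.2,
    y = -(idx %/% ncol) * 0.2,
    stringsAsFactors = FALSE)
}
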