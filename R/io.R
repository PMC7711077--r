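#' Write a trial set to the portable container
#'
#' The container is a directory holding `meta.json` (labels, sample rate,
#' montage, subject id, array shape) and `data.tsv` (one row per
#' (trial, channel), samples as columns, full `%.17g` precision so the
#' round trip is bit-exact for doubles).
#'
#' @param ts an [eeg_trial_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(ts$data)
  meta <- list(schema = "migroup-trialset-1",
               n_trials = dm[1], n_channels = dm[2], n_samples = dm[3],
               sample_rate = ts$sample_rate, labels = ts$labels,
               subject_id = ts$subject_id,
               montage = ts$montage)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  flat <- matrix(aperm(ts$data, c(3, 2, 1)), nrow = dm[3])  # samples x (ch*trial)
  con <- file(file.path(path, "data.tsv"), "w")
  on.exit(close(con))
  writeLines(apply(t(flat), 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a trial set from the portable container
#' @param path container directory written by [write_trialset()].
#' @return an [eeg_trial_set()].
#' @export
read_trialset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a trial-set container (meta.json missing): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema, "migroup-trialset-1"))
    stop("unknown container schema: ", meta$schema)
  vals <- scan(file.path(path, "data.tsv"), sep = "\t", quiet = TRUE)
  flat <- matrix(vals, nrow = meta$n_samples)                # samples x (ch*trial)
  dat <- aperm(array(flat, dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  montage <- as.data.frame(meta$montage, stringsAsFactors = FALSE)
  eeg_trial_set(dat, meta$labels, as.numeric(meta$sample_rate), montage,
                subject_id = meta$subject_id)
}

# ---- minimal GDF 2.x subset -------------------------------------------------

gdf_dtype <- function(code) {
  switch(as.character(code),
         "3" = list(what = "integer", size = 2L, signed = TRUE),
         "5" = list(what = "integer", size = 4L, signed = TRUE),
         "16" = list(what = "double", size = 4L, signed = TRUE),
         "17" = list(what = "double", size = 8L, signed = TRUE),
         stop("unsupported GDF channel data type code: ", code))
}

pad_str <- function(s, n) {
  r <- charToRaw(substr(s, 1, n))
  c(r, raw(n - length(r)))
}

#' Read a GDF 2.x file and epoch labeled motor-imagery trials
#'
#' A minimal reader for the GDF 2.x subset used by two-class motor-imagery
#' competition recordings: fixed 256-byte header, per-channel headers,
#' channel-blocked data records (int16/int32/float32/float64 with
#' physical scaling) and a mode-1 or mode-3 event table. Trials are
#' epoched to `[0, epoch_duration]` s from each trial-start event
#' (default code 768) and labeled by the first cue event (default 769 =
#' left, 770 = right) within the trial; trials flagged by a rejection
#' event (default 1023) are dropped. When no trial-start events exist,
#' cue events themselves define the onsets shifted by `cue_offset`.
#'
#' @param path GDF file.
#' @param epoch_duration trial span in seconds (default 7).
#' @param event_codes named list: `trial_start`, `cues` (named vector
#'   code -> label), `reject`.
#' @param cue_offset seconds from trial start to cue (used in the
#'   cue-only fallback).
#' @param montage optional montage data.frame; default matches the channel
#'   labels against the standard 22-channel layout, else a generic grid.
#' @return an [eeg_trial_set()].
#' @export
read_gdf <- function(path, epoch_duration = 7,
                     event_codes = list(trial_start = 768,
                                        cues = c("769" = "left", "770" = "right"),
                                        reject = 1023),
                     cue_offset = 2, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- rawToChar(readBin(con, "raw", 8))
  if (!grepl("^GDF", version)) stop("not a GDF file (version string: ", version, ")")
  invisible(readBin(con, "raw", 184 - 8))              # patient/recording block
  header_blocks <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  invisible(readBin(con, "raw", 236 - 186))
  nr_lo <- readBin(con, "integer", 1, size = 4, endian = "little")     # int64 n_records
  nr_hi <- readBin(con, "integer", 1, size = 4, endian = "little")
  n_records <- (if (nr_lo < 0) nr_lo + 2^32 else nr_lo) + nr_hi * 2^32
  dur_num <- readBin(con, "integer", 1, size = 4, endian = "little")
  dur_den <- readBin(con, "integer", 1, size = 4, endian = "little")
  ns <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  invisible(readBin(con, "raw", 2))
  if (ns < 1 || n_records < 1) stop("empty GDF file")

  labels_raw <- vapply(seq_len(ns), function(i) {
    r <- readBin(con, "raw", 16)
    trimws(rawToChar(r[r != as.raw(0)]))
  }, character(1))
  invisible(readBin(con, "raw", 80 * ns))              # transducer
  invisible(readBin(con, "raw", 6 * ns))               # physical dimension (obsolete)
  invisible(readBin(con, "raw", 2 * ns))               # physdim code
  physmin <- readBin(con, "double", ns, size = 8, endian = "little")
  physmax <- readBin(con, "double", ns, size = 8, endian = "little")
  digmin  <- readBin(con, "double", ns, size = 8, endian = "little")
  digmax  <- readBin(con, "double", ns, size = 8, endian = "little")
  invisible(readBin(con, "raw", 64 * ns))              # prefiltering (obsolete)
  invisible(readBin(con, "raw", 4 * ns))               # time offset
  invisible(readBin(con, "raw", 12 * ns))              # lowpass/highpass/notch
  spr <- readBin(con, "integer", ns, size = 4, endian = "little")
  dtype <- readBin(con, "integer", ns, size = 4, endian = "little")
  invisible(readBin(con, "raw", 32 * ns))              # sensor position/info

  # skip any extra header blocks beyond the fixed + channel headers
  extra <- header_blocks * 256L - (256L + 256L * ns)
  if (extra > 0) invisible(readBin(con, "raw", extra))

  fs <- spr[1] * dur_den / dur_num
  n_total <- n_records * spr[1]
  dat <- matrix(0, nrow = ns, ncol = n_total)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dt <- gdf_dtype(dtype[ch])
      v <- readBin(con, dt$what, spr[ch], size = dt$size,
                   signed = dt$signed, endian = "little")
      if (dtype[ch] %in% c(3L, 5L)) {
        v <- (v - digmin[ch]) * (physmax[ch] - physmin[ch]) /
          (digmax[ch] - digmin[ch]) + physmin[ch]
      }
      dat[ch, (r - 1) * spr[ch] + seq_len(spr[ch])] <- v
    }
  }

  mode <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  if (length(mode) == 0) stop("GDF file has no event table")
  nev_bytes <- readBin(con, "raw", 3)
  nev <- sum(as.integer(nev_bytes) * 256^(0:2))
  ev_fs <- readBin(con, "double", 1, size = 4, endian = "little")
  if (!is.finite(ev_fs) || ev_fs <= 0) ev_fs <- fs
  pos <- readBin(con, "integer", nev, size = 4, endian = "little")
  typ <- readBin(con, "integer", nev, size = 2, signed = FALSE, endian = "little")
  if (nev == 0) stop("GDF event table is empty; cannot epoch trials")

  cue_map <- event_codes$cues
  starts <- pos[typ == event_codes$trial_start]
  n_ep <- round(epoch_duration * fs)
  onsets <- integer(0); labels <- character(0)
  if (length(starts)) {
    for (s in starts) {
      w <- which(pos >= s & pos <= s + round((cue_offset + 2) * fs) &
                   typ %in% as.integer(names(cue_map)))
      if (!length(w)) next
      onsets <- c(onsets, s)
      labels <- c(labels, cue_map[as.character(typ[w[1]])])
    }
  } else {
    w <- which(typ %in% as.integer(names(cue_map)))
    onsets <- pos[w] - round(cue_offset * fs)
    labels <- unname(cue_map[as.character(typ[w])])
  }
  # drop rejected or out-of-range trials
  rej <- pos[typ == event_codes$reject]
  keep <- vapply(seq_along(onsets), function(i) {
    o <- onsets[i]
    o >= 1 && o + n_ep - 1 <= n_total &&
      !any(rej >= o & rej <= o + n_ep - 1)
  }, logical(1))
  onsets <- onsets[keep]; labels <- labels[keep]
  if (!length(onsets))
    stop("no labeled trials found (looked for cue codes ",
         paste(names(cue_map), collapse = ", "), ")")

  arr <- array(0, dim = c(length(onsets), ns, n_ep))
  for (i in seq_along(onsets))
    arr[i, , ] <- dat[, onsets[i] + seq_len(n_ep) - 1]

  if (is.null(montage)) {
    std <- montage_bci2a()
    montage <- if (all(labels_raw %in% std$channel) && !anyDuplicated(labels_raw)) {
      montage_bci2a(labels_raw)
    } else {
      m <- montage_grid(ns)
      m$channel <- make.unique(ifelse(labels_raw == "", m$channel, labels_raw))
      m
    }
  }
  eeg_trial_set(arr, labels, fs, montage,
                subject_id = sub("\\.gdf$", "", basename(path), ignore.case = TRUE))
}

#' Write a trial set as a GDF 2.20 file (float32 samples, mode-1 events)
#'
#' Companion writer for the [read_gdf()] subset: continuous concatenated
#' trials, one data record per trial, with trial-start (768) and cue
#' (769/770) events. Mainly intended for tests and for exporting synthetic
#' cohorts to GDF-consuming tools.
#'
#' @param ts an [eeg_trial_set()] whose two labels map onto left/right.
#' @param path output file.
#' @param cue_offset seconds from trial start to the cue event.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(ts, path, cue_offset = 2) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  dm <- dim(ts$data)
  ns <- dm[2]; spr <- dm[3]; nrec <- dm[1]
  labs <- sort(unique(ts$labels))
  code_of <- stats::setNames(c(769L, 770L), labs)   # first label = left cue code
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_str("GDF 2.20", 8), con)
  writeBin(raw(184 - 8), con)
  writeBin(as.integer(1 + ns), con, size = 2, endian = "little")  # header blocks
  writeBin(raw(236 - 186), con)
  writeBin(as.integer(c(nrec, 0L)), con, size = 4, endian = "little")  # int64 n_records
  # record duration = spr / fs seconds, stored as rational num/den
  writeBin(as.integer(spr), con, size = 4, endian = "little")
  writeBin(as.integer(round(ts$sample_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(ns), con, size = 2, endian = "little")
  writeBin(raw(2), con)
  for (ch in channels(ts)) writeBin(pad_str(ch, 16), con)
  writeBin(raw(80 * ns), con)
  writeBin(raw(6 * ns), con)
  writeBin(raw(2 * ns), con)
  writeBin(rep(-1e4, ns), con, size = 8, endian = "little")  # physmin
  writeBin(rep(1e4, ns), con, size = 8, endian = "little")   # physmax
  writeBin(rep(-1e4, ns), con, size = 8, endian = "little")  # digmin
  writeBin(rep(1e4, ns), con, size = 8, endian = "little")   # digmax
  writeBin(raw(64 * ns), con)
  writeBin(raw(4 * ns), con)
  writeBin(raw(12 * ns), con)
  writeBin(as.integer(rep(spr, ns)), con, size = 4, endian = "little")
  writeBin(as.integer(rep(16L, ns)), con, size = 4, endian = "little")  # float32
  writeBin(raw(32 * ns), con)
  for (r in seq_len(nrec)) for (ch in seq_len(ns))
    writeBin(as.double(ts$data[r, ch, ]), con, size = 4, endian = "little")
  # event table, mode 1
  onsets <- (seq_len(nrec) - 1L) * spr + 1L
  pos <- as.integer(rbind(onsets, onsets + round(cue_offset * ts$sample_rate)))
  typ <- as.integer(rbind(rep(768L, nrec), code_of[ts$labels]))
  nev <- length(pos)
  writeBin(as.raw(1), con)
  writeBin(as.raw(c(nev %% 256, (nev %/% 256) %% 256, nev %/% 65536)), con)
  writeBin(as.double(ts$sample_rate), con, size = 4, endian = "little")
  writeBin(pos, con, size = 4, endian = "little")
  writeBin(typ, con, size = 2, endian = "little")
  invisible(path)
}

#' Export a spatial dynamics cell as a topographic map
#'
#' Writes the exact per-channel values as delimited text (normative) and,
#' optionally, an inverse-distance-weighted interpolated scalp map as PNG
#' (decorative).
#'
#' @param theta named numeric vector (names = channels) for one
#'   time-frequency cell.
#' @param montage montage data.frame covering all names in `theta`.
#' @param file_prefix output path prefix (`.tsv` / `.png` appended).
#' @param png write the image too.
#' @param grid_n interpolation grid resolution per axis.
#' @return path of the value file, invisibly.
#' @export
topomap_export <- function(theta, montage, file_prefix, png = TRUE, grid_n = 64) {
  if (is.null(names(theta))) stop("theta must be a named channel vector")
  mi <- match(names(theta), montage$channel)
  if (anyNA(mi)) stop("unknown channel in theta: ",
                      paste(names(theta)[is.na(mi)], collapse = ", "))
  tsv <- paste0(file_prefix, ".tsv")
  utils::write.table(
    data.frame(channel = names(theta), value = sprintf("%.9g", theta)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (png) {
    xy <- montage[mi, c("x", "y")]
    gx <- seq(min(xy$x) - 0.1, max(xy$x) + 0.1, length.out = grid_n)
    gy <- seq(min(xy$y) - 0.1, max(xy$y) + 0.1, length.out = grid_n)
    z <- outer(gx, gy, Vectorize(function(px, py) {
      d2 <- (xy$x - px)^2 + (xy$y - py)^2
      if (any(d2 < 1e-12)) return(theta[which.min(d2)])
      w <- 1 / d2^1.5
      sum(w * theta) / sum(w)
    }))
    grDevices::png(paste0(file_prefix, ".png"), width = 480, height = 480)
    graphics::image(gx, gy, z, col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "", ylab = "", axes = FALSE, asp = 1)
    graphics::points(xy$x, xy$y, pch = 20)
    graphics::text(xy$x, xy$y, names(theta), pos = 3, cex = 0.7)
    grDevices::dev.off()
  }
  invisible(tsv)
}
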