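#' Per-channel relevance test of time-frequency dynamics over an interval
#'
#' The supervised thresholding rule: per (channel, band), a two-sample
#' Mann-Whitney test compares the dynamics' values across the window
#' positions falling inside the interval between the two class labels.
#' For unlabeled dynamics (the CSP patterns merge both labels) the contrast
#' is instead the interval versus a task-negative baseline interval.
#' Kolmogorov-Smirnov (normality) and Bartlett (homoscedasticity)
#' diagnostics are recorded per cell but do not alter the test.
#'
#' The tested values are the extractor's natural scale: the trial-averaged
#' band power for ERD/S (rank-equivalent to the relative change under a
#' label-shared reference, and free of the shared offset each label's own
#' estimated baseline injects into its series), unscaled node strength for
#' connectivity, and the normalized pattern magnitude for CSP.
#'
#' @param dyn a `tf_dynamics` object.
#' @param interval `c(start, end)` seconds (e.g. the motor-imagery
#'   interval).
#' @param alpha significance level for the raw mask (default 0.05).
#' @param baseline_interval contrast interval for unlabeled dynamics
#'   (default the task-negative `c(0, 2)`).
#' @param min_samples minimum window positions required per side.
#' @param thin keep every `thin`-th window position, or `"auto"` to space
#'   positions so the retained samples are approximately independent
#'   (0.25 s for the per-sample power grid, 0.3 s for the wavelet
#'   connectivity grid, one window length for overlapping-window grids):
#'   the rank test assumes independent samples, and overlapping or
#'   smoothed series would otherwise inflate its level.
#' @return object of class `significance_mask`: `p` and `kappa`
#'   (`channel x band` matrices), `ks_p`, `bartlett_p`, `alpha`,
#'   `interval`.
#' @export
channel_relevance <- function(dyn, interval, alpha = 0.05,
                              baseline_interval = c(0, 2), min_samples = 8,
                              thin = "auto") {
  stopifnot(inherits(dyn, "tf_dynamics"))
  vals <- switch(dyn$extractor,
                 erds = if (!is.null(dyn$xi)) dyn$xi else dyn$zeta,
                 wpli = dyn$phi_hat,
                 dyn$theta)
  labeled <- isTRUE(dyn$labeled)
  pos <- dyn$positions
  if (identical(thin, "auto")) {
    spacing <- if (length(pos) > 1) min(diff(pos)) else 1
    gap <- switch(dyn$extractor,
                  erds = 0.25,
                  wpli = 0.3,
                  if (!is.null(dyn$tau)) dyn$tau else spacing)
    thin <- max(1L, round(gap / spacing))
  }
  sub_idx <- function(idx) idx[seq(1, length(idx), by = thin)]
  in_i <- which(pos >= interval[1] & pos <= interval[2])
  if (length(in_i) < min_samples)
    stop("interval holds ", length(in_i), " window positions; need >= ", min_samples)
  in_i <- sub_idx(in_i)
  if (!labeled) {
    in_b <- which(pos >= baseline_interval[1] & pos <= baseline_interval[2])
    if (length(in_b) < min_samples)
      stop("baseline interval holds too few window positions")
    in_b <- sub_idx(in_b)
  }
  C <- dim(vals)[1]; nb <- dim(vals)[2]
  p <- ks_p <- bart_p <- matrix(NA_real_, C, nb,
                                dimnames = list(dyn$channels, NULL))
  for (ci in seq_len(C)) for (b in seq_len(nb)) {
    if (labeled) {
      x <- vals[ci, b, in_i, 1]; y <- vals[ci, b, in_i, 2]
    } else {
      x <- vals[ci, b, in_i]; y <- vals[ci, b, in_b]
    }
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) next
    p[ci, b] <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    z <- c(x, y)
    if (stats::sd(z) > 0) {
      ks_p[ci, b] <- suppressWarnings(
        stats::ks.test(z, "pnorm", mean(z), stats::sd(z))$p.value)
      g <- factor(rep(1:2, c(length(x), length(y))))
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        bart_p[ci, b] <- stats::bartlett.test(z, g)$p.value
    }
  }
  kappa <- (!is.na(p)) & (p < alpha)
  structure(list(p = p, kappa = kappa, ks_p = ks_p, bartlett_p = bart_p,
                 alpha = alpha, interval = interval,
                 extractor = dyn$extractor, channels = dyn$channels),
            class = "significance_mask")
}

#' Storey-type positive-false-discovery-rate correction
#'
#' Estimates the null proportion `pi0` from the p-value distribution
#' (smoothed over a lambda grid) and converts p-values to q-values;
#' Benjamini-Hochberg is available as a conservative fallback
#' (equivalent to `pi0 = 1`).
#'
#' @param p numeric vector of p-values (NAs ignored and returned as NA).
#' @param q acceptance level for the mask (default 0.05).
#' @param method `"storey"` or `"BH"`.
#' @param lambda grid for the `pi0` estimate.
#' @param pfdr if TRUE, include Storey's positive-FDR finite-sample
#'   `Pr(R > 0)` adjustment in the q-values.
#' @return list: `qvalues` (same length as `p`), `mask` (`qvalues <= q`),
#'   `pi0`, `method`.
#' @export
pfdr_correct <- function(p, q = 0.05, method = c("storey", "BH"),
                         lambda = seq(0.05, 0.9, by = 0.05), pfdr = FALSE) {
  method <- match.arg(method)
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m < 1) stop("no p-values supplied")
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  qv <- rep(NA_real_, length(p))
  if (method == "BH" || m < 12) {
    pi0 <- 1
    qv[ok] <- stats::p.adjust(pv, method = "BH")
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- min(1, max(stats::predict(fit, max(lambda))$y, 1e-3))
    o <- order(pv)
    ranked <- pv[o]
    denom <- seq_len(m)
    qraw <- pi0 * m * ranked / denom
    if (pfdr) qraw <- qraw / (1 - (1 - ranked)^m)
    qmon <- rev(cummin(rev(pmin(qraw, 1))))
    qv[ok[o]] <- qmon
  }
  list(qvalues = qv, mask = !is.na(qv) & qv <= q, pi0 = pi0, method = method)
}

#' Aggregate subject-level dynamics into a group model
#'
#' Per (channel, band) cell, averages the subjects' dynamics over those
#' subjects whose corrected relevance mask retains the cell; the number of
#' contributing subjects (`support`) is recorded, and cells supported by
#' fewer than `min_support` of the cohort are marked unreliable (NA), not
#' zero.
#'
#' @param dyn_list list of `tf_dynamics`, one per subject, sharing the
#'   (channel, band, position) grid.
#' @param mask_list list of logical `channel x band` matrices (e.g.
#'   corrected `kappa`), one per subject.
#' @param min_support minimum fraction of the cohort that must contribute
#'   to a cell (default 0.5).
#' @return object of class `group_dynamics`: `theta_group` (same shape as
#'   one subject's `theta`), `support` (`channel x band`), `n_subjects`.
#' @export
group_aggregate <- function(dyn_list, mask_list, min_support = 0.5) {
  M <- length(dyn_list)
  stopifnot(M >= 1, length(mask_list) == M)
  ref <- dyn_list[[1]]
  dm <- dim(ref$theta)
  for (s in seq_len(M)) {
    if (!identical(dim(dyn_list[[s]]$theta), dm))
      stop("subject ", s, " has a mismatched dynamics grid (theta dimensions differ)")
    if (!identical(dyn_list[[s]]$channels, ref$channels))
      stop("subject ", s, " has a mismatched channel axis")
  }
  C <- dm[1]; nb <- dm[2]
  support <- matrix(0L, C, nb, dimnames = list(ref$channels, NULL))
  acc <- array(0, dim = dm)
  for (s in seq_len(M)) {
    msk <- mask_list[[s]]
    stopifnot(all(dim(msk) == c(C, nb)))
    th <- dyn_list[[s]]$theta
    th[!is.finite(th)] <- 0
    for (ci in seq_len(C)) for (b in seq_len(nb)) {
      if (isTRUE(msk[ci, b])) {
        if (length(dm) == 4) acc[ci, b, , ] <- acc[ci, b, , ] + th[ci, b, , ]
        else acc[ci, b, ] <- acc[ci, b, ] + th[ci, b, ]
        support[ci, b] <- support[ci, b] + 1L
      }
    }
  }
  theta_group <- array(NA_real_, dim = dm, dimnames = dimnames(ref$theta))
  thresh <- max(1L, ceiling(min_support * M))
  for (ci in seq_len(C)) for (b in seq_len(nb)) {
    if (support[ci, b] >= thresh) {
      if (length(dm) == 4) theta_group[ci, b, , ] <- acc[ci, b, , ] / support[ci, b]
      else theta_group[ci, b, ] <- acc[ci, b, ] / support[ci, b]
    }
  }
  structure(list(theta_group = theta_group, support = support,
                 n_subjects = M, min_support = min_support,
                 bands = ref$bands, positions = ref$positions,
                 channels = ref$channels, extractor = ref$extractor,
                 labeled = isTRUE(ref$labeled)),
            class = "group_dynamics")
}

#' @export
print.group_dynamics <- function(x, ...) {
  cat(sprintf("<group_dynamics:%s> %d subjects; %d/%d cells supported (>= %g of cohort)\n",
              x$extractor, x$n_subjects,
              sum(x$support >= max(1, ceiling(x$min_support * x$n_subjects))),
              length(x$support), x$min_support))
  invisible(x)
}

#' Split a cohort into BCI-literate and BCI-illiterate assemblies
#'
#' Subjects are points `(mean accuracy, sd accuracy)`. The
#' `ceil(trim * M)` points with the largest Mahalanobis distance to the
#' sample center seed the split; the final assignment cuts the
#' mean-accuracy ranking at the widest feasible gap, i.e. the largest gap
#' that keeps every trimmed low-accuracy outlier below the cut and every
#' trimmed high-accuracy outlier above it. With no usable gap (identical
#' points), the bottom-ranked `ceil(trim * M)` subjects form the
#' illiterate set, ties broken by subject index.
#'
#' @param accuracy data.frame with columns `subject`, `mean`, `sd`.
#' @param trim fraction trimmed by Mahalanobis distance (default 0.10).
#' @return object of class `literacy_split`: `literate`, `illiterate`
#'   (subject vectors), `distances`, `trimmed`, `predictor_points`,
#'   `cut_accuracy`.
#' @export
literacy_split <- function(accuracy, trim = 0.10) {
  stopifnot(is.data.frame(accuracy), all(c("subject", "mean", "sd") %in% names(accuracy)))
  M <- nrow(accuracy)
  if (M < 5) stop("need at least 5 subjects")
  X <- as.matrix(accuracy[, c("mean", "sd")])
  ctr <- colMeans(X)
  S <- stats::cov(X)
  d <- tryCatch({
    if (abs(det(S)) < 1e-12 * (sum(diag(S))^2 + 1e-300)) stop("singular")
    stats::mahalanobis(X, ctr, S)
  }, error = function(e) {
    message("literacy_split: singular predictor covariance; using standardized Euclidean distance")
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    rowSums(sweep(sweep(X, 2, ctr), 2, sds, "/")^2)
  })
  n_trim <- ceiling(trim * M)
  trim_idx <- order(-d, seq_len(M))[seq_len(n_trim)]
  retained_mean <- mean(accuracy$mean[-trim_idx])
  low_out  <- trim_idx[accuracy$mean[trim_idx] <  retained_mean]
  high_out <- trim_idx[accuracy$mean[trim_idx] >= retained_mean]
  rk <- order(-accuracy$mean, seq_len(M))     # descending accuracy, index ties
  ranked_acc <- accuracy$mean[rk]
  gaps <- ranked_acc[-M] - ranked_acc[-1]     # gap below rank r
  feasible <- vapply(seq_len(M - 1), function(r) {
    top <- rk[seq_len(r)]
    all(!(low_out %in% top)) && all(high_out %in% top)
  }, logical(1))
  if (any(feasible & gaps > 1e-12)) {
    cand <- which(feasible)
    cut <- cand[which.max(gaps[cand])]
  } else if (any(gaps > 1e-12)) {
    cut <- which.max(gaps)
  } else {
    cut <- M - n_trim
  }
  lit_idx <- rk[seq_len(cut)]
  ill_idx <- rk[(cut + 1):M]
  structure(list(literate = accuracy$subject[sort(lit_idx)],
                 illiterate = accuracy$subject[sort(ill_idx)],
                 distances = stats::setNames(d, accuracy$subject),
                 trimmed = accuracy$subject[sort(trim_idx)],
                 predictor_points = accuracy,
                 cut_accuracy = ranked_acc[cut]),
            class = "literacy_split")
}

#' Gaussian-kernel similarity of two spatial dynamics
#'
#' `sim = exp(-||eta - eta'||^2 / sigma^2)`: 1 iff the vectors coincide,
#' strictly decreasing in their distance. When `sigma` is not given it is
#' set by the median heuristic over `reference_set` (a list of vectors,
#' conventionally the motor-imagery-segment dynamics being compared), or,
#' lacking that, to the distance between the two inputs.
#'
#' @param eta,eta_prime equal-length numeric vectors.
#' @param sigma positive kernel width, or NULL to estimate.
#' @param reference_set optional list of vectors for the median heuristic.
#' @return similarity in `(0, 1]`.
#' @export
kernel_similarity <- function(eta, eta_prime, sigma = NULL, reference_set = NULL) {
  if (length(eta) != length(eta_prime)) stop("vectors must have equal length")
  dd <- sqrt(sum((eta - eta_prime)^2))
  if (is.null(sigma)) {
    sigma <- if (!is.null(reference_set) && length(reference_set) >= 2) {
      pd <- utils::combn(length(reference_set), 2, function(ij)
        sqrt(sum((reference_set[[ij[1]]] - reference_set[[ij[2]]])^2)))
      stats::median(pd[pd > 0])
    } else dd
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (sigma <= 0) stop("sigma must be positive")
  exp(-dd^2 / sigma^2)
}

#' Default primary-motor-area channel subset
#' @param available channel names present in the montage.
#' @return the sensorimotor channels (C3, Cz, C4 and immediate
#'   fronto-central / centro-parietal neighbors) found in `available`.
#' @export
primary_motor_channels <- function(available) {
  intersect(c("C3", "Cz", "C4", "FC3", "FC4", "CP3", "CP4"), available)
}

# flatten a group model to a similarity vector over a channel subset and
# position window; unreliable cells contribute 0 (no confident activity)
group_model_vector <- function(gd, channel_subset = NULL, interval = NULL) {
  ci <- if (is.null(channel_subset)) seq_along(gd$channels)
        else match(channel_subset, gd$channels)
  if (anyNA(ci)) stop("channel subset not in the group model")
  pos <- gd$positions
  pi_ <- if (is.null(interval)) seq_along(pos)
         else which(pos >= interval[1] & pos <= interval[2])
  th <- if (length(dim(gd$theta_group)) == 4)
    gd$theta_group[ci, , pi_, , drop = FALSE]
  else gd$theta_group[ci, , pi_, drop = FALSE]
  v <- as.numeric(th)
  v[!is.finite(v)] <- 0
  v
}

#' Desegregation analysis of the group model
#'
#' Recomputes the group model after removing the worst-ranked 0, 1, 2, ...
#' subjects (by accuracy) and scores each model's Gaussian-kernel
#' similarity to a reference model over a channel subset (default the
#' primary motor area) and position interval (default the motor-imagery
#' interval when the grid covers it).
#'
#' @param dyn_list list of subject `tf_dynamics`.
#' @param mask_list list of corrected relevance masks (one per subject).
#' @param accuracy_ranking subject indices ordered worst to best.
#' @param max_removed how many subjects to peel off (default `M - 3`;
#'   removal never leaves fewer than 3 subjects).
#' @param channel_subset channel names for the similarity vectors.
#' @param interval position window for the similarity vectors.
#' @param reference a `group_dynamics` to compare against, or NULL to use
#'   the full-cohort model.
#' @param sigma kernel width; NULL = median heuristic over all model
#'   vectors.
#' @param min_support passed to [group_aggregate()].
#' @return list: `curve` (data.frame `removed`, `similarity`), `models`,
#'   `pairwise` similarity matrix, `sigma`.
#' @export
desegregation_curve <- function(dyn_list, mask_list, accuracy_ranking,
                                max_removed = NULL, channel_subset = NULL,
                                interval = NULL, reference = NULL,
                                sigma = NULL, min_support = 0.5) {
  M <- length(dyn_list)
  stopifnot(length(accuracy_ranking) == M)
  if (is.null(channel_subset)) {
    channel_subset <- primary_motor_channels(dyn_list[[1]]$channels)
    if (!length(channel_subset)) channel_subset <- dyn_list[[1]]$channels
  }
  if (is.null(max_removed)) max_removed <- M - 3L
  max_removed <- min(max_removed, M - 3L)
  if (max_removed < 0) stop("removal would leave fewer than 3 subjects")
  models <- vector("list", max_removed + 1L)
  for (r in 0:max_removed) {
    keep <- setdiff(seq_len(M), accuracy_ranking[seq_len(r)])
    models[[r + 1L]] <- group_aggregate(dyn_list[keep], mask_list[keep],
                                        min_support = min_support)
  }
  vecs <- lapply(models, group_model_vector,
                 channel_subset = channel_subset, interval = interval)
  ref_vec <- if (is.null(reference)) vecs[[1]]
             else group_model_vector(reference, channel_subset, interval)
  if (is.null(sigma)) {
    allv <- c(vecs, list(ref_vec))
    pd <- utils::combn(length(allv), 2, function(ij)
      sqrt(sum((allv[[ij[1]]] - allv[[ij[2]]])^2)))
    sigma <- stats::median(pd[pd > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  sim <- vapply(vecs, kernel_similarity, numeric(1),
                eta_prime = ref_vec, sigma = sigma)
  nmod <- length(vecs)
  pw <- matrix(1, nmod, nmod)
  for (i in seq_len(nmod - 1)) for (j in (i + 1):nmod) {
    pw[i, j] <- pw[j, i] <- kernel_similarity(vecs[[i]], vecs[[j]], sigma = sigma)
  }
  list(curve = data.frame(removed = 0:max_removed, similarity = sim),
       models = models, pairwise = pw, sigma = sigma,
       channel_subset = channel_subset)
}
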