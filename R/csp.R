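#' Class-conditional covariance matrices for one time-frequency cell
#'
#' The simplest class variance estimate: average over the class trials of
#' `X X' / n_samples` on the window samples of band-passed data. Optional
#' shrinkage toward the scaled identity guards short windows.
#'
#' @param trials band-passed [eeg_trial_set()].
#' @param window `c(start, end)` seconds, or NULL for the whole trial.
#' @param gamma shrinkage coefficient in `[0, 1]`: each class covariance
#'   becomes `(1 - gamma) * S + gamma * (tr(S)/C) * I`.
#' @return object of class `class_covariances`: `sigma` (named list of the
#'   two C x C matrices), `n_trials` (per class), `window`, `gamma`.
#' @export
class_covariances <- function(trials, window = NULL, gamma = 0) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  labs <- sort(unique(trials$labels))
  n <- n_samples(trials)
  sr <- if (is.null(window)) c(1L, n) else sample_range(window, trials$sample_rate, n)
  sigma <- list(); ntr <- integer(0)
  for (lb in labs) {
    X <- class_trials(trials, lb)[, , sr[1]:sr[2], drop = FALSE]
    if (dim(X)[1] < 2) stop("class ", lb, " has fewer than 2 trials")
    C <- dim(X)[2]
    S <- matrix(0, C, C)
    for (i in seq_len(dim(X)[1])) {
      M <- X[i, , ]
      S <- S + tcrossprod(M) / ncol(M)
    }
    S <- S / dim(X)[1]
    if (gamma > 0) S <- (1 - gamma) * S + gamma * (sum(diag(S)) / C) * diag(C)
    S <- (S + t(S)) / 2
    sigma[[lb]] <- S
    ntr[lb] <- dim(X)[1]
  }
  structure(list(sigma = sigma, n_trials = ntr,
                 window = if (is.null(window)) c(0, n / trials$sample_rate) else window,
                 gamma = gamma, channels = channels(trials)),
            class = "class_covariances")
}

#' Fit common spatial patterns for one time-frequency cell
#'
#' Maximizes the Rayleigh quotient
#' `J(w) = w' S_l w / (w' (S_l + S_l') w)` subject to `||w|| = 1`, solved as
#' the generalized symmetric eigenproblem `S_l w = J (S_l + S_l') w` via
#' whitening. Returns the `k` largest- and `k` smallest-J eigenvectors
#' (2k filters), rows unit-normalized with the largest-magnitude entry made
#' positive, plus the pattern (pseudo-inverse) matrix.
#'
#' @param cov a [class_covariances()] object.
#' @param k per-side component count (default 3); `2k <= C`.
#' @return object of class `spatial_filter_set`: `W` (2k x C), `rq_values`
#'   (descending, in (0,1)), `Winv` (C x 2k patterns), `k`, `channels`.
#' @export
csp_fit <- function(cov, k = 3) {
  stopifnot(inherits(cov, "class_covariances"))
  S1 <- cov$sigma[[1]]; S2 <- cov$sigma[[2]]
  C <- ncol(S1)
  if (2 * k > C) stop("2k exceeds the channel count")
  Sc <- S1 + S2
  ec <- eigen(Sc, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (min(ec$values) <= max(tol, 0))
    stop("composite covariance is singular; re-estimate with shrinkage gamma > 0")
  Wh <- ec$vectors %*% diag(1 / sqrt(ec$values), C) %*% t(ec$vectors)  # Sc^(-1/2)
  M <- Wh %*% S1 %*% Wh
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)              # eigenvalues descending = J
  sel <- c(seq_len(k), C - k + seq_len(k))      # k largest, then k smallest
  W <- t(Wh %*% em$vectors[, sel, drop = FALSE])
  # unit rows, largest-|entry| positive
  for (i in seq_len(nrow(W))) {
    W[i, ] <- W[i, ] / sqrt(sum(W[i, ]^2))
    if (W[i, which.max(abs(W[i, ]))] < 0) W[i, ] <- -W[i, ]
  }
  rq <- em$values[sel]
  # recompute J for the normalized rows (norm-invariant, but keep exact)
  rq <- vapply(seq_len(nrow(W)), function(i) {
    w <- W[i, ]
    as.numeric((w %*% S1 %*% w) / (w %*% Sc %*% w))
  }, numeric(1))
  Winv <- MASS::ginv(W)
  colnames(W) <- cov$channels
  rownames(Winv) <- cov$channels
  structure(list(W = W, rq_values = rq, Winv = Winv, k = k, channels = cov$channels),
            class = "spatial_filter_set")
}

#' Log-variance CSP features for one time-frequency cell
#'
#' Projects each trial through the fitted filters and takes the element-wise
#' log of the per-component variance over the window samples.
#'
#' @param filters a [csp_fit()] result for the same (band, window) cell.
#' @param trials band-passed [eeg_trial_set()].
#' @param window `c(start, end)` seconds, or NULL for the whole trial.
#' @param var_floor variance floor substituted (and logged) for degenerate
#'   zero-variance components.
#' @return `n_trials x 2k` matrix; attribute `"labels"` carries the trial
#'   labels.
#' @export
csp_features <- function(filters, trials, window = NULL, var_floor = 1e-12) {
  stopifnot(inherits(filters, "spatial_filter_set"),
            inherits(trials, "eeg_trial_set"))
  n <- n_samples(trials)
  sr <- if (is.null(window)) c(1L, n) else sample_range(window, trials$sample_rate, n)
  ntr <- n_trials(trials)
  D <- matrix(0, ntr, nrow(filters$W))
  for (i in seq_len(ntr)) {
    Z <- filters$W %*% trials$data[i, , sr[1]:sr[2]]
    v <- apply(Z, 1, stats::var)
    if (any(v < var_floor)) v <- pmax(v, var_floor)
    D[i, ] <- log(v)
  }
  attr(D, "labels") <- trials$labels
  D
}

#' CSP pattern dynamics over a time-frequency grid
#'
#' For each (band, window) cell, fits CSP and takes the absolute first
#' pattern column (the pattern of the highest-variance filter, a single
#' component), scaled to `[0, 1]` per cell by its maximum. The result is
#' the spatial activation dynamics of the discriminant subspace, merged
#' over both labels.
#'
#' @param trials raw [eeg_trial_set()] (the function band-passes internally).
#' @param fb a [build_filterbank()] object.
#' @param grid a [make_window_grid()] object (fixed-step).
#' @param k per-side component count for the fitted filters.
#' @param gamma shrinkage passed to [class_covariances()]; `"auto"` retries
#'   a singular cell with `gamma = 1e-3`.
#' @return object of class `tf_dynamics`: array `theta[channel, band,
#'   position]` in `[0, 1]`, plus `bands`, `positions`, `channels`,
#'   `extractor = "csp"` and the per-cell filter list.
#' @export
csp_pattern_dynamics <- function(trials, fb, grid, k = 3, gamma = "auto") {
  stopifnot(inherits(trials, "eeg_trial_set"))
  nb <- nrow(fb$bands); np <- length(grid$positions); C <- n_channels(trials)
  theta <- array(NA_real_, dim = c(C, nb, np),
                 dimnames = list(channels(trials), NULL, NULL))
  filters <- vector("list", nb * np)
  for (b in seq_len(nb)) {
    tb <- bandpass(trials, fb$bands[b, ])
    for (p in seq_len(np)) {
      win <- c(grid$positions[p], grid$positions[p] + grid$tau)
      g0 <- if (identical(gamma, "auto")) 0 else gamma
      cv <- class_covariances(tb, window = win, gamma = g0)
      fit <- tryCatch(csp_fit(cv, k = k), error = function(e) NULL)
      if (is.null(fit) && identical(gamma, "auto")) {
        cv <- class_covariances(tb, window = win, gamma = 1e-3)
        fit <- csp_fit(cv, k = k)
      }
      if (is.null(fit)) stop("singular covariance in band ", b, ", window ", p)
      a <- abs(fit$Winv[, 1])                  # highest-variance pattern
      theta[, b, p] <- if (max(a) > 0) a / max(a) else a
      filters[[(b - 1) * np + p]] <- fit
    }
  }
  structure(list(theta = theta, bands = fb$bands, positions = grid$positions,
                 channels = channels(trials), extractor = "csp",
                 labeled = FALSE, tau = grid$tau, filters = filters),
            class = "tf_dynamics")
}

#' @export
print.tf_dynamics <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("<tf_dynamics:%s> %d channels x %d bands x %d positions%s\n",
              x$extractor, d[1], d[2], d[3],
              if (isTRUE(x$labeled)) sprintf(" x %d labels", d[4]) else ""))
  invisible(x)
}

# regularized linear discriminant on feature rows (internal)
rlda_fit <- function(X, y, lambda = 0.1) {
  labs <- sort(unique(y))
  X0 <- X[y == labs[1], , drop = FALSE]; X1 <- X[y == labs[2], , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, m0)) + crossprod(sweep(X1, 2, m1))) /
    (nrow(X) - 2)
  p <- ncol(X)
  S <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  S <- S + 1e-10 * (sum(diag(S)) / p + 1) * diag(p)
  w <- solve(S, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2
  list(w = w, b = b, labs = labs)
}

rlda_predict <- function(fit, X) {
  s <- as.numeric(X %*% fit$w) + fit$b
  ifelse(s > 0, fit$labs[2], fit$labs[1])
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (lb in unique(y)) {
    idx <- sample(which(y == lb))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated accuracy time-course of filter-bank CSP features
#'
#' Per window position, fits CSP filters on the training folds only
#' (per band), builds the log-variance feature block over all bands, and
#' classifies with a shrinkage-regularized linear discriminant under
#' stratified k-fold cross-validation.
#'
#' @param trials raw [eeg_trial_set()].
#' @param fb a [build_filterbank()].
#' @param grid a fixed-step [make_window_grid()].
#' @param k CSP components per side.
#' @param folds cross-validation folds (default 10).
#' @param lambda discriminant shrinkage.
#' @param gamma covariance shrinkage for the per-fold CSP fits.
#' @param seed fold-assignment seed.
#' @return data.frame with one row per window position: `position`,
#'   `accuracy` (mean over folds), `sd` (across folds).
#' @export
accuracy_timecourse <- function(trials, fb, grid, k = 3, folds = 10,
                                lambda = 0.1, gamma = 1e-3, seed = 1L) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  tab <- table(trials$labels)
  if (min(tab) < 8) stop("need at least 8 trials per class")
  if (max(tab) / min(tab) > 4) warning("class imbalance beyond 4:1")
  folds <- min(folds, min(tab))
  y <- trials$labels
  fold <- stratified_folds(y, folds, seed)
  nb <- nrow(fb$bands)
  banded <- lapply(seq_len(nb), function(b) bandpass(trials, fb$bands[b, ]))
  out <- data.frame(position = grid$positions, accuracy = NA_real_, sd = NA_real_)
  for (p in seq_along(grid$positions)) {
    win <- c(grid$positions[p], grid$positions[p] + grid$tau)
    acc <- numeric(folds)
    for (fo in seq_len(folds)) {
      tr <- which(fold != fo); te <- which(fold == fo)
      Dtr <- NULL; Dte <- NULL
      for (b in seq_len(nb)) {
        sub <- banded[[b]]
        train_set <- sub; train_set$data <- sub$data[tr, , , drop = FALSE]
        train_set$labels <- y[tr]
        cv <- class_covariances(train_set, window = win, gamma = gamma)
        fit <- csp_fit(cv, k = k)
        Dtr <- cbind(Dtr, csp_features(fit, train_set, window = win))
        test_set <- sub; test_set$data <- sub$data[te, , , drop = FALSE]
        test_set$labels <- y[te]
        Dte <- cbind(Dte, csp_features(fit, test_set, window = win))
      }
      cls <- rlda_fit(Dtr, y[tr], lambda = lambda)
      acc[fo] <- mean(rlda_predict(cls, Dte) == y[te])
    }
    out$accuracy[p] <- mean(acc)
    out$sd[p] <- stats::sd(acc)
  }
  out
}
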