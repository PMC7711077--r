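test_that("class covariances behave on white noise, full shrinkage and duplicated channels", {
  ts <- noise_trials(n_per_class = 30, C = 4, S = 500, seed = 3)
  cv <- class_covariances(ts)
  expect_equal(unname(diag(cv$sigma[[1]])), rep(1, 4), tolerance = 0.1)
  offd <- cv$sigma[[1]][upper.tri(cv$sigma[[1]])]
  expect_true(all(abs(offd) < 0.05))
  # gamma = 1: exactly the scaled identity
  cv1 <- class_covariances(ts, gamma = 1)
  S <- cv1$sigma[[1]]
  expect_equal(S, diag(mean(diag(S)), 4), tolerance = 1e-12, ignore_attr = TRUE)
  # duplicated channel pair -> rank-1 2x2 block
  ts2 <- ts
  ts2$data[, 2, ] <- ts2$data[, 1, ]
  cv2 <- class_covariances(ts2)
  blk <- cv2$sigma[[1]][1:2, 1:2]
  expect_lt(abs(det(blk)), 1e-10 * max(blk)^2)
  expect_error(class_covariances(ts, gamma = 2), "gamma")
})

test_that("csp_fit solves the Rayleigh-quotient problem", {
  ts <- noise_trials(n_per_class = 4, C = 2, S = 50, seed = 4)
  cv <- class_covariances(ts)
  # equal class covariances: J = 1/2 for every filter
  cv$sigma[[1]] <- cv$sigma[[2]] <- matrix(c(2, 0.5, 0.5, 1), 2)
  f <- csp_fit(cv, k = 1)
  expect_equal(f$rq_values, c(0.5, 0.5), tolerance = 1e-12)
  # diagonal example: max J = 4/5 along axis 1, min J = 1/5 along axis 2
  cv$sigma[[1]] <- diag(c(4, 1)); cv$sigma[[2]] <- diag(c(1, 4))
  f <- csp_fit(cv, k = 1)
  expect_equal(f$rq_values, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(f$W), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  # contract: unit rows, descending J, W Winv = identity on the subspace
  expect_equal(rowSums(f$W^2), rep(1, 2), tolerance = 1e-12)
  expect_equal(f$W %*% f$Winv, diag(2), tolerance = 1e-8)
  # singular composite without shrinkage is diagnosed
  cv$sigma[[1]] <- matrix(0, 2, 2); cv$sigma[[2]] <- matrix(0, 2, 2)
  expect_error(csp_fit(cv, k = 1), "shrinkage")
})

test_that("eigen solution matches the brute-force sphere oracle on random SPD pairs", {
  set.seed(5)
  worst <- 0
  for (r in 1:40) {
    C <- sample(2:3, 1)
    A <- matrix(rnorm(C * C), C); S1 <- crossprod(A) + 0.1 * diag(C)
    B <- matrix(rnorm(C * C), C); S2 <- crossprod(B) + 0.1 * diag(C)
    cv <- structure(list(sigma = list(a = S1, b = S2),
                         n_trials = c(a = 10, b = 10), window = c(0, 1),
                         gamma = 0, channels = paste0("ch", seq_len(C))),
                    class = "class_covariances")
    f <- csp_fit(cv, k = 1)
    worst <- max(worst, abs(f$rq_values[1] - rq_sphere_max(S1, S2)))
    # complementarity: swapping labels maps J to 1 - J
    cv2 <- cv; cv2$sigma <- list(a = S2, b = S1)
    f2 <- csp_fit(cv2, k = 1)
    expect_equal(f2$rq_values[1], 1 - f$rq_values[2], tolerance = 1e-9)
  }
  expect_lt(worst, 1e-3)
})

test_that("log-variance features obey the scale law and the floor", {
  ts <- noise_trials(n_per_class = 6, C = 4, S = 300, seed = 6)
  cv <- class_covariances(ts)
  f <- csp_fit(cv, k = 2)
  D <- csp_features(f, ts)
  expect_equal(dim(D), c(12, 4))          # 2k = 4 features per cell
  # scaling all trials by 10 shifts every feature by 2 log(10)
  ts10 <- ts
  ts10$data <- ts$data * 10
  D10 <- csp_features(f, ts10)
  expect_equal(D10 - D, matrix(2 * log(10), 12, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero-variance projection hits the floor
  ts0 <- ts
  ts0$data[] <- 0
  ts0$data[, 1, ] <- 1   # constant channel, zero variance after projection
  D0 <- csp_features(f, ts0, var_floor = 1e-12)
  expect_true(all(D0 <= log(1e-12) + 1e-9))
})

test_that("pattern dynamics land on the discriminative channel and stay in [0,1]", {
  sp <- small_spec(n_trials = 30, seed = 7,
                   erd = list(erd_plant("C3", c(8, 12), c(2.6, 4.6), -0.6,
                                        label = "right")))
  ts <- generate_subject(sp, 1)
  fb <- build_filterbank(8, 12, 4, 2)
  grid <- make_window_grid(1, 0.5, T = 7, fs = ts$sample_rate)
  dyn <- csp_pattern_dynamics(ts, fb, grid, k = 2)
  expect_true(all(dyn$theta >= 0 & dyn$theta <= 1))
  # within the MI interval the strongest pattern weight sits on C3
  sel <- which(dyn$positions >= 2.6 & dyn$positions + 1 <= 4.6)
  avg <- rowMeans(dyn$theta[, 1, sel])
  expect_equal(names(which.max(avg)), "C3")
})

test_that("accuracy time-course is at chance under permuted labels and high on plants", {
  sp <- small_spec(n_trials = 20, seed = 8,
                   erd = list(erd_plant("C3", c(8, 12), c(2.6, 4.6), -0.7,
                                        label = "right")))
  ts <- generate_subject(sp, 1)
  fb <- build_filterbank(8, 12, 4, 2)
  grid <- make_window_grid(2, 0, T = 7, fs = ts$sample_rate)
  acc <- accuracy_timecourse(ts, fb, grid, k = 2, folds = 5, seed = 1)
  # window covering the plant discriminates well; pre-cue window near chance
  expect_gt(acc$accuracy[acc$position == 2], 0.8)
  perm <- ts
  set.seed(99)
  perm$labels <- sample(perm$labels)
  accp <- accuracy_timecourse(perm, fb, grid, k = 2, folds = 5, seed = 1)
  expect_lt(mean(accp$accuracy), 0.7)
  # invariance to channel re-ordering and global per-trial gain
  reord <- ts
  ord <- rev(seq_len(10))
  reord$data <- ts$data[, ord, , drop = FALSE]
  reord$montage <- ts$montage[ord, ]
  accr <- accuracy_timecourse(reord, fb, grid, k = 2, folds = 5, seed = 1)
  expect_equal(accr$accuracy, acc$accuracy, tolerance = 1e-9)
  gained <- ts
  gained$data <- ts$data * 3.7
  accg <- accuracy_timecourse(gained, fb, grid, k = 2, folds = 5, seed = 1)
  expect_equal(accg$accuracy, acc$accuracy, tolerance = 1e-9)
})
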