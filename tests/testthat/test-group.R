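# small labeled dynamics object built directly (values, not signals)
make_dyn <- function(theta_l, theta_r, positions, channels, extractor = "erds") {
  C <- length(channels)
  arr <- array(NA_real_, c(C, 1, length(positions), 2),
               dimnames = list(channels, NULL, NULL, c("l", "r")))
  arr[, 1, , 1] <- theta_l
  arr[, 1, , 2] <- theta_r
  structure(list(theta = pmin(abs(arr), 1), zeta = arr,
                 bands = cbind(8, 12), positions = positions,
                 channels = channels, extractor = extractor,
                 labeled = TRUE, labels = c("l", "r")),
            class = "tf_dynamics")
}

test_that("channel relevance is calibrated on nulls and powerful on separated series", {
  set.seed(23)
  pos <- seq(2.6, 4.6, by = 0.05)
  chans <- paste0("ch", 1:4)
  # null: identical distributions -> uniform p, rejection rate near alpha
  pvals <- replicate(150, {
    d <- make_dyn(matrix(rnorm(4 * length(pos)), 4),
                  matrix(rnorm(4 * length(pos)), 4), pos, chans)
    channel_relevance(d, c(2.6, 4.6), alpha = 0.05)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  expect_gt(suppressWarnings(ks.test(as.numeric(pvals), "punif"))$p.value, 1e-4)
  # power: series offset by 5 pooled sd
  hit <- replicate(50, {
    d <- make_dyn(matrix(rnorm(4 * length(pos)), 4),
                  matrix(rnorm(4 * length(pos)) + 5, 4), pos, chans)
    all(channel_relevance(d, c(2.6, 4.6), alpha = 0.05)$kappa)
  })
  expect_gte(mean(hit), 0.99)
  # alpha = 0 retains nothing; diagnostics recorded
  d <- make_dyn(matrix(rnorm(4 * length(pos)), 4),
                matrix(rnorm(4 * length(pos)), 4), pos, chans)
  m0 <- channel_relevance(d, c(2.6, 4.6), alpha = 0)
  expect_false(any(m0$kappa))
  expect_true(all(is.finite(m0$ks_p)))
  expect_true(all(is.finite(m0$bartlett_p)))
  expect_error(channel_relevance(d, c(2.6, 2.7)), "positions")
})

test_that("unlabeled dynamics are contrasted against the task-negative interval", {
  set.seed(24)
  pos <- seq(0, 6, by = 0.1)
  C <- 3
  arr <- array(rnorm(C * 1 * length(pos)), c(C, 1, length(pos)))
  arr[2, 1, pos >= 2.6 & pos <= 4.6] <- arr[2, 1, pos >= 2.6 & pos <= 4.6] + 4
  d <- structure(list(theta = arr, bands = cbind(8, 12), positions = pos,
                      channels = paste0("ch", 1:3), extractor = "csp",
                      labeled = FALSE),
                 class = "tf_dynamics")
  m <- channel_relevance(d, c(2.6, 4.6), alpha = 0.01, baseline_interval = c(0, 2))
  expect_true(m$kappa[2, 1])
  expect_false(m$kappa[1, 1])
})

test_that("the Storey correction is calibrated, keeps overwhelming signal and beats BH", {
  set.seed(25)
  # uniform nulls: discovery proportion stays at/below q
  fdp <- replicate(200, {
    p <- runif(120)
    mean(pfdr_correct(p, q = 0.05)$mask)
  })
  expect_lt(mean(fdp), 0.05)
  # overwhelming signal all retained
  r <- pfdr_correct(rep(1e-6, 10), q = 0.05)
  expect_true(all(r$mask))
  # single p-value reduces to the raw threshold under the BH fallback
  r1 <- pfdr_correct(0.04, q = 0.05)
  expect_identical(r1$method %in% c("storey", "BH"), TRUE)
  expect_true(r1$mask)
  # mixed case: Storey q-values never exceed BH q-values (pi0 <= 1)
  p <- c(runif(80), rbeta(40, 0.2, 5))
  qs <- pfdr_correct(p, method = "storey")
  qb <- pfdr_correct(p, method = "BH")
  expect_lte(qs$pi0, 1)
  expect_true(all(qs$qvalues <= qb$qvalues + 1e-12))
  expect_gte(sum(qs$mask), sum(qb$mask))
  # NAs pass through, invalid values rejected
  qna <- pfdr_correct(c(0.01, NA, 0.5))
  expect_true(is.na(qna$qvalues[2]))
  expect_error(pfdr_correct(c(0.1, 1.2)), "p-values")
})

test_that("group aggregation is idempotent, masked and support-aware", {
  pos <- seq(0, 6, by = 0.5)
  chans <- paste0("ch", 1:3)
  base <- matrix(seq(0, 1, length.out = 3 * length(pos)), 3)
  dyns <- lapply(1:4, function(i) make_dyn(base, base, pos, chans))
  full <- lapply(1:4, function(i) matrix(TRUE, 3, 1))
  g <- group_aggregate(dyns, full)
  expect_equal(g$theta_group[, 1, , 1], dyns[[1]]$theta[, 1, , 1])
  expect_true(all(g$support == 4))
  # masks empty everywhere: all cells unreliable, no numeric output
  empty <- lapply(1:4, function(i) matrix(FALSE, 3, 1))
  g0 <- group_aggregate(dyns, empty)
  expect_true(all(is.na(g0$theta_group)))
  expect_true(all(g0$support == 0))
  # below-threshold support is withheld as NA, not zero
  part <- list(matrix(c(TRUE, FALSE, FALSE), 3), matrix(FALSE, 3, 1),
               matrix(FALSE, 3, 1), matrix(FALSE, 3, 1))
  gp <- group_aggregate(dyns, part, min_support = 0.5)
  expect_true(all(is.na(gp$theta_group[1, 1, , ])))
  # grid mismatch is named
  bad <- make_dyn(base[, -1], base[, -1], pos[-1], chans)
  expect_error(group_aggregate(list(dyns[[1]], bad), full[1:2]), "grid|dimensions")
})

test_that("literacy split trims by Mahalanobis distance and cuts at the widest gap", {
  # one extreme outlier in a tight cluster is trimmed first
  acc <- data.frame(subject = paste0("S", 1:9),
                    mean = c(90, 91, 92, 89, 90.5, 91.5, 60, 88, 89.5),
                    sd = c(3, 4, 3.5, 3, 4, 3.2, 12, 3.8, 3.1))
  sp <- literacy_split(acc)
  expect_true("S7" %in% sp$trimmed)
  expect_true("S7" %in% sp$illiterate)
  # clear two-cluster structure: cut lands between the clusters
  acc2 <- data.frame(subject = paste0("S", 1:9),
                     mean = c(95, 94, 93, 92, 91, 72, 71, 70, 69),
                     sd = c(2, 2, 3, 2, 3, 6, 7, 6, 7))
  sp2 <- literacy_split(acc2)
  expect_setequal(sp2$literate, paste0("S", 1:5))
  expect_setequal(sp2$illiterate, paste0("S", 6:9))
  # identical points: deterministic index tie-break, both sets non-empty
  acc3 <- data.frame(subject = paste0("S", 1:6), mean = 80, sd = 5)
  expect_message(sp3 <- literacy_split(acc3), "singular")
  expect_length(sp3$illiterate, 1)
  expect_length(sp3$literate, 5)
  expect_error(literacy_split(acc3[1:3, ]), "5 subjects")
})

test_that("kernel similarity obeys its analytic identities", {
  v <- c(1, 2, 3)
  expect_equal(kernel_similarity(v, v, sigma = 2), 1)
  # distance = sigma -> exp(-1)
  expect_equal(kernel_similarity(c(0, 0), c(3, 4), sigma = 5), exp(-1))
  # symmetry and strict monotonicity on a distance ladder
  prev <- 2
  for (d in c(0.5, 1, 2, 4)) {
    s1 <- kernel_similarity(c(0, 0), c(d, 0), sigma = 1.5)
    s2 <- kernel_similarity(c(d, 0), c(0, 0), sigma = 1.5)
    expect_equal(s1, s2)
    expect_lt(s1, prev)
    expect_true(s1 > 0 && s1 <= 1)
    prev <- s1
  }
  expect_error(kernel_similarity(v, v, sigma = -1), "positive")
  expect_error(kernel_similarity(v, c(1, 2)), "length")
})

test_that("desegregation keeps similarity 1 on homogeneous cohorts and at zero removals", {
  pos <- seq(2.6, 4.6, by = 0.25)
  chans <- c("C3", "Cz", "C4")
  base <- matrix(runif(3 * length(pos)), 3)
  dyns <- lapply(1:6, function(i) make_dyn(base, base, pos, chans))
  masks <- lapply(1:6, function(i) matrix(TRUE, 3, 1))
  ds <- desegregation_curve(dyns, masks, accuracy_ranking = 1:6,
                            channel_subset = chans)
  expect_equal(ds$curve$similarity[1], 1)
  expect_true(all(abs(ds$curve$similarity - 1) < 1e-9))
  expect_true(isSymmetric(ds$pairwise))
  expect_equal(nrow(ds$curve), 4)          # stops at 3 remaining subjects
  expect_error(desegregation_curve(dyns[1:2], masks[1:2], 1:2), "fewer than 3")
})
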