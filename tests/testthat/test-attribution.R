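test_that("AUROC loss is the stated percentage", {
  expect_equal(aurocLoss(0.9, 0.45), 50)
  expect_equal(aurocLoss(0.8, 0.8), 0)
})

test_that("permuting an uninformative constant group destroys nothing", {
  fit <- smallBinaryFit()
  xz <- fit$td$x[1:400, ]
  # a column block that is constant across the evaluation set is invariant
  # under permutation, so its AUROC loss is identically zero
  xz[, c("cis09", "cis10")] <- 0
  pi <- permutationImportance(fit$model, xz, fit$td$y[1:400] == "positive",
                              list(const = c("cis09", "cis10")), seed = 3)
  expect_lt(abs(pi$loss_pct), 1)
})

test_that("the planted group dominates permutation importance", {
  fit <- smallBinaryFit()
  idx <- seq_len(min(2000L, nrow(fit$td$x)))
  groups <- list(planted_cis = c("cis01", "cis02"),
                 decoy_cis = c("cis07", "cis08"),
                 planted_trans = c("RBP001_a", "RBP001_b", "RBP002_a",
                                   "RBP002_b"),
                 decoy_trans = c("RBP015_a", "RBP015_b", "RBP016_a",
                                 "RBP016_b"))
  pi <- permutationImportance(fit$model, fit$td$x[idx, ],
                              fit$td$y[idx] == "positive", groups,
                              seed = 5, n_perm = 5)
  loss <- stats::setNames(pi$loss_pct, pi$group)
  expect_gt(loss["planted_cis"], loss["decoy_cis"])
  expect_gt(loss["planted_cis"], loss["decoy_trans"])
  expect_gt(loss["planted_trans"], loss["decoy_trans"])
  expect_error(permutationImportance(fit$model, fit$td$x[idx, ],
                                     fit$td$y[idx] == "positive",
                                     list(bad = integer()), seed = 1),
               "empty")
})

test_that("union of disjoint groups loses at least as much as either", {
  fit <- smallBinaryFit()
  idx <- seq_len(1500L)
  groups <- list(g1 = c("cis01", "cis02"),
                 g2 = c("RBP001_a", "RBP001_b", "RBP002_a", "RBP002_b"),
                 g12 = c("cis01", "cis02", "RBP001_a", "RBP001_b",
                         "RBP002_a", "RBP002_b"))
  pi <- permutationImportance(fit$model, fit$td$x[idx, ],
                              fit$td$y[idx] == "positive", groups, seed = 2)
  loss <- stats::setNames(pi$loss_pct, pi$group)
  expect_gt(loss["g12"], max(loss["g1"], loss["g2"]) - 2)
})

test_that("IG of a linear model is the closed form at any step count", {
  set.seed(6)
  w <- rnorm(7)
  f <- function(z) sum(w * z)
  attr(f, "gradient") <- function(z) w
  x <- rnorm(7); xb <- rnorm(7)
  for (steps in c(2, 11, 100)) {
    ig <- integratedGradients(f, x, xb, steps = steps)
    expect_equal(unname(ig$ig), w * (x - xb), tolerance = 1e-12)
    expect_lt(ig$residual, 1e-10)
  }
})

test_that("IG is additive over summed models", {
  set.seed(7)
  w1 <- rnorm(5); w2 <- rnorm(5)
  mk <- function(w) {
    f <- function(z) sum(w * z) + 0.5 * sum(w * z^2)
    attr(f, "gradient") <- function(z) w + w * z
    f
  }
  x <- rnorm(5); xb <- rnorm(5)
  igs <- lapply(list(mk(w1), mk(w2), mk(w1 + w2)),
                integratedGradients, x = x, baseline = xb, steps = 200)
  expect_equal(igs[[1]]$ig + igs[[2]]$ig, igs[[3]]$ig, tolerance = 1e-8)
})

test_that("IG on the dense model is complete and self-convergent", {
  fit <- smallBinaryFit()
  pos <- which(fit$td$y == "positive")[1:5]
  neg <- which(fit$td$y == "negative")[1:5]
  for (k in 1:3) {
    ig <- integratedGradients(fit$model, fit$td$x[pos[k], ],
                              fit$td$x[neg[k], ], steps = 300)
    expect_lt(ig$residual, 0.01 * max(abs(ig$fx - ig$fbaseline), 0.01))
    ig50 <- integratedGradients(fit$model, fit$td$x[pos[k], ],
                                fit$td$x[neg[k], ], steps = 50)
    ig500 <- integratedGradients(fit$model, fit$td$x[pos[k], ],
                                 fit$td$x[neg[k], ], steps = 500)
    expect_lt(max(abs(ig50$ig - ig500$ig)), 0.02)
  }
})

test_that("identical input and baseline give flagged all-zero IG", {
  fit <- smallBinaryFit()
  ig <- integratedGradients(fit$model, fit$td$x[1, ], fit$td$x[1, ])
  expect_true(ig$degenerate)
  expect_true(all(ig$ig == 0))
})

test_that("baseline representatives are the nearest to the class median", {
  # 5 candidate vectors with a hand-computable coordinate-wise median
  m <- rbind(c(0, 0), c(1, 1), c(10, 10), c(0.4, 0.6), c(2, 2))
  med <- c(1, 1)                      # column medians
  d2 <- rowSums(sweep(m, 2, med)^2)   # 2, 0, 162, 0.52, 2
  picked <- circDSC:::.nearestToMedian(m, 1:5, 1:2, 3)
  expect_equal(picked, order(d2)[1:3])
  expect_equal(picked, c(2, 4, 1))    # tie between rows 1 and 5 -> row 1
})

test_that("cis protocol recovers planted features with zero trans IG", {
  fit <- smallBinaryFit()
  corpus <- fit$corpus
  suppressWarnings(
    ac <- aigCis(fit$model, corpus$cis_norm, corpus$trans_mat,
                 corpus$ratios, corpus$organs, "O1", steps = 50,
                 max_targets = 5))
  expect_gt(ac$n_trials, 0)
  expect_identical(ac$max_trans_ig, 0)
  top3 <- names(sort(ac$values, decreasing = TRUE))[1:3]
  expect_true(all(c("cis01", "cis02") %in% top3))
})

test_that("trans protocol recovers planted RBPs with zero cis IG", {
  fit <- smallBinaryFit()
  corpus <- fit$corpus
  suppressWarnings(
    at <- aigTrans(fit$model, corpus$cis_norm, corpus$trans_mat,
                   corpus$ratios, corpus$organs, "O1", steps = 50,
                   max_circs = 5))
  expect_gt(at$n_trials, 0)
  expect_identical(at$max_cis_ig, 0)
  # the small corpus is noisy per-feature; require the planted regulators'
  # columns to carry more attribution than the decoys on average
  planted_cols <- grepl("^RBP00[12]_", names(at$values))
  expect_gt(mean(at$values[planted_cols]), mean(at$values[!planted_cols]))
})

test_that("a single sample group yields an empty trans report", {
  fit <- smallBinaryFit()
  corpus <- fit$corpus
  one <- stats::setNames(rep("O1", length(corpus$organs)),
                         names(corpus$organs))
  expect_warning(at <- aigTrans(fit$model, corpus$cis_norm,
                                corpus$trans_mat, corpus$ratios, one, "O1"),
                 "one group")
  expect_equal(at$n_trials, 0L)
})
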