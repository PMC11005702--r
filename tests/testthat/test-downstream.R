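test_that("circRNA index follows its defining identities", {
  expect_equal(circIndex(c(1, 0, 0)), 0)
  expect_equal(circIndex(c(0, 1, 0)), 1)
  expect_equal(circIndex(c(0.2, 0.3, 0.5)), 0.8 * (-0.2))
  # exchanging region and panel flips the sign exactly
  p <- cbind(runif(20, 0, 0.5), runif(20, 0, 0.3), 0)
  p[, 3] <- 1 - p[, 1] - p[, 2]
  expect_equal(circIndex(p), -circIndex(p[, c(1, 3, 2)]))
  expect_true(all(abs(circIndex(p)) <= 1))
  expect_error(circIndex(c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("tau is 1 for single-tissue, 0 for uniform circRNAs", {
  expect_equal(tauSpecificity(c(0.4, 0, 0)), 1)
  expect_equal(tauSpecificity(c(0.3, 0.3, 0.3)), 0)
  expect_equal(tauSpecificity(c(0.6, 0.3, 0.3)), 0.5)
  expect_warning(t0 <- tauSpecificity(c(0, 0, 0)), "undefined")
  expect_true(is.na(t0))
  m <- rbind(a = c(0.4, 0, 0), b = c(0.2, 0.2, 0.2))
  expect_equal(unname(tauSpecificity(m)), c(1, 0))
})

test_that("consistency calls apply both 0.35 thresholds strictly", {
  up4 <- matrix(c(rep(0.5, 4), rep(0.1, 6)), 1)     # 4/10 pairs up
  none <- matrix(0.1, 1, 10)
  r <- consistentRegulation(rbind(up4, none), matrix(0.1, 2, 10))
  expect_equal(r$call, c("up", "none"))
  # 3 up and 3 down of 10: both at 30 %, below the cut
  pc <- matrix(c(rep(0.6, 3), rep(0.1, 7)), 1)
  pd <- matrix(c(rep(0.1, 7), rep(0.6, 3)), 1)
  expect_equal(consistentRegulation(pc, pd)$call, "none")
  # hand-checked 3 x 4 table
  pc3 <- rbind(e1 = c(0.9, 0.8, 0.4, 0.1), e2 = c(0.1, 0.1, 0.1, 0.1),
               e3 = c(0.36, 0.2, 0.1, 0.2))
  pd3 <- rbind(e1 = c(0.0, 0.1, 0.1, 0.2), e2 = c(0.5, 0.5, 0.1, 0.1),
               e3 = c(0.1, 0.1, 0.1, 0.1))
  r3 <- consistentRegulation(pc3, pd3)
  expect_equal(r3$call, c("up", "down", "none"))   # e3: 1/4 = 25 % < 35 %
  expect_error(consistentRegulation(matrix(0, 1, 0), matrix(0, 1, 0)),
               "zero")
})

test_that("raising an up-probability never demotes a consistent-up call", {
  set.seed(40)
  pc <- matrix(runif(50), 5, 10)
  pd <- matrix(runif(50, 0, 0.2), 5, 10)
  base <- consistentRegulation(pc, pd)$call
  pc2 <- pc; pc2[, 1] <- pmin(pc[, 1] + 0.5, 1)
  raised <- consistentRegulation(pc2, pd)$call
  expect_true(all(!(base == "up" & raised != "up")))
})

test_that("enrichment matches the sample odds ratio and exact tails", {
  uni <- paste0("c", 1:100)
  # table (10, 10, 10, 70)
  res <- enrichmentTest(paste0("c", 1:20), paste0("c", c(1:10, 21:30)), uni)
  expect_equal(unname(res$table), c(10, 10, 10, 70))
  expect_equal(res$odds_ratio, 7)
  # exhaustive hypergeometric tail on a 20-element universe
  u20 <- paste0("u", 1:20)
  pred <- paste0("u", 1:10); ref <- paste0("u", 6:15)
  res20 <- enrichmentTest(pred, ref, u20)
  tail_exact <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(10, 10 - k), numeric(1))) / choose(20, 10)
  expect_equal(res20$p_value, tail_exact)
  expect_equal(res20$p_value,
               fisher.test(matrix(unname(res20$table), 2, byrow = TRUE),
                           alternative = "greater")$p.value)
  # empty predicted set
  e0 <- enrichmentTest(character(), ref, u20)
  expect_true(is.na(e0$odds_ratio))
  expect_equal(e0$p_value, 1)
  # zero cell -> continuity-corrected OR, flagged
  rz <- enrichmentTest(paste0("u", 1:5), paste0("u", 1:5), u20)
  expect_true(rz$or_corrected)
  expect_error(enrichmentTest("a", "a", character()), "universe")
})

test_that("exact Wilcoxon path agrees with full enumeration up to n = 8", {
  vecs <- list(c(0.3, 0.3, 0.3, 0, 0, 0, 0),
               c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
               c(0, 0, 0.1, 0.2, 0.2, 0.3),
               c(1, 1, 1, 1, 0, 0, 0, 0))
  for (v in vecs) {
    n <- length(v)
    for (nx in 1:(n - 1)) {
      r <- rank(v)
      obs <- sum(r[seq_len(nx)])
      cmb <- utils::combn(n, nx)
      p_enum <- mean(apply(cmb, 2, function(ix) sum(r[ix]) >= obs))
      p_dp <- wilcoxRankSum(v[seq_len(nx)], v[-seq_len(nx)])$p_value
      expect_equal(p_dp, p_enum, tolerance = 1e-12,
                   info = paste(paste(v, collapse = ","), nx))
    }
  }
})

test_that("the documented exact example gives p = 1/35", {
  w <- wilcoxRankSum(c(0.3, 0.3, 0.3), c(0, 0, 0, 0))
  expect_true(w$exact)
  expect_equal(w$p_value, 1 / 35)
})

test_that("large samples switch to the tie-corrected normal path", {
  set.seed(50)
  x <- rnorm(20, 1); y <- rnorm(20)
  w <- wilcoxRankSum(x, y)
  expect_false(w$exact)
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(w$p_value, ref, tolerance = 1e-9)
})

test_that("marker criteria require all three conditions", {
  # exactly 5 expressing cells fails the strict > 5 rule
  type <- rep(c("T1", "T2"), c(5, 10))
  bsj <- c(rep(3L, 5), rep(0L, 10))
  fsj <- c(rep(3L, 5), rep(10L, 10))
  suppressWarnings(mc <- markerCriteria(type, bsj, fsj))
  expect_false(mc$marker[mc$cell_type == "T1"])
  # 7 expressing cells, high ratio, clean separation -> marker
  type2 <- rep(c("T1", "T2"), c(7, 8))
  bsj2 <- c(rep(5L, 7), rep(1L, 8))
  fsj2 <- c(rep(5L, 7), rep(60L, 8))
  mc2 <- markerCriteria(type2, bsj2, fsj2)
  expect_true(mc2$marker[mc2$cell_type == "T1"])
  # low mean ratio fails regardless of the test
  bsj3 <- c(rep(1L, 7), rep(1L, 8))
  fsj3 <- c(rep(60L, 7), rep(60L, 8))
  mc3 <- markerCriteria(type2, bsj3, fsj3)
  expect_false(any(mc3$marker))
  expect_warning(m0 <- markerCriteria(type2, rep(0L, 15), rep(1L, 15)),
                 "not expressed")
  expect_null(m0)
})

test_that("marker accuracy counts TP and TN over cell types", {
  p <- c(T1 = 0.9, T2 = 0.8, T3 = 0.1, T4 = 0.2)
  expect_equal(markerAccuracy(p, c("T1", "T2")), 1)
  expect_equal(markerAccuracy(c(T1 = 0.1, T2 = 0.9, T3 = 0.1, T4 = 0.1),
                              "T1"), 0.5)
  expect_error(markerAccuracy(numeric(), "T1"), "no cell types")
  # uniform-random null accuracy matches the Bernoulli expectation
  set.seed(60)
  accs <- replicate(1e4, {
    markerAccuracy(stats::setNames(runif(4), paste0("T", 1:4)), "T1")
  })
  expect_equal(mean(accs), (0.65 + 3 * 0.35) / 4, tolerance = 0.01)
})

test_that("LASSO recovers a sparse noiseless proportion map", {
  set.seed(3)
  X <- matrix(runif(200 * 36), 200, 36,
              dimnames = list(NULL, paste0("p", 1:36)))
  beta <- numeric(36); beta[c(2, 7, 30)] <- c(0.5, -0.3, 0.4)
  y <- as.numeric(0.2 + X %*% beta)
  fit <- lassoProportions(X, cbind(myeloid = pmin(pmax(y, 0), 1)),
                          folds = 10, seed = 1)
  expect_gt(cor(fit$myeloid$fitted, y), 0.99)
  expect_true(all(paste0("p", c(2, 7, 30)) %in% fit$myeloid$support))
})

test_that("degenerate LASSO designs give intercept-only fits", {
  X <- matrix(1, 30, 5, dimnames = list(NULL, paste0("p", 1:5)))
  y <- runif(30, 0.2, 0.4)
  fit <- lassoProportions(X, y, folds = 5, seed = 1)
  expect_equal(fit$target$fitted, rep(mean(y), 30))
  expect_equal(length(fit$target$support), 0L)
  expect_error(lassoProportions(matrix(runif(10), 5, 2), runif(5),
                                folds = 10), "folds")
})

test_that("specific circRNA selection is tau-ordered and decorrelated", {
  set.seed(70)
  base <- runif(50)
  probs <- cbind(a = base, b = base + rnorm(50, 0, 0.01),
                 c = runif(50), d = runif(50))
  tau <- c(a = 0.95, b = 0.9, c = 0.85, d = 0.5)
  sel <- selectSpecificCircs(tau, probs, tau_thr = 0.75, r_max = 0.5)
  expect_equal(sel[1], "a")
  expect_false("b" %in% sel)      # near-duplicate of a
  expect_true("c" %in% sel)
  expect_false("d" %in% sel)      # below the tau threshold
})
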