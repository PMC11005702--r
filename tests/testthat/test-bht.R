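test_that("posteriors match an independent brute-force quadrature", {
  b <- bhtBattery()[1:8, ]                   # subset keeps this test quick
  fl <- bhtFlat(b$bA, b$fA, b$bB, b$fB)
  oracle <- mapply(bruteBht, b$bA, b$fA, b$bB, b$fB)
  expect_lt(max(abs(fl$p_diff - oracle)), 1e-3)
  ii <- bhtInfo(b$bA, b$fA, b$bB, b$fB, prior_q = 0.8)
  oracle_i <- mapply(function(...) bruteBht(..., q = 0.8),
                     b$bA, b$fA, b$bB, b$fB)
  expect_lt(max(abs(ii$p_diff - oracle_i)), 1e-3)
})

test_that("identical extreme data concentrate the posterior near zero", {
  r <- bhtFlat(0, 200, 0, 200)
  expect_lt(r$p_diff, 0.1)
  expect_equal(r$direction, "none")
})

test_that("strongly opposed counts give a confident directional call", {
  r <- bhtFlat(80, 20, 5, 95)
  expect_gt(r$p_diff, 0.9)
  expect_equal(r$direction, "higher_in_A")
  expect_equal(r$mle_delta, 2 * 80 / (2 * 80 + 20) - 2 * 5 / (2 * 5 + 95))
})

test_that("flat posterior is invariant under sample swap; direction flips", {
  b <- bhtBattery()[c(2, 5, 11, 17), ]
  fwd <- bhtFlat(b$bA, b$fA, b$bB, b$fB)
  rev <- bhtFlat(b$bB, b$fB, b$bA, b$fA)
  expect_equal(fwd$p_diff, rev$p_diff, tolerance = 1e-12)
  expect_equal(fwd$mle_delta, -rev$mle_delta)
  # info model: swap of samples and of the prior components together
  ii <- bhtInfo(b$bA, b$fA, b$bB, b$fB, prior_q = 0.7)
  ir <- bhtInfo(b$bB, b$fB, b$bA, b$fA, prior_q = 0.7)
  expect_equal(ii$p_diff, ir$p_diff, tolerance = 1e-12)
})

test_that("informative posterior is monotone in the prior", {
  qs <- c(0, 0.1, 0.5, 0.9, 1)
  p <- vapply(qs, function(q) bhtInfo(3, 30, 9, 24, prior_q = q)$p_diff,
              numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1], 0)
  expect_equal(p[5], 1)
  # prior_q = 0.5 preserves the flat model's ordering over events
  b <- bhtBattery()
  fl <- bhtFlat(b$bA, b$fA, b$bB, b$fB)$p_diff
  i5 <- bhtInfo(b$bA, b$fA, b$bB, b$fB, prior_q = 0.5)$p_diff
  expect_equal(order(fl), order(i5))
  expect_error(bhtInfo(1, 1, 1, 1, prior_q = 1.2), "0,1")
})

test_that("posteriors converge to 0/1 as counts scale", {
  # true delta psi > C: psi 0.4 vs 0.2 (c = 2)
  ks <- c(1, 5, 25, 125)
  p_diffm <- vapply(ks, function(k)
    bhtFlat(25 * k, 75 * k, 11 * k, 89 * k)$p_diff, numeric(1))
  expect_true(all(diff(p_diffm) > -1e-9))   # saturates at 1
  expect_gt(p_diffm[4], 0.999)
  p_same <- vapply(ks, function(k)
    bhtFlat(25 * k, 75 * k, 25 * k, 75 * k)$p_diff, numeric(1))
  expect_true(all(diff(p_same) < 1e-9))
  expect_lt(p_same[4], 0.01)
})

test_that("all-zero counts are flagged and report the prior mass", {
  r <- bhtFlat(0, 0, 0, 0)
  expect_false(r$defined)
  ri <- bhtInfo(0, 0, 0, 0, prior_q = 0.3)
  expect_false(ri$defined)
  expect_equal(ri$p_diff, 0.3)
})

test_that("the plain-proportion convention (c = 1) is selectable", {
  r2 <- bhtFlat(30, 70, 10, 90, c = 2)
  r1 <- bhtFlat(30, 70, 10, 90, c = 1)
  expect_equal(r1$mle_delta, 0.3 - 0.1)
  expect_equal(r2$mle_delta, 60 / 130 - 20 / 110)
  oracle1 <- bruteBht(30, 70, 10, 90, conv = 1)
  expect_lt(abs(r1$p_diff - oracle1), 1e-3)
})

test_that("count filters drop exactly the printed boundary cases", {
  # BSJ must be > 2: a BSJ of exactly 2 fails
  lab <- makeTrainingLabels(2, 25, 10, 25)
  expect_false(lab$kept[1])
  # BSJ + FSJ must be > 20: 10 + 9 = 19 fails in both samples
  lab2 <- makeTrainingLabels(10, 9, 10, 9)
  expect_false(lab2$kept[1])
  # FSJ must be > 2 as well
  lab3 <- makeTrainingLabels(30, 2, 30, 40)
  expect_false(lab3$kept[1])
  lab4 <- makeTrainingLabels(30, 40, 30, 40)
  expect_true(lab4$kept[1])
})

test_that("the labeler reproduces oracle-derived survivors and classes", {
  # 5 events engineered around the filters and posterior cuts
  bA <- c(2, 10, 80, 30, 12)
  fA <- c(25, 9, 20, 570, 88)
  bB <- c(10, 10, 5, 30, 30)
  fB <- c(25, 9, 95, 570, 70)
  lab <- makeTrainingLabels(bA, fA, bB, fB,
                            event_id = paste0("t", 1:5))
  expect_equal(lab$kept, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  oracle <- mapply(bruteBht, bA[3:5], fA[3:5], bB[3:5], fB[3:5])
  expected <- ifelse(oracle > 0.9, "positive",
                     ifelse(oracle < 0.1, "negative", "ambiguous"))
  expect_equal(lab$label[3:5], expected)
  expect_equal(sum(lab$label == "positive", na.rm = TRUE), 2L)
  expect_equal(lab$class3[3], "higher_in_A")
})

test_that("doubling the quadrature grid barely moves the posterior", {
  b <- bhtBattery()[seq(1, 19, by = 3), ]
  p1 <- bhtFlat(b$bA, b$fA, b$bB, b$fB, grid = 201)$p_diff
  p2 <- bhtFlat(b$bA, b$fA, b$bB, b$fB, grid = 402)$p_diff
  expect_lt(max(abs(p1 - p2)), 1e-3)
})
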