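test_that("frequencies are exact dilution-corrected ratios", {
  f <- frequencies(platingExperiment(1000L, 500L, 0L))
  expect_equal(f$survival, 0.5)
  expect_equal(f$translocFreq, 0)
  # counts chosen to give the wild-type frequency exactly
  f2 <- frequencies(platingExperiment(1e6, 9e5, 270L))
  expect_equal(f2$translocFreq, 0.27e-3)
  # random counts against a hand-rolled ratio oracle
  set.seed(21)
  for (k in 1:25) {
    sc <- sample(1:5000, 1); sg <- sample(0:5000, 1); sl <- sample(0:100, 1)
    d <- runif(3, 0.5, 100)
    f3 <- frequencies(platingExperiment(sc, sg, sl, d[1], d[2], d[3]))
    expect_equal(f3$survival, (sg * d[2]) / (sc * d[1]))
    expect_equal(f3$translocFreq, (sl * d[3]) / (sc * d[1]))
  }
  expect_error(frequencies(platingExperiment(0L, 1L, 1L)), "undefined-frequency")
})

test_that("fold changes follow the reporting rounding rule", {
  expect_equal(foldChange(0.27, 0.01)$label, "27-fold decrease")
  expect_equal(foldChange(1.49, 0.005)$label, "300-fold decrease")  # 298 -> 1 sf
  expect_equal(foldChange(0.4, 0.4)$label, "1-fold")
  expect_error(foldChange(0, 1), "undefined")
  # symmetric magnitude, opposite direction
  set.seed(31)
  for (k in 1:20) {
    a <- runif(1, 0.001, 10); b <- runif(1, 0.001, 10)
    fab <- foldChange(a, b); fba <- foldChange(b, a)
    expect_equal(fab$rounded, fba$rounded)
    if (a != b) expect_false(fab$direction == fba$direction)
  }
})

test_that("exact Mann-Whitney p equals full enumeration for small groups", {
  r <- mannWhitney(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / choose(8, 4))
  expect_true(r$exact)
  set.seed(41)
  for (k in 1:30) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    x <- sample(1:1000, nA + nB)          # distinct -> no ties
    a <- x[seq_len(nA)]; b <- x[-seq_len(nA)]
    expect_equal(mannWhitney(a, b)$p, enumMW(a, b), tolerance = 1e-12)
  }
  # identical tied groups: maximal p via the approximation
  expect_gt(mannWhitney(c(1, 1, 2), c(1, 2, 2))$p, 0.5)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

# textbook Pearson chi-square on a 2 x k table
chisqOracle <- function(a, b) {
  m <- rbind(a, b); m <- m[, colSums(m) > 0, drop = FALSE]
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(chi2 = sum((m - e)^2 / e), df = ncol(m) - 1)
}

test_that("repair-type distribution comparisons match the textbook formula", {
  wt <- c(I = 16, II = 5, III = 2, IV = 1)
  tel1 <- c(I = 9, II = 6, III = 4, IV = 8)
  got <- compareTypeDistributions(wt, tel1)
  ora <- chisqOracle(wt, tel1)
  expect_equal(got$chi2, ora$chi2)
  expect_equal(got$df, ora$df)
  expect_equal(got$p, stats::pchisq(ora$chi2, ora$df, lower.tail = FALSE))
  # 2x2 collapse (Type I vs rest) against the closed form
  a2 <- c(I = 16, rest = 8); b2 <- c(I = 9, rest = 18)
  g2 <- compareTypeDistributions(a2, b2)
  a <- 16; b <- 8; c <- 9; d <- 18; n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(g2$chi2, closed)
  # identical distributions: chi2 = 0, p = 1
  same <- compareTypeDistributions(wt, wt)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_gte(got$chi2, 0)
  expect_error(compareTypeDistributions(wt, c(X = 1, Y = 2)), "mismatch")
})

test_that("chi-square is zero iff the distributions are proportional", {
  a <- c(I = 4, II = 8, III = 2, IV = 6)
  expect_equal(compareTypeDistributions(a, 3 * a)$chi2, 0)
  expect_gt(compareTypeDistributions(a, c(I = 8, II = 4, III = 2, IV = 6))$chi2, 0)
})

test_that("frequency estimator is unbiased over simulated platings", {
  trueFreq <- 0.27e-3
  est <- vapply(1:500, function(k)
    frequencies(simulatePlating(trueFreq, 1e6, seed = 1000 + k))$translocFreq,
    numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - trueFreq), 3 * se)
})
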