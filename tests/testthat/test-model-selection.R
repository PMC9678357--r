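test_that("AICc follows the small-sample closed form and its domain rules", {
  expect_equal(aiccFromFit(0, k = 2, n = 10), 4 + 12 / 7)
  # correction vanishes for large n
  expect_equal(aiccFromFit(0, k = 2, n = 1e7), 4, tolerance = 1e-5)
  # n = k + 2 is the smallest valid sample; n = k + 1 is degenerate
  expect_silent(aiccFromFit(-5, k = 3, n = 5))
  expect_error(aiccFromFit(-5, k = 3, n = 4), "n > k")
  # monotone decreasing in n at fixed logLik, k
  vals <- vapply(6:40, function(n) aiccFromFit(-10, 4, n), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("Akaike probability reproduces the pairwise-evidence formula", {
  expect_equal(akaikeProbability(-10, -10)@probability, 0.5)
  # delta-AICc = 2 corresponds to 73.11% evidence
  p2 <- akaikeProbability(0, -2)
  expect_equal(p2@probability, exp(1) / (1 + exp(1)))
  expect_equal(round(100 * p2@probability, 2), 73.11)
  expect_false(p2@decisive)
  # complementary probabilities sum to one and grow with the difference
  D <- seq(-6, 6, by = 0.5)
  pD <- plogis(0.5 * D)
  expect_equal(pD + rev(pD), rep(1, length(D)))
  expect_true(all(diff(pD) > 0))
  expect_error(akaikeProbability(NA, 1), "finite")
})

test_that("printed AICc pairs give the published model probabilities", {
  # caudal forelimb area, white matter: quadratic at 99.98%
  cfaW <- akaikeProbability(-682.2, -699.8, c("linear", "quadratic"))
  expect_identical(cfaW@preferred, "quadratic")
  expect_equal(round(100 * cfaW@probability, 2), 99.98)
  expect_true(cfaW@decisive)
  # caudal forelimb area, gray matter: quadratic above 99.99%
  cfaG <- akaikeProbability(-1337, -1358, c("linear", "quadratic"))
  expect_gt(100 * cfaG@probability, 99.99)
  # fMRI VOI, white matter: linear below 0.01%
  fmriW <- akaikeProbability(-664.3, -686.6, c("linear", "quadratic"))
  expect_lt(100 * (1 - fmriW@probability), 0.01)
})

test_that("trajectory comparison picks the lowest AICc with the delta rule", {
  mkFits <- function(aiccs, ks = c(3, 4)) {
    # invert AICc to logLik so compareTrajectories recomputes consistently
    n <- 60
    data.frame(model = names(aiccs), k = ks, n = n,
               logLik = mapply(function(a, k)
                 -(a - 2 * k - 2 * k * (k + 1) / (n - k - 1)) / 2,
                 aiccs, ks))
  }
  cmp <- compareTrajectories(mkFits(c(linear = -10, quadratic = -15)))
  expect_identical(cmp@preferred, "quadratic")
  expect_equal(cmp@delta, 5)
  expect_true(cmp@decisive)

  cmp2 <- compareTrajectories(mkFits(c(linear = -10, quadratic = -11)))
  expect_identical(cmp2@preferred, "quadratic")
  expect_equal(cmp2@delta, 1)
  expect_false(cmp2@decisive)

  # rostral forelimb area WMV row: quadratic by 0.53, not decisive
  cmp3 <- compareTrajectories(mkFits(c(linear = -94.80, quadratic = -95.33)))
  expect_identical(cmp3@preferred, "quadratic")
  expect_equal(cmp3@delta, 0.53, tolerance = 1e-9)
  expect_false(cmp3@decisive)

  # ties break toward fewer parameters
  tie <- compareTrajectories(mkFits(c(quadratic = -12, linear = -12),
                                    ks = c(4, 3)))
  expect_identical(tie@preferred, "linear")

  bad <- mkFits(c(linear = -10, quadratic = -15))
  bad$n <- c(60, 50)
  expect_error(compareTrajectories(bad), "incomparable")
})

test_that("comparison tables serialize with two-decimal percentages", {
  fits <- rbind(modelFit("linear", -5, 3, 30),
                modelFit("asymptotic", -2, 3, 30))
  cmp <- compareTrajectories(fits)
  f <- tempfile(fileext = ".tsv")
  writeComparisonTsv(cmp, f)
  tab <- read.delim(f)
  expect_identical(names(tab), c("model", "k", "n", "logLik", "AIC", "AICc",
                                 "deltaAICc", "probability_pct"))
  expect_identical(tab$model[1], "asymptotic")
  expect_equal(tab$probability_pct[1],
               round(100 * cmp@probability, 2))
})
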