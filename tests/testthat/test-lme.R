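subjects6 <- data.frame(id = sprintf("s%d", 1:6),
                        group = rep(c("trained", "control"), each = 3),
                        tiv = c(400, 410, 420, 405, 415, 425))
days6 <- c(0, 2, 6, 8, 10, 14)

test_that("a pure time course with no group difference yields beta3 = 0", {
  panel <- plastimap:::.buildPanel(subjects6, days6, shape = "asymptotic")
  fit <- fitVoxelLme(panel$f, panel)
  expect_lt(abs(fit$beta3), 1e-6)
})

test_that("voxel logLik matches brute-force marginal-likelihood maximization", {
  set.seed(42)
  subj <- data.frame(id = sprintf("s%d", 1:4),
                     group = rep(c("trained", "control"), each = 2),
                     tiv = c(400, 420, 410, 430))
  for (shape in c("linear", "asymptotic")) {
    panel <- plastimap:::.buildPanel(subj, c(0, 6, 14), shape = shape)
    y <- 0.8 + 0.05 * panel$group * panel$f +
      rnorm(4, 0, 0.02)[as.integer(panel$subject)] +
      rnorm(4, 0, 0.01)[as.integer(panel$subject)] * panel$f +
      rnorm(nrow(panel), 0, 0.01)
    fit <- fitVoxelLme(y, panel)
    expect_equal(fit$logLik, lmeLogLikOracle(y, panel), tolerance = 1e-4)
  }
})

test_that("interaction CIs achieve nominal coverage under the generative model", {
  set.seed(123)
  subj <- data.frame(id = sprintf("s%02d", 1:40),
                     group = rep(c("trained", "control"), each = 20),
                     tiv = rnorm(40, 415, 20))
  panel <- plastimap:::.buildPanel(subj, days6, shape = "asymptotic")
  g <- panel$group; f <- panel$f; si <- as.integer(panel$subject)
  hits <- 0
  for (i in 1:100) {
    y <- 0.8 + 0.05 * g * f + rnorm(40, 0, 0.02)[si] +
      rnorm(40, 0, 0.01)[si] * f + rnorm(nrow(panel), 0, 0.01)
    fit <- fitVoxelLme(y, panel)
    ci <- fit$beta3 + c(-1, 1) * qnorm(0.975) * fit$se3
    if (ci[1] <= 0.05 && 0.05 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("fits are invariant to subject order and TIV rescaling", {
  set.seed(77)
  panel <- plastimap:::.buildPanel(subjects6, days6, shape = "linear")
  y <- 0.8 + 0.03 * panel$group * panel$f +
    rnorm(6, 0, 0.02)[as.integer(panel$subject)] + rnorm(nrow(panel), 0, 0.01)
  fit <- fitVoxelLme(y, panel)
  # permute rows
  perm <- sample(nrow(panel))
  fitP <- fitVoxelLme(y[perm], panel[perm, ])
  expect_equal(fitP$beta3, fit$beta3, tolerance = 1e-6)
  expect_equal(fitP$logLik, fit$logLik, tolerance = 1e-6)
  # rescale TIV: beta1 rescales inversely, interaction unchanged
  panel2 <- panel
  panel2$tiv <- panel$tiv * 10
  fitS <- fitVoxelLme(y, panel2)
  expect_equal(fitS$beta3, fit$beta3, tolerance = 1e-6)
  expect_equal(fitS$beta[["tiv"]], fit$beta[["tiv"]] / 10, tolerance = 1e-4)
})

test_that("degenerate and constant voxels are flagged with p = 1", {
  panel <- plastimap:::.buildPanel(subjects6, days6, shape = "linear")
  fit <- fitVoxelLme(rep(0.8, nrow(panel)), panel)
  expect_true(fit$degenerate)
  expect_equal(fit$p3, 1)
  expect_false(fit$converged)
})

test_that("the batch driver reproduces single-voxel fits", {
  set.seed(31)
  subj <- data.frame(id = sprintf("s%02d", 1:12),
                     group = rep(c("trained", "control"), each = 6),
                     tiv = rnorm(12, 415, 20))
  panel <- plastimap:::.buildPanel(subj, days6, shape = "quadratic")
  Y <- vapply(1:4, function(i)
    0.8 + 0.04 * panel$group * panel$f +
      rnorm(12, 0, 0.02)[as.integer(panel$subject)] +
      rnorm(nrow(panel), 0, 0.01),
    numeric(nrow(panel)))
  batch <- plastimap:::.fitVoxelBatch(Y, panel)
  for (i in 1:4) {
    single <- fitVoxelLme(Y[, i], panel)
    expect_equal(batch$beta3[i], single$beta3, tolerance = 1e-5)
    expect_equal(batch$se3[i], single$se3, tolerance = 1e-4)
    expect_equal(batch$logLik[i], single$logLik, tolerance = 1e-4)
    expect_equal(batch$k[i], single$k)
  }
})

test_that("missing sessions produce an unbalanced panel, not an error", {
  miss <- matrix(FALSE, 6, 6)
  miss[1, 1:2] <- TRUE
  panel <- plastimap:::.buildPanel(subjects6, days6, missing = miss,
                                   shape = "asymptotic")
  expect_equal(nrow(panel), 34)
  set.seed(8)
  y <- 0.8 + 0.05 * panel$group * panel$f + rnorm(nrow(panel), 0, 0.01)
  fit <- fitVoxelLme(y, panel)
  expect_true(fit$converged)
  expect_equal(fit$n, 34)
})
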