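test_that("trajectory bases are anchored, bounded and shaped as specified", {
  days <- c(0, 2, 6, 8, 10, 14)
  for (s in c("linear", "asymptotic", "quadratic")) {
    f <- trajectoryBasis(s, days, 14)
    expect_equal(f[1], 0)            # all curves start at baseline
    expect_true(all(abs(f) <= 1))
  }
  expect_equal(trajectoryBasis("asymptotic", 14, 14), 1)  # plateau endpoint
  expect_equal(trajectoryBasis("quadratic", 14, 14), 0)   # renormalization
  expect_equal(trajectoryBasis("quadratic", 7, 14), 1)    # mid-course peak
  expect_equal(trajectoryBasis("linear", 7, 14), 0.5)
  expect_error(trajectoryBasis("linear", 15, 14), "within")
  expect_error(trajectoryBasis("linear", -1, 14), "within")
})

test_that("BH step-up rejects exactly the hand-computed set", {
  r <- fdrBH(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$threshold, 0.04)
  expect_false(any(fdrBH(c(0.9, 0.95), 0.05)$reject))
  expect_true(fdrBH(0.049, 0.05)$reject)   # m = 1: raw comparison
  expect_false(fdrBH(0.051, 0.05)$reject)
  expect_length(fdrBH(numeric(0), 0.05)$reject, 0)
  # agreement with the step-up definition on random vectors
  set.seed(4)
  for (i in 1:10) {
    p <- runif(50)^2
    r <- fdrBH(p, 0.05)
    ps <- sort(p)
    k <- which(ps <= seq_along(ps) * 0.05 / length(ps))
    expected <- if (length(k)) p <= ps[max(k)] else rep(FALSE, length(p))
    expect_identical(r$reject, expected)
  }
})

test_that("cluster volumes convert counts exactly and scale as count * h^3", {
  expect_equal(clusterVolume(78442, 0.08), 40.16)
  expect_equal(clusterVolume(109811, 0.08), 56.22)
  expect_equal(clusterVolume(33817, 0.08), 17.31)
  expect_equal(clusterVolume(0, 0.08), 0)
  expect_equal(clusterVolume(1000, 0.1), 1)
  # linear in count, cubic in voxel size (exact)
  expect_equal(clusterVolume(2 * 777, 0.08, digits = Inf),
               2 * clusterVolume(777, 0.08, digits = Inf))
  expect_equal(clusterVolume(777, 0.16, digits = Inf),
               8 * clusterVolume(777, 0.08, digits = Inf))
  expect_error(clusterVolume(-1, 0.08), "non-negative")
})

test_that("Gaussian smoothing preserves totals and converts FWHM correctly", {
  v <- array(0, c(21, 21, 21))
  v[11, 11, 11] <- 1
  sm <- smoothVolume(v, fwhm = 0.4, voxelSize = 0.08)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm), which.max(v))
  # impulse response sd equals fwhm / (2 sqrt(2 log 2)) in voxels
  prof <- sm[, 11, 11]
  sdEmp <- sqrt(sum(prof * (seq_len(21) - 11)^2) / sum(prof))
  expect_equal(sdEmp, 0.4 / (2 * sqrt(2 * log(2))) / 0.08, tolerance = 0.01)
  expect_identical(smoothVolume(v, 0), v)
  # total preserved for a random field too
  set.seed(9)
  r <- array(runif(8000), c(20, 20, 20))
  expect_equal(sum(smoothVolume(r, 0.4, 0.08)), sum(r), tolerance = 1e-6)
})

test_that("tissue-probability masking is inclusive at the threshold", {
  expect_identical(as.vector(tpmMask(array(c(0.1, 0.2, 0.3), c(3, 1, 1)))),
                   c(FALSE, TRUE, TRUE))
  expect_false(any(tpmMask(array(0, c(2, 2, 2)))))
  expect_true(all(tpmMask(array(0.5, c(2, 2, 2)))))
  expect_error(tpmMask(array(1.5, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("VOI extraction normalizes to the control group per session", {
  sim <- simLongitudinalVolumes(seed = 5, nPerGroup = 4, grid = c(6, 6, 6),
                                effectAmplitude = 0, noiseSd = 0,
                                ranInterceptSd = 0, ranSlopeSd = 0)
  series <- sim$series
  # trained values at 0.95 x control everywhere
  d <- series@data
  trained <- series@subjects$group == "trained"
  d[trained, , , , ] <- 0.95 * d[trained, , , , ]
  series@data <- d
  voi <- array(FALSE, c(6, 6, 6)); voi[2:4, 2:4, 2:4] <- TRUE
  m <- extractVoi(series, voi)
  expect_equal(unname(m[trained, ]), matrix(0.95, 4, 6))
  expect_equal(unname(m[!trained, ]), matrix(1, 4, 6))
  # identical groups give the identity trajectory
  m2 <- extractVoi(sim$series, voi)
  expect_equal(unname(m2), matrix(1, 8, 6))
  zero <- series; zero@data[] <- 0
  expect_error(extractVoi(zero, voi), "control-group mean")
  expect_error(extractVoi(series, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("per-subject trajectory AICc separates asymptotic from linear", {
  days <- c(0, 2, 6, 8, 10, 14)
  yAsym <- 1 + 0.05 * trajectoryBasis("asymptotic", days, 14)
  a <- subjectTrajectoryAicc(yAsym, days)
  expect_lt(a[["asymptotic"]], a[["linear"]])
  # flat trajectories tie within the shared small-sample correction
  set.seed(2)
  yFlat <- rep(1, 6) + rnorm(6, 0, 1e-4)
  aF <- subjectTrajectoryAicc(yFlat, days)
  expect_lt(abs(aF[["asymptotic"]] - aF[["linear"]]), 2)
  expect_error(subjectTrajectoryAicc(c(1, 2, 3), c(0, 2, 6)), "at least 4")
})
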