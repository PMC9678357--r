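test_that("generators are deterministic given a seed", {
  a <- simLongitudinalVolumes(seed = 4, nPerGroup = 3, grid = c(4, 4, 4))
  b <- simLongitudinalVolumes(seed = 4, nPerGroup = 3, grid = c(4, 4, 4))
  expect_identical(a$series@data, b$series@data)
  expect_identical(a$series@subjects, b$series@subjects)

  f1 <- simFiberStack(seed = 2, dims = c(y = 32, x = 32, z = 12), nFibers = 3)
  f2 <- simFiberStack(seed = 2, dims = c(y = 32, x = 32, z = 12), nFibers = 3)
  expect_identical(intensity(f1$stack), intensity(f2$stack))
  expect_identical(f1$truth$totalLength, f2$truth$totalLength)

  s1 <- simSection(seed = 3)
  s2 <- simSection(seed = 3)
  expect_identical(s1$image, s2$image)

  t1 <- simBehaviorSessions(seed = 6, nAnimals = 2)
  t2 <- simBehaviorSessions(seed = 6, nAnimals = 2)
  expect_identical(t1, t2)

  # different seeds differ
  expect_false(identical(simSection(seed = 3)$image,
                         simSection(seed = 4)$image))
})

test_that("noise-free volumes follow the stated generative identities", {
  sim <- simLongitudinalVolumes(seed = 1, nPerGroup = 3, grid = c(6, 6, 6),
                                effectShape = "asymptotic",
                                effectAmplitude = -0.05, noiseSd = 0,
                                ranInterceptSd = 0, ranSlopeSd = 0)
  dat <- sim$series@data
  ctrl <- sim$series@subjects$group == "control"
  f <- trajectoryBasis("asymptotic", sessionDays(sim$series), 14)
  # controls are exactly constant
  for (s in which(ctrl))
    expect_equal(max(abs(sweep(dat[s, , , , ], 2:4, dat[s, 1, , , ]))), 0)
  # trained in-region trajectories are exactly baseline(1 + a f(t))
  reg <- which(sim$truth)[1]
  regIdx <- arrayInd(reg, c(6, 6, 6))
  tr <- which(!ctrl)[1]
  expect_equal(dat[tr, , regIdx[1], regIdx[2], regIdx[3]],
               0.8 * (1 - 0.05 * f), tolerance = 1e-12)
  # out-of-region trained voxels carry no effect
  out <- which(!sim$truth)[1]
  outIdx <- arrayInd(out, c(6, 6, 6))
  expect_equal(dat[tr, , outIdx[1], outIdx[2], outIdx[3]], rep(0.8, 6),
               tolerance = 1e-12)
  expect_error(simLongitudinalVolumes(effectRegion = array(TRUE, c(2, 2, 2)),
                                      grid = c(4, 4, 4)),
               "outside")
})

test_that("staggered entry marks early sessions missing for trained subjects", {
  sim <- simLongitudinalVolumes(seed = 2, nPerGroup = 6, grid = c(4, 4, 4),
                                dropout = 0.5)
  miss <- missingSessions(sim$series)
  trained <- sim$series@subjects$group == "trained"
  expect_equal(sum(rowSums(miss[trained, ]) > 0), 3)
  expect_true(all(!miss[, 3:6]))
  expect_false(any(miss[!trained, ]))
})

test_that("fiber ground truth is exact bookkeeping of the polylines", {
  sim <- simFiberStack(seed = 7, dims = c(y = 48, x = 48, z = 16),
                       nFibers = 4)
  recomputed <- sum(vapply(sim$truth$polylines, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1)))
  expect_equal(sim$truth$totalLength, recomputed, tolerance = 1e-6)
  expect_true(all(vapply(sim$truth$polylines, function(p)
    all(p[, "z"] <= sim$truth$plateauDepth), logical(1))))
})

test_that("a shallow labeling plateau is rejected by the depth rule", {
  sim <- simFiberStack(seed = 13, decayDepth = 1.5)
  prof <- labeledDepth(sim$stack)
  expect_false(prof$accepted)
  expect_lte(prof$thref, 2)
})

test_that("behavior generator saturates, improves and nulls out as configured", {
  # fast saturation to certainty
  tr <- simBehaviorSessions(seed = 5, nAnimals = 6, rate = 3, pMax = 1,
                            invalidProb = 0)
  sc <- scoreTrials(tr)
  late <- sc$successPct[sc$day > 3]
  expect_gte(mean(late), 95)
  # monotone p(d): day-mean success is nondecreasing on average over seeds
  diffs <- 0
  for (s in 1:40) {
    sc <- scoreTrials(simBehaviorSessions(seed = 100 + s, nAnimals = 2,
                                          invalidProb = 0))
    dm <- tapply(sc$successPct, sc$day, mean)
    diffs <- diffs + diff(dm)
  }
  expect_true(all(diffs / 40 > -2))
  expect_gt(sum(diffs), 0)
  # flat learning curve centers learning rates on zero
  tr0 <- simBehaviorSessions(seed = 10, nAnimals = 40, p0 = 0.4, pMax = 0.4)
  sc0 <- scoreTrials(tr0)
  b <- vapply(split(sc0, sc0$animal),
              function(a) learningRate(a$successPct, a$day), numeric(1))
  expect_lt(abs(mean(b)), 2 * sd(b) / sqrt(length(b)) + 1)
  expect_error(simBehaviorSessions(pMax = 1.3), "\\[0, 1\\]")
})
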