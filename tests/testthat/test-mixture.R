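test_that("E-step posterior equals the prior under equal likelihoods", {
  ss <- SeedSet(paste0("s", 1:5), rep("GAGGUA", 5))
  uni <- PWM(matrix(0.25, 4, 6))
  m <- PWMixture(c(0.5, 0.5), list(uni, uni))
  z <- eStep(ss, m)
  expect_equal(unname(z), matrix(0.5, 5, 2))
  m2 <- PWMixture(c(0.9, 0.1), list(uni, uni))
  expect_equal(unname(eStep(ss, m2)),
               matrix(rep(c(0.9, 0.1), each = 5), 5, 2))
})

test_that("E-step reproduces the hand Bayes ratio 10:1", {
  # component 1 assigns 10x the likelihood of component 2 to "AC"
  p1 <- PWM(cbind(c(0.7, 0.1, 0.1, 0.1), c(0.5, 0.5, 0, 0)))     # P = 0.35
  p2 <- PWM(cbind(c(0.07, 0.31, 0.31, 0.31), c(0.5, 0.5, 0, 0))) # P = 0.035
  m <- PWMixture(c(0.5, 0.5), list(p1, p2))
  ss <- SeedSet("x", "AC")
  expect_equal(unname(eStep(ss, m))[1, ], c(10 / 11, 1 / 11))
  expect_equal(unname(eStep(ss, m)), oracleEStep("AC", c(0.5, 0.5),
                                                 list(p1, p2)))
})

test_that("E-step errors when every component has zero likelihood", {
  p <- PWM(cbind(c(1, 0, 0, 0)))
  m <- PWMixture(1, list(p))
  expect_error(eStep(SeedSet("x", "C"), m), "pseudocount")
  expect_error(marginalLogLik(SeedSet("x", "C"), m), "pseudocount")
})

test_that("M-step recovers mixing weights and smoothed frequencies", {
  ss <- SeedSet(paste0("s", 1:4),
                c("AAAAAA", "CCCCCC", "AAAAAA", "AAAAAA"))
  z <- matrix(c(1, 0, 1, 1, 0, 1, 0, 0), 4, 2)
  upd <- mStep(ss, z, pseudocount = 0)
  expect_equal(upd$lambdas, c(0.75, 0.25))

  # k = 1 empirical frequencies, no smoothing
  ss2 <- SeedSet(c("a", "b"), c("AAAAAA", "CCCCCC"))
  upd2 <- mStep(ss2, matrix(1, 2, 1), pseudocount = 0)
  expect_equal(unname(probMatrix(upd2$pwms[[1]])),
               matrix(c(0.5, 0.5, 0, 0), 4, 6))

  # (1+1)/(4+1) smoothing arithmetic
  upd3 <- mStep(SeedSet("a", "AAAAAA"), matrix(1, 1, 1), pseudocount = 1)
  expect_equal(unname(probMatrix(upd3$pwms[[1]])),
               matrix(c(0.4, 0.2, 0.2, 0.2), 4, 6))

  # zero-responsibility component with no pseudocount keeps its PWM
  old <- list(PWM(matrix(0.25, 4, 6)),
              PWM(matrix(c(0.7, 0.1, 0.1, 0.1), 4, 6)))
  expect_warning(
    upd4 <- mStep(ss2, matrix(c(1, 1, 0, 0), 2, 2), pseudocount = 0,
                  pwms = old),
    "zero total responsibility")
  expect_equal(probMatrix(upd4$pwms[[2]]), probMatrix(old[[2]]))
})

test_that("marginal log-likelihood has the stated closed forms", {
  ss <- SeedSet(paste0("s", 1:7), randomSeedStrings(7))
  uni <- PWM(matrix(0.25, 4, 6))
  expect_equal(marginalLogLik(ss, PWMixture(1, list(uni))), 7 * log(0.25^6))
  # mixture of identical components collapses to one component
  set.seed(3)
  p <- randomPWM(6)
  expect_equal(marginalLogLik(ss, PWMixture(c(0.5, 0.5), list(p, p))),
               marginalLogLik(ss, PWMixture(1, list(p))))
})

test_that("EM normalization is conserved and trajectories ascend", {
  set.seed(21)
  for (trial in 1:10) {
    truth <- sampleMixture(k = sample(2:4, 1), n = sample(40:120, 1),
                           separation = "random", rngSeed = 100 + trial)
    fit <- fitMixture(truth@seeds, k = 3, rngSeed = trial)
    expect_equal(sum(mixingWeights(fit)), 1, tolerance = 1e-9)
    for (p in pwmList(fit))
      expect_equal(colSums(probMatrix(p)), rep(1, 6), tolerance = 1e-9)
    expect_equal(unname(rowSums(responsibilities(fit))),
                 rep(1, length(truth@seeds)), tolerance = 1e-9)
    expect_true(all(diff(logLikTrajectory(fit)) >= -1e-9))
  }
})

test_that("EM is deterministic given the seed", {
  truth <- sampleMixture(k = 3, n = 150, rngSeed = 6)
  f1 <- fitMixture(truth@seeds, k = 3, rngSeed = 9)
  f2 <- fitMixture(truth@seeds, k = 3, rngSeed = 9)
  expect_identical(logLikTrajectory(f1), logLikTrajectory(f2))
  expect_identical(lapply(pwmList(f1), probMatrix),
                   lapply(pwmList(f2), probMatrix))
})

test_that("permuting the initialization permutes the fit identically", {
  truth <- sampleMixture(k = 3, n = 120, rngSeed = 14)
  init <- initPWMs(truth@seeds, k = 3, rngSeed = 31)
  perm <- c(3L, 1L, 2L)
  f1 <- fitMixture(truth@seeds, k = 3, initPwms = init)
  f2 <- fitMixture(truth@seeds, k = 3, initPwms = init[perm])
  expect_equal(logLikTrajectory(f1), logLikTrajectory(f2))
  expect_equal(mixingWeights(f2), mixingWeights(f1)[perm])
  expect_equal(lapply(pwmList(f2), probMatrix),
               lapply(pwmList(f1)[perm], probMatrix))
  expect_equal(unname(responsibilities(f2)),
               unname(responsibilities(f1)[, perm]))
})

test_that("scan over k is reproducible and k=1 restarts coincide", {
  truth <- sampleMixture(k = 3, n = 150, rngSeed = 2)
  one <- scanK(truth@seeds, kValues = 1, restarts = 3, rngSeed = 5)
  # k = 1 has no latent structure: every restart reaches the same optimum
  fits <- vapply(1:3, function(r)
    tail(logLikTrajectory(
      fitMixture(truth@seeds, 1, rngSeed = seedmix:::.deriveSeed(5, 1, r))),
      1), numeric(1))
  expect_equal(max(fits) - min(fits), 0, tolerance = 1e-6)
  expect_equal(one$table$best_loglik, max(fits))

  s1 <- scanK(truth@seeds, kValues = 2:3, restarts = 2, rngSeed = 8)
  s2 <- scanK(truth@seeds, kValues = 2:3, restarts = 2, rngSeed = 8)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$bestK, s2$bestK)
})

test_that("hard assignment takes the argmax with lowest-index ties", {
  z <- rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1))
  rownames(z) <- c("a", "b", "c")
  g <- assignGroups(z)
  expect_equal(unname(groupLabels(g)), c(2L, 1L, 1L))
  # all rows identical -> one non-empty group, the rest empty
  z2 <- matrix(1 / 3, 4, 3, dimnames = list(letters[1:4], NULL))
  g2 <- assignGroups(z2)
  expect_equal(unname(groupLabels(g2)), rep(1L, 4))
  expect_equal(nGroups(g2), 3L)
})

test_that("model JSON round-trips at full precision", {
  truth <- sampleMixture(k = 2, n = 80, rngSeed = 4)
  fit <- fitMixture(truth@seeds, k = 2, rngSeed = 3)
  path <- tempfile(fileext = ".json")
  writeMixtureModel(fit, path)
  back <- readMixtureModel(path)
  expect_identical(back@lambdas, fit@lambdas)
  expect_identical(lapply(back@pwms, probMatrix),
                   lapply(pwmList(fit), probMatrix))
  expect_identical(back@k, fit@k)
  # a rewrite of the reread model is byte-identical
  path2 <- tempfile(fileext = ".json")
  back@nIter <- fit@nIter
  writeMixtureModel(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
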