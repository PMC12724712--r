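test_that("periodic kernel: closed values, symmetry, exact periodicity", {
  expect_equal(periodicKernel(5, 5, 4, 300, 1)[1, 1], 4)
  expect_equal(periodicKernel(0, 300, 4, 300, 1)[1, 1], 4, tolerance = 1e-12)
  expect_equal(periodicKernel(0, 75, 5, 300, 1)[1, 1], 5 * exp(-1),
               tolerance = 1e-12)
  t <- c(0, 10, 50, 200)
  K <- periodicKernel(t, t, 2.5, 120, 0.8)
  expect_equal(K, t(K))
  expect_true(all(K <= 2.5 + 1e-12))
  expect_error(periodicKernel(0, 1, variance = -1), "variance")
})

test_that("SoftPlus link is stable, positive and monotone", {
  expect_equal(softplusLink(0), 10 * log(2))
  expect_equal(softplusLink(50), 500, tolerance = 1e-6)  # linear asymptote
  expect_equal(softplusLink(-50), 10 * exp(-50), tolerance = 1e-55)
  expect_gt(softplusLink(-745), 0)  # no underflow to exactly zero
  x <- seq(-30, 30, length.out = 500)
  expect_true(all(diff(softplusLink(x)) > 0))
})

test_that("generalized-Poisson log-pmf: Poisson limit, normalization, mean", {
  expect_equal(genpoisLogPmf(0, 2, 0), -2)
  expect_equal(sum(dgenpois(0:300, 1.5, 0.3)), 1, tolerance = 1e-10)
  expect_equal(sum((0:400) * dgenpois(0:400, 1, 0.5)), 2, tolerance = 1e-8)
  expect_error(dgenpois(1, 2, 1.2), "alpha")
})

test_that("contaminated likelihood mixes with a uniform floor", {
  y <- c(0, 3, 7); mu <- c(1, 2.5, 4)
  expect_equal(contaminatedLogLik(y, mu, 0.2, pNoise = 0, yMax = 10),
               dgenpois(y, mu * 0.8, 0.2, log = TRUE))
  # extreme outlier pinned to the mixture floor
  fl <- contaminatedLogLik(500, 0.01, 0, pNoise = 0.001, yMax = 500)
  expect_equal(fl, log(0.001 / 501), tolerance = 1e-6)
  # mixture bounds: at least each weighted component
  set.seed(1)
  for (i in 1:20) {
    yy <- rpois(1, 5); mm <- runif(1, 0.5, 8); aa <- runif(1, -0.5, 0.7)
    lm <- contaminatedLogLik(yy, mm, aa, 0.001, 50)
    lg <- dgenpois(yy, mm * (1 - aa), aa, log = TRUE)
    expect_gte(lm + 1e-10, log(0.999) + lg)
    expect_gte(lm + 1e-10, log(0.001 / 51))
  }
})

test_that("pseudo-R2 has its defining anchor points", {
  obs <- c(1, 4, 2, 6)
  expect_equal(pseudoR2(obs, obs, 3), 1)
  expect_equal(pseudoR2(obs, rep(3, 4), 3), 0)
  tg <- seq(0, 2 * pi, length.out = 50)
  expect_lt(pseudoR2(sin(tg), -sin(tg), 0), 0)  # anti-phase prediction
  expect_warning(r <- pseudoR2(c(2, 2), c(1, 3), 2), "undefined")
  expect_true(is.na(r))
})

test_that("latent GP recovers period and dispersion from sinusoid counts", {
  set.seed(11)
  g <- genOngoingCounts(period = 300, latentAmp = 1, alpha = 0.5,
                        duration = 1500, bin = 5, mode = "sinusoid")
  fit <- fitLatentGP(g$counts, holdout = 300)
  expect_lt(abs(fit@hyper["period"] - 300) / 300, 0.05)
  expect_lt(abs(fit@hyper["alpha"] - 0.5), 0.15)
  expect_gt(fit@pseudoR2Test, 0)
  expect_gt(fit@pseudoR2Train, fit@pseudoR2Test * 0.5)
})

test_that("regular low-variance counts yield negative dispersion", {
  set.seed(12)
  g <- genOngoingCounts(period = 300, latentAmp = 0, alpha = -0.5,
                        duration = 1500, bin = 5, latentMean = 2)
  fit <- fitLatentGP(g$counts, holdout = 300)
  expect_lt(fit@hyper["alpha"], 0)
  expect_lt(fit@hyper["variance"], 0.05)
})

test_that("held-out counts never influence the fitted hyperparameters", {
  set.seed(13)
  g <- genOngoingCounts(period = 300, latentAmp = 1, alpha = 0.3,
                        duration = 1000, bin = 5)
  y <- counts(g$counts)
  f1 <- fitLatentGP(BinnedCounts(y, 0, 5), holdout = 300, maxit = 150)
  y2 <- y
  tampered <- seq(length(y) - 10, length(y))  # inside the holdout tail
  y2[tampered] <- y2[tampered] + 17L
  f2 <- fitLatentGP(BinnedCounts(y2, 0, 5), holdout = 300, maxit = 150)
  expect_identical(f1@hyper, f2@hyper)
  expect_identical(f1@predTest, f2@predTest)
})

test_that("phase folding reproduces cycles at the fitted period", {
  set.seed(14)
  g <- genOngoingCounts(period = 300, latentAmp = 1.5, alpha = 0,
                        duration = 1500, bin = 5)
  fit <- fitLatentGP(g$counts, holdout = 300, maxit = 150)
  pf <- phaseFold(fit, nPhase = 40)
  expect_length(pf$rate, 40)
  # one fitted-period cycle: profile has a single dominant harmonic
  sp <- Mod(fft(pf$rate - mean(pf$rate)))[2:20]
  expect_equal(which.max(sp), 1L)
  # folding at twice the period shows two cycles
  pf2 <- phaseFold(fit, nPhase = 40, period = 2 * unname(fit@hyper["period"]))
  sp2 <- Mod(fft(pf2$rate - mean(pf2$rate)))[2:20]
  expect_equal(which.max(sp2), 2L)
  # constant prediction folds flat
  cfit <- fit
  cfit@predTrain <- rep(2, length(fit@predTrain))
  expect_lt(diff(range(phaseFold(cfit, nPhase = 20)$rate)), 1e-12)
})
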