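test_that("thinning sampler matches Poisson statistics", {
  set.seed(1)
  expect_equal(nSpikes(sampleInhomPoisson(function(t) 0 * t, 0, 100)), 0)
  tr <- sampleInhomPoisson(function(t) rep(10, length(t)), 0, 1000)
  expect_lt(abs(nSpikes(tr) - 10000), 3 * sqrt(10000))
  # step rate: silent before the step, ~20 Hz after (segment-wise Poisson)
  step_fn <- function(t) ifelse(t < 50, 0, 20)
  tr2 <- sampleInhomPoisson(step_fn, 0, 100)
  tms <- spikeTimes(tr2)
  expect_equal(sum(tms < 50), 0)
  expect_lt(abs(sum(tms >= 50) - 1000), 3 * sqrt(1000))
  expect_error(sampleInhomPoisson(function(t) t - 1e3, 0, 10), "nonnegative")
})

test_that("thinning gives per-segment Poisson counts (chi-square GOF)", {
  # piecewise-constant rate: counts per segment ~ Poisson(rate * len)
  set.seed(2)
  rate_fn <- function(t) ifelse(t < 100, 5, ifelse(t < 200, 15, 2))
  n1 <- n2 <- n3 <- numeric(40)
  for (i in 1:40) {
    tms <- spikeTimes(sampleInhomPoisson(rate_fn, 0, 300))
    n1[i] <- sum(tms < 100); n2[i] <- sum(tms >= 100 & tms < 200)
    n3[i] <- sum(tms >= 200)
  }
  for (pair in list(list(n1, 500), list(n2, 1500), list(n3, 200))) {
    z <- (mean(pair[[1]]) - pair[[2]]) / sqrt(pair[[2]] / 40)
    expect_lt(abs(z), 4)
    # variance consistent with Poisson (chi-square on sample variance)
    vr <- var(pair[[1]]) / pair[[2]] * 39
    expect_gt(vr, qchisq(1e-4, 39)); expect_lt(vr, qchisq(1 - 1e-4, 39))
  }
})

test_that("generalized Poisson sampler has the stated moments", {
  set.seed(4)
  # mean theta/(1-alpha), variance theta/(1-alpha)^3, against direct pmf
  # summation and within 3 SE at n = 1e5
  for (par in list(c(1, 0.5), c(5, -0.5), c(2, 0.3))) {
    th <- par[1]; al <- par[2]
    cap <- if (al < 0) mtspike:::genpois_support_max(th, al) else 300
    p <- dgenpois(0:cap, th, al)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    m_pmf <- sum((0:cap) * p)
    v_pmf <- sum((0:cap)^2 * p) - m_pmf^2
    x <- rgenpois(1e5, th, al)
    expect_lt(abs(mean(x) - m_pmf), 3 * sqrt(v_pmf / 1e5))
    if (al >= 0) {  # untruncated: closed-form moments hold exactly
      expect_equal(m_pmf, th / (1 - al), tolerance = 1e-6)
      expect_equal(v_pmf, th / (1 - al)^3, tolerance = 1e-4)
    }
    if (al < 0) expect_lt(var(x), mean(x))  # underdispersion
  }
})

test_that("generalized Poisson at alpha = 0 is exactly Poisson", {
  expect_equal(dgenpois(0:30, 2.5, 0), dpois(0:30, 2.5), tolerance = 1e-12)
  set.seed(5)
  x <- rgenpois(1e5, 4, 0)
  # chi-square GOF against Poisson(4), pooling the right tail
  obs <- tabulate(pmin(x, 9) + 1, nbins = 10)
  pr <- c(dpois(0:8, 4), 1 - ppois(8, 4))
  stat <- sum((obs - 1e5 * pr)^2 / (1e5 * pr))
  expect_lt(stat, qchisq(0.999, 9))
})

test_that("ongoing-count generator produces the intended rhythm and dispersion", {
  set.seed(6)
  g0 <- genOngoingCounts(latentAmp = 0, alpha = 0, duration = 1500)
  cv_means <- sd(counts(g0$counts)) / mean(counts(g0$counts))
  expect_lt(cv_means, 0.35)  # no modulation beyond count noise
  expect_true(all(g0$rate == g0$rate[1]))
  # sinusoid mode: autocorrelation of counts peaks at one period lag
  g <- genOngoingCounts(period = 300, latentAmp = 2, alpha = 0,
                        duration = 1500, bin = 5)
  ac <- acf(counts(g$counts), lag.max = 80, plot = FALSE)$acf[-1]
  lag_peak <- which.max(ac[40:80]) + 39   # search away from lag 0
  expect_lt(abs(lag_peak * 5 - 300), 15)  # within 3 bins of 300 s
  # overdispersion from alpha > 0: index of dispersion of counts > 1
  g2 <- genOngoingCounts(latentAmp = 0, alpha = 0.6, duration = 1500)
  expect_gt(var(counts(g2$counts)) / mean(counts(g2$counts)), 1.5)
  expect_warning(genOngoingCounts(period = 800, duration = 700),
                 "unidentifiable")
})

test_that("heart-rate generator hits its mean and couples to a latent", {
  g <- genHeartRate(sdBpm = 0, oscAmp = 0, duration = 100)
  expect_true(all(rateValues(g) == 391.1))
  tg <- seq(0, 998, by = 2)
  lat <- sin(2 * pi * tg / 300)
  g2 <- genHeartRate(sdBpm = 0, oscAmp = 10, coupledLatent = lat,
                     duration = 1000)
  expect_equal(sd(rateValues(g2)), 10, tolerance = 1e-6)
  expect_gt(cor(rateValues(g2), lat), 0.99)
})

test_that("cohort generation is deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  cfg <- cohortConfig(nAnimals = 1, trialsPerCell = 2,
                      cellsPerAnimal = c(ON = 1, NEUTRAL = 1))
  genCohort(cfg, outDir = d1, seed = 9)
  genCohort(cfg, outDir = d2, seed = 9)
  for (f in c("spikes.tsv", "events.tsv", "hr.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("synthetic NEUTRAL cells are regular and ON cells rise pre-withdrawal", {
  set.seed(10)
  cfg <- cohortConfig(nAnimals = 2, trialsPerCell = 3)
  coh <- genCohort(cfg, seed = 11)
  classes <- vapply(coh$trains, cellClass, "")
  for (tr in coh$trains[classes == "NEUTRAL"]) {
    s <- isiStats(tr)
    expect_lt(s$cv, 1)
    expect_lt(abs(s$meanIsi - 0.1), 0.03)  # ~10 Hz tonic
  }
  # ON PSTH rises before the withdrawal time
  wins <- list()
  for (tr in coh$trains[classes == "ON"])
    wins <- c(wins, trialWindows(tr, coh$events, "withdrawal"))
  p <- buildPSTH(wins, binWidth = 0.5)
  tc <- binTimes(p); cts <- counts(p)
  expect_gt(mean(cts[tc > -1 & tc < 0]), 2 * mean(cts[tc > -6 & tc < -3]))
})

test_that("PSTH peak matches the generating peak time at pooled scale", {
  # single pooled-scale unit: the population rate as one inhomogeneous
  # Poisson process, so the peak-location example has adequate power
  set.seed(20)
  on <- cohortConfig()$on
  rate_fn <- function(t) evaluateRate("on_double_exp", on, t - 110) / 0.05
  tr <- sampleInhomPoisson(rate_fn, 90, 215, unitId = "pool",
                           animalId = "a1", cellClass = "ON")
  ev <- data.frame(animal_id = "a1", trial_index = 1,
                   heat_onset_s = 101, withdrawal_s = 110)
  p <- buildPSTH(trialWindows(tr, ev, "withdrawal", pre = 10, post = 100),
                 binWidth = 0.5)
  tpk <- binTimes(p)[which.max(counts(p))]
  expect_lt(abs(tpk - on$ts), 0.5)
})
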