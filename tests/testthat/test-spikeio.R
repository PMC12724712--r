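test_that("SpikeTrain validity enforces ordering, span and class labels", {
  st <- SpikeTrain(c(0.3, 0.1, 0.2), tStart = 0, tStop = 1)
  expect_equal(spikeTimes(st), c(0.1, 0.2, 0.3))  # constructor sorts
  expect_error(new("SpikeTrain", unitId = "u", animalId = "a",
                   cellClass = "ON", spikeTimes = c(2, 1),
                   tStart = 0, tStop = 3), "nondecreasing")
  expect_error(SpikeTrain(0.5, tStart = 1, tStop = 2), "within")
  expect_error(SpikeTrain(cellClass = "BOGUS"), "cellClass")
})

test_that("spike table round trip preserves times, labels and span", {
  trains <- list(
    SpikeTrain(c(0.111111111, 5.5, 9.123456789), tStart = 0, tStop = 10,
               unitId = "u1", animalId = "a1", cellClass = "ON"),
    SpikeTrain(c(1, 2, 3), tStart = 0, tStop = 10,
               unitId = "u2", animalId = "a2", cellClass = "NEUTRAL"))
  f <- tempfile(fileext = ".tsv")
  writeSpikeTable(trains, f)
  back <- readSpikeTable(f)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(spikeTimes(back[[i]]), spikeTimes(trains[[i]]),
                 tolerance = 1e-9)
    expect_identical(cellClass(back[[i]]), cellClass(trains[[i]]))
    expect_equal(recordingSpan(back[[i]]), c(0, 10), tolerance = 1e-9)
  }
})

test_that("spike table reader handles small and degenerate files", {
  f <- tempfile()
  writeLines(c("animal_id\tunit_id\tcell_class\tspike_time_s",
               "a1\tu1\tON\t0.1", "a1\tu1\tON\t0.2", "a1\tu1\tON\t0.3"), f)
  tr <- readSpikeTable(f)
  expect_length(tr, 1)
  expect_equal(nSpikes(tr[[1]]), 3)
  writeLines("animal_id\tunit_id\tcell_class\tspike_time_s", f)
  expect_length(readSpikeTable(f), 0)
  writeLines(c("animal_id\tunit_id\tcell_class\tspike_time_s",
               "a1\tu1\tON\tnot_a_number"), f)
  expect_error(readSpikeTable(f), "malformed")
  writeLines(c("animal_id\tunit_id\tcell_class\tspike_time_s",
               "a1\tu1\tON\t0.3", "a1\tu1\tON\t0.1"), f)
  expect_warning(tr <- readSpikeTable(f), "unsorted")
  expect_equal(spikeTimes(tr[[1]]), c(0.1, 0.3))
})

test_that("binSpikes uses half-open bins and conserves counts", {
  st <- SpikeTrain(c(0.01, 0.02, 0.06), tStart = 0, tStop = 0.2)
  expect_equal(counts(binSpikes(st, 0, 0.1, 0.05)), c(2L, 1L))
  empty <- SpikeTrain(numeric(0), tStart = 0, tStop = 10)
  expect_equal(counts(binSpikes(empty, 0, 10, 1)), rep(0L, 10))
  expect_error(binSpikes(st, 0, 1, -0.1), "width")
  # conservation against the hist() oracle on random spikes
  set.seed(1)
  tms <- sort(runif(1000, 0, 50))
  tr <- SpikeTrain(tms, tStart = 0, tStop = 50)
  bc <- binSpikes(tr, 0, 50, 0.73)
  nb <- length(counts(bc))
  oracle <- hist(tms[tms < nb * 0.73], breaks = seq(0, nb * 0.73, by = 0.73),
                 plot = FALSE, right = FALSE)$counts
  expect_equal(counts(bc), as.integer(oracle))
  expect_equal(sum(counts(bc)), sum(tms < nb * 0.73))
})

test_that("smoothRate gives constant output for regular trains and trims", {
  reg <- SpikeTrain(seq(0.05, 99.95, by = 0.1), tStart = 0, tStop = 100)
  rs <- smoothRate(reg)
  expect_true(all(abs(rateValues(rs) - 10) < 0.51))  # boxcar edge quantum
  expect_equal(rs@step, 2)
  expect_equal(rateTimes(rs)[1], 2)  # first 2 s trimmed
  expect_lte(max(rateTimes(rs)), 98)
  short <- SpikeTrain(c(0.5, 1), tStart = 0, tStop = 3)
  expect_error(smoothRate(short), "span")
  empty <- SpikeTrain(numeric(0), tStart = 0, tStop = 50)
  expect_true(all(rateValues(smoothRate(empty)) == 0))
})

test_that("smoothRate of a homogeneous Poisson train recovers the rate", {
  # Monte-Carlo oracle: time-averaged smoothed rate within 3 SE of truth
  rate <- 7
  set.seed(42)
  devs <- replicate(5, {
    n <- rpois(1, rate * 400)
    tr <- SpikeTrain(sort(runif(n, 0, 400)), tStart = 0, tStop = 400)
    mean(rateValues(smoothRate(tr)))
  })
  se <- sqrt(rate / 396)  # variance of a 396 s average of a Poisson rate
  expect_true(all(abs(devs - rate) < 3 * se))
})

test_that("trial windows align, exclude truncated trials, skip absent markers", {
  tr <- SpikeTrain(c(95, 100.2, 101, 150), tStart = 0, tStop = 300)
  ev <- data.frame(animal_id = "a1", trial_index = 1,
                   heat_onset_s = 92, withdrawal_s = 100)
  w <- trialWindows(tr, ev)
  expect_length(w, 1)
  expect_true(w[[1]]$included)
  expect_equal(w[[1]]$times, c(-5, 0.2, 1, 50))
  # recording ends 50 s after event -> excluded
  tr2 <- SpikeTrain(c(95), tStart = 0, tStop = 150)
  expect_false(trialWindows(tr2, ev)[[1]]$included)
  # next trial onset 80 s after event -> excluded
  ev2 <- rbind(ev, data.frame(animal_id = "a1", trial_index = 2,
                              heat_onset_s = 180, withdrawal_s = 189))
  w2 <- trialWindows(tr, ev2)
  expect_false(w2[[1]]$included)
  # absent withdrawal marker -> trial skipped with a message
  ev3 <- data.frame(animal_id = "a1", trial_index = 1:2,
                    heat_onset_s = c(92, 1000), withdrawal_s = c(100, NA))
  expect_message(w3 <- trialWindows(tr, ev3), "skipped")
  expect_length(w3, 1)
})

test_that("PSTH is additive and invariant to window order", {
  tr <- SpikeTrain(c(95, 99.5, 100.5, 120), tStart = 0, tStop = 500)
  ev <- data.frame(animal_id = "a1", trial_index = 1,
                   heat_onset_s = 92, withdrawal_s = 100)
  w <- trialWindows(tr, ev)
  p1 <- buildPSTH(w, binWidth = 0.5)
  p2 <- buildPSTH(c(w, w), binWidth = 0.5)
  expect_equal(counts(p2), 2L * counts(p1))
  expect_equal(p2@nTrials, 2L)
  w3 <- c(w, w, w)
  expect_equal(counts(buildPSTH(rev(w3), 0.5)), counts(buildPSTH(w3, 0.5)))
  # zero included windows -> empty PSTH, flagged
  tr2 <- SpikeTrain(c(95), tStart = 0, tStop = 150)
  wex <- trialWindows(tr2, ev)
  expect_warning(p0 <- buildPSTH(wex, 0.5), "no included")
  expect_equal(p0@nTrials, 0L)
  expect_true(all(counts(p0) == 0L))
  # mixed alignments rejected
  wh <- trialWindows(tr, ev, alignment = "heat_onset")
  expect_error(buildPSTH(c(w, wh), 0.5), "alignment")
})

test_that("count conservation holds for arbitrary half-open binnings", {
  set.seed(3)
  for (rep in 1:5) {
    tms <- sort(runif(rpois(1, 200), 0, 37))
    tr <- SpikeTrain(tms, tStart = 0, tStop = 37)
    width <- runif(1, 0.1, 3)
    nb <- floor(37 / width)
    bc <- binSpikes(tr, 0, 37, width)
    expect_equal(sum(counts(bc)), sum(tms < nb * width))
  }
})
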