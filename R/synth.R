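## Synthetic cohort generator.
##
## Emulates the statistical structure of the recordings the analyses assume:
## evoked ON/OFF piecewise rates around heat trials at 5-min intervals,
## NEUTRAL regular ~10 Hz gamma-renewal firing, ~300 s quasi-periodic ongoing
## modulation with generalized-Poisson dispersion, and a heart-rate series
## (~391 bpm) optionally sharing the slow oscillation. Every generator is a
## pure function of its arguments plus R's seeded global RNG.

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Draws candidate events from a homogeneous Poisson process at the supremum
#' rate and keeps each with probability \code{rateFn(t)/rateMax}.
#'
#' @param rateFn vectorized function time (s) -> rate (spikes/s), bounded and
#'   nonnegative on \code{[t0, t1]}.
#' @param t0,t1 interval (s).
#' @param rateMax an upper bound on \code{rateFn} over the interval; by
#'   default estimated from a dense grid and checked.
#' @param ... metadata passed to [SpikeTrain()] (\code{unitId} etc.).
#' @return A \code{SpikeTrain} with spikes in \code{[t0, t1)}.
#' @export
sampleInhomPoisson <- function(rateFn, t0, t1, rateMax = NULL, ...) {
  stopifnot(t1 > t0)
  grid <- seq(t0, t1, length.out = 2001)
  rg <- rateFn(grid)
  if (any(!is.finite(rg)) || any(rg < 0))
    stop("rateFn must be finite and nonnegative on [t0, t1]")
  if (is.null(rateMax)) rateMax <- max(rg) * 1.05 + 1e-12
  if (max(rg) > rateMax) stop("rateMax is not an upper bound for rateFn")
  if (rateMax <= 0)
    return(SpikeTrain(numeric(0), tStart = t0, tStop = t1, ...))
  n <- rpois(1, rateMax * (t1 - t0))
  cand <- sort(runif(n, t0, t1))
  r <- rateFn(cand)
  if (any(r > rateMax + 1e-9)) stop("rateFn exceeded rateMax at a candidate")
  keep <- runif(n) < r / rateMax
  SpikeTrain(cand[keep], tStart = t0, tStop = t1, ...)
}

#' Regular-but-jittered tonic spike train (gamma renewal process)
#'
#' NEUTRAL-style units fire tonically near 10 Hz with interspike-interval
#' coefficient of variation well below 1; a gamma renewal process with shape
#' \code{1/cv^2} reproduces that regularity (a Poisson train cannot).
#'
#' @param rate mean firing rate (spikes/s); default 10.
#' @param cv target ISI coefficient of variation; default 0.35.
#' @param t0,t1 interval (s).
#' @param ... metadata passed to [SpikeTrain()].
#' @return A \code{SpikeTrain}.
#' @export
sampleGammaRenewal <- function(rate = 10, cv = 0.35, t0, t1, ...) {
  stopifnot(t1 > t0, rate > 0, cv > 0)
  shape <- 1 / cv^2
  scale <- 1 / (rate * shape)
  n_guess <- ceiling((t1 - t0) * rate * 1.5 + 50)
  isi <- rgamma(n_guess, shape = shape, scale = scale)
  tms <- t0 + cumsum(isi)
  while (sum(isi) < (t1 - t0)) {
    isi2 <- rgamma(n_guess, shape = shape, scale = scale)
    isi <- c(isi, isi2)
    tms <- t0 + cumsum(isi)
  }
  SpikeTrain(tms[tms < t1], tStart = t0, tStop = t1, ...)
}

#' Generate ongoing counts from a periodic latent process
#'
#' Draws a latent periodic signal (either an exact sinusoid, for sharp
#' recovery tests, or a draw from a periodic-kernel Gaussian process), maps it
#' through the scaled SoftPlus link to a rate, and emits per-bin generalized
#' Poisson counts with mean \code{rate * bin}.
#'
#' @param period oscillation period (s); default 300.
#' @param latentAmp amplitude of the latent signal (sinusoid mode) or kernel
#'   standard deviation (GP mode); 0 gives constant-mean counts.
#' @param lengthscale periodic-kernel lengthscale (GP mode); default 1.
#' @param alpha generalized-Poisson dispersion in (-1, 1).
#' @param A SoftPlus scale (spikes/s); default 10.
#' @param duration total duration (s); at least 3 periods recommended for
#'   identifiability (warned otherwise).
#' @param bin bin width (s); default 5.
#' @param latentMean constant latent mean; default 0 (rate A log 2 at
#'   \code{latentAmp = 0}).
#' @param mode \code{"sinusoid"} (deterministic latent, random counts) or
#'   \code{"gp"} (latent drawn from the periodic kernel).
#' @param phase sinusoid phase (radians) at t = 0; default 0.
#' @return List with \code{counts} (a \code{BinnedCounts}), \code{latent},
#'   \code{rate} (spikes/s per bin center), and the generating parameters
#'   (\code{groundTruth}).
#' @export
genOngoingCounts <- function(period = 300, latentAmp = 1, lengthscale = 1,
                             alpha = 0, A = 10, duration = 1500, bin = 5,
                             latentMean = 0,
                             mode = c("sinusoid", "gp"), phase = 0) {
  mode <- match.arg(mode)
  stopifnot(period > 0, bin > 0, duration > bin)
  if (duration < period)
    warning("duration shorter than one period; period unidentifiable")
  else if (duration < 3 * period)
    warning("fewer than 3 cycles; period weakly identifiable")
  tc <- seq(bin / 2, duration - bin / 2, by = bin)
  latent <- if (mode == "sinusoid") {
    latentMean + latentAmp * sin(2 * pi * tc / period + phase)
  } else {
    K <- periodicKernel(tc, tc, variance = latentAmp^2, period = period,
                        lengthscale = lengthscale)
    L <- chol(K + diag(1e-8, length(tc)))
    latentMean + drop(crossprod(L, rnorm(length(tc))))
  }
  rate <- softplusLink(latent, A = A)
  mu <- pmax(rate * bin, 1e-9)
  y <- rgenpois(length(mu), theta = mu * (1 - alpha), alpha = alpha)
  list(counts = BinnedCounts(y, t0 = 0, binWidth = bin),
       latent = latent, rate = rate,
       groundTruth = list(period = period, latentAmp = latentAmp,
         lengthscale = lengthscale, alpha = alpha, A = A,
         latentMean = latentMean, mode = mode, phase = phase, bin = bin))
}

#' Generate a heart-rate series
#'
#' bpm series on a regular grid: mean + slow oscillation (or a supplied
#' latent series, optionally lagged) + white noise.
#'
#' @param meanBpm mean heart rate; default 391.1 bpm.
#' @param sdBpm white-noise standard deviation (bpm).
#' @param oscPeriod oscillation period (s); ignored when \code{coupledLatent}
#'   is given.
#' @param oscAmp oscillation amplitude (bpm).
#' @param coupledLatent optional numeric series (on the same grid) replacing
#'   the internal sinusoid, scaled to amplitude \code{oscAmp} (sd units).
#' @param lag lag (s) applied to the coupled latent; default 0.
#' @param duration duration (s).
#' @param step sampling period (s); default 2.
#' @return A \code{RateSeries} in bpm.
#' @export
genHeartRate <- function(meanBpm = 391.1, sdBpm = 5, oscPeriod = 300,
                         oscAmp = 0, coupledLatent = NULL, lag = 0,
                         duration = 1500, step = 2) {
  stopifnot(meanBpm > 0, step > 0, duration > step)
  tg <- seq(0, duration - step, by = step)
  osc <- if (!is.null(coupledLatent)) {
    x <- as.numeric(coupledLatent)
    if (length(x) != length(tg))
      stop("coupledLatent must match the heart-rate grid (", length(tg),
           " samples)")
    k <- round(lag / step)
    x <- if (k != 0) c(rep(x[1], k), head(x, -k)) else x
    s <- sd(x)
    if (s > 0) oscAmp * (x - mean(x)) / s else rep(0, length(x))
  } else if (oscAmp > 0) {
    oscAmp * sin(2 * pi * tg / oscPeriod)
  } else rep(0, length(tg))
  noise <- if (sdBpm > 0) rnorm(length(tg), 0, sdBpm) else rep(0, length(tg))
  RateSeries(meanBpm + osc + noise, t0 = 0, step = step)
}

#' Default cohort configuration
#'
#' Study-condition defaults for [genCohort()]: trials at 5-minute intervals
#' (3-4 per cell), evoked piecewise parameters at the reported population
#' posterior means with baselines matching pooled-count scale, ~300 s ongoing
#' modulation, NEUTRAL tonic ~10 Hz regular firing, and a ~391 bpm heart
#' rate.
#'
#' @param nAnimals number of animals.
#' @param cellsPerAnimal named counts per class, e.g.
#'   \code{c(ON = 1, OFF = 1, NEUTRAL = 1)}.
#' @param trialsPerCell trials per cell (3-4 in the evoked protocol).
#' @param interTrialInterval seconds between heat onsets; default 300.
#' @return A named list understood by [genCohort()].
#' @export
cohortConfig <- function(nAnimals = 2,
                         cellsPerAnimal = c(ON = 1, OFF = 1, NEUTRAL = 1),
                         trialsPerCell = 4, interTrialInterval = 300) {
  stopifnot(trialsPerCell >= 1, interTrialInterval > 0)
  list(
    nAnimals = nAnimals,
    cellsPerAnimal = cellsPerAnimal,
    trialsPerCell = trialsPerCell,
    interTrialInterval = interTrialInterval,
    withdrawalLatency = c(mean = 8.7, sd = 1.1),  # s after heat onset
    on = list(rPre = 20, rPost = 18, kPre = 60, kFast = 30,
              tau1 = 0.481, tau2 = 2.850, tau3 = 61.252, ts = -0.176),
    # sigmoid slope: in the increasing-sigmoid convention used by
    # evaluateRate(), a response *falling* from a to u0 has k < 0; the
    # reported slope is the magnitude (2.895 1/s)
    off = list(a = 25, b = 2, u0 = 2.5, k = -2.895, c = 18,
               tau = 4.206, k3 = 0.063, ts = 2.234),
    neutral = list(rate = 10, cv = 0.35),
    ongoing = list(period = 300, latentAmp = 1, lengthscale = 1,
                   alphaOn = 0.5, alphaOff = 0.3, A = 10, bin = 5),
    heartRate = list(meanBpm = 391.1, sdBpm = 5, oscAmp = 8,
                     coupledFraction = 0.3, lag = 10),
    nCellsPooledOn = 70, nCellsPooledOff = 60
  )
}

#' Generate a synthetic cohort and write interchange files
#'
#' Per animal, draws per-class units; evoked trials use the ON/OFF piecewise
#' rate families (per-cell rates are the pooled-population rate divided by
#' the pooled cell count), NEUTRAL units fire as regular gamma-renewal trains,
#' and between-trial segments carry the slow ~300 s ongoing modulation. A
#' heart-rate series is generated per animal, coupled to the animal's shared
#' latent phase for a configurable fraction of animals. Deterministic given
#' \code{seed}.
#'
#' @param config list from [cohortConfig()].
#' @param outDir output directory for \code{spikes.tsv}, \code{events.tsv},
#'   \code{hr.tsv}; \code{NULL} skips writing.
#' @param seed integer seed.
#' @return List with \code{trains}, \code{events}, \code{heartRate},
#'   \code{groundTruth}, and (when written) \code{files}.
#' @export
genCohort <- function(config = cohortConfig(), outDir = NULL, seed = 1) {
  set.seed(seed)
  cfg <- config
  ev_rows <- list(); trains <- list(); hr <- list(); gt <- list()
  n_on_pool <- cfg$nCellsPooledOn; n_off_pool <- cfg$nCellsPooledOff
  t_sess_end <- (cfg$trialsPerCell + 1) * cfg$interTrialInterval
  for (ai in seq_len(cfg$nAnimals)) {
    aid <- sprintf("a%02d", ai)
    onset <- cfg$interTrialInterval * seq_len(cfg$trialsPerCell)
    wl <- pmax(2, rnorm(cfg$trialsPerCell, cfg$withdrawalLatency["mean"],
                        cfg$withdrawalLatency["sd"]))
    wd <- onset + wl
    for (k in seq_len(cfg$trialsPerCell))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(animal_id = aid,
        trial_index = k, heat_onset_s = onset[k], withdrawal_s = wd[k])
    phase <- runif(1, 0, 2 * pi)  # shared per-animal latent phase
    latent_fn <- function(t) sin(2 * pi * t / cfg$ongoing$period + phase)
    ui <- 0
    for (cls in names(cfg$cellsPerAnimal)) {
      for (j in seq_len(cfg$cellsPerAnimal[[cls]])) {
        ui <- ui + 1
        uid <- sprintf("%s_u%02d_%s", aid, ui, cls)
        if (cls == "NEUTRAL") {
          tr <- sampleGammaRenewal(cfg$neutral$rate, cfg$neutral$cv,
            t0 = 0, t1 = t_sess_end, unitId = uid, animalId = aid,
            cellClass = cls)
        } else {
          per_cell <- if (cls == "ON") 1 / n_on_pool else 1 / n_off_pool
          pars <- if (cls == "ON") cfg$on else cfg$off
          variant <- if (cls == "ON") "on_double_exp" else "off_linear_exp"
          bw <- 0.05
          base_rate <- function(t) {
            # slow ongoing modulation of the per-cell baseline
            m <- softplusLink(cfg$ongoing$latentAmp * latent_fn(t),
                              A = cfg$ongoing$A)
            m / softplusLink(0, A = cfg$ongoing$A)
          }
          rate_fn <- function(t) {
            r <- rep(0, length(t))
            mod <- base_rate(t)
            evoked <- rep(1, length(t))
            for (k in seq_along(wd)) {
              rel <- t - wd[k]
              inwin <- rel >= -min(10, wl[k]) & rel <= cfg$interTrialInterval
              if (any(inwin)) {
                lam <- evaluateRate(variant, pars, rel[inwin]) / bw
                evoked[inwin] <- lam * per_cell /
                  (if (cls == "ON") pars$rPre / bw * per_cell
                   else pars$a / bw * per_cell)
              }
            }
            baseline <- if (cls == "ON") pars$rPre / bw * per_cell
                        else pars$a / bw * per_cell
            baseline * mod * evoked
          }
          tr <- sampleInhomPoisson(rate_fn, 0, t_sess_end,
            unitId = uid, animalId = aid, cellClass = cls)
        }
        trains[[length(trains) + 1L]] <- tr
        gt[[uid]] <- list(animal = aid, cellClass = cls, phase = phase)
      }
    }
    coupled <- (ai <= round(cfg$heartRate$coupledFraction * cfg$nAnimals))
    tg <- seq(0, t_sess_end - 2, by = 2)
    hr[[aid]] <- genHeartRate(cfg$heartRate$meanBpm, cfg$heartRate$sdBpm,
      oscPeriod = cfg$ongoing$period,
      oscAmp = if (coupled) cfg$heartRate$oscAmp else 0,
      coupledLatent = if (coupled) latent_fn(tg - cfg$heartRate$lag)
                      else NULL,
      lag = 0, duration = t_sess_end, step = 2)
    gt[[aid]] <- list(phase = phase, hrCoupled = coupled)
  }
  events <- do.call(rbind, ev_rows)
  out <- list(trains = trains, events = events, heartRate = hr,
              groundTruth = gt)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    f <- c(spikes = file.path(outDir, "spikes.tsv"),
           events = file.path(outDir, "events.tsv"),
           hr = file.path(outDir, "hr.tsv"))
    writeSpikeTable(trains, f["spikes"])
    writeEventTable(events, f["events"])
    writeHeartRateTable(hr, f["hr"])
    out$files <- f
  }
  out
}

#' Simulate pooled evoked counts from a piecewise model
#'
#' Draws Poisson counts per 50 ms bin over the analysis window directly from
#' a piecewise rate family evaluated at the bin centers -- the pooled
#' (population-summed) counts the evoked models are fitted to.
#'
#' @param variant model variant (see [evaluateRate()]).
#' @param params generating parameter list.
#' @param pre,post window (s); defaults 10 and 100.
#' @param binWidth bin width (s); default 0.05.
#' @return A \code{BinnedCounts} with \code{t0 = -pre}.
#' @export
simulateEvokedCounts <- function(variant, params, pre = 10, post = 100,
                                 binWidth = 0.05) {
  tc <- seq(-pre + binWidth / 2, post - binWidth / 2, by = binWidth)
  lam <- evaluateRate(variant, params, tc)
  BinnedCounts(rpois(length(tc), pmax(lam, 1e-12)), t0 = -pre,
               binWidth = binWidth)
}
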