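## Frequency-domain and variability summaries of ongoing activity, and the
## periodic-GP marginal-likelihood period scan.

#' Welch power spectral density
#'
#' Averaged modified periodogram over half-overlapping segments. The
#' normalization is one-sided density: \code{sum(power) * df} equals the
#' series variance for a boxcar window and a single full-length segment
#' (Parseval), and approximately for Hann-windowed averages.
#'
#' @param x numeric series (regularly sampled) or a \code{RateSeries} /
#'   \code{BinnedCounts}.
#' @param dt sampling period (s); taken from the object when one is given.
#' @param segLength segment length in samples; default
#'   \code{max(length/8, 600 s / dt)} capped at the series length.
#' @param window \code{"hann"} (default) or \code{"boxcar"}.
#' @param demean subtract the mean of each segment; default TRUE.
#' @return List with \code{freq} (Hz, DC excluded), \code{power} (one-sided
#'   density), \code{df}, \code{segLength}, \code{window}.
#' @export
welchPsd <- function(x, dt = NULL, segLength = NULL,
                     window = c("hann", "boxcar"), demean = TRUE) {
  window <- match.arg(window)
  if (is(x, "RateSeries")) { dt <- x@step; x <- rateValues(x) }
  else if (is(x, "BinnedCounts")) { dt <- x@binWidth; x <- as.numeric(counts(x)) }
  stopifnot(!is.null(dt), dt > 0, length(x) >= 8)
  n <- length(x)
  if (is.null(segLength))
    segLength <- min(n, max(floor(n / 8), ceiling(600 / dt)))
  segLength <- min(segLength, n)
  step <- max(1, floor(segLength / 2))
  starts <- seq(1, n - segLength + 1, by = step)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))
  } else rep(1, segLength)
  wnorm <- sum(w^2)
  nf <- floor(segLength / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segLength - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)
    p <- Mod(X[2:(nf + 1)])^2
    acc <- acc + p
  }
  # one-sided density: double the interior bins (the Nyquist bin, present
  # only for even segment lengths, has no folded counterpart)
  pw <- acc / length(starts) * dt / wnorm
  interior <- if (segLength %% 2 == 0) seq_len(nf - 1) else seq_len(nf)
  pw[interior] <- 2 * pw[interior]
  freq <- (1:nf) / (segLength * dt)
  list(freq = freq, power = pw, df = 1 / (segLength * dt),
       segLength = segLength, window = window)
}

#' Low-frequency spectral peak and width of ongoing activity
#'
#' Estimates the Welch PSD and locates the dominant peak in the slow band
#' (below \code{fMax}, DC excluded), reporting it as a period together with
#' its full width at half maximum (from linearly interpolated half-power
#' crossings, converted to period units). The peak is flagged absent when it
#' does not exceed \code{peakFactor} times the median band power; series
#' shorter than two cycles of 300 s are flagged unreliable.
#'
#' @param series a \code{RateSeries} or \code{BinnedCounts} (or numeric with
#'   \code{dt}).
#' @param dt sampling period when \code{series} is a bare vector.
#' @param fMax upper edge of the slow band (Hz); default 0.1.
#' @param peakFactor detection threshold relative to median band power;
#'   default 3.
#' @param ... passed to [welchPsd()].
#' @return List with \code{peakPeriod} (s), \code{fwhm} (s), \code{peakFreq},
#'   \code{peakPower}, \code{present}, \code{reliable}, and the
#'   \code{spectrum}.
#' @export
psdPeak <- function(series, dt = NULL, fMax = 0.1, peakFactor = 3, ...) {
  sp <- welchPsd(series, dt = dt, ...)
  dur <- if (is(series, "RateSeries")) length(rateValues(series)) * series@step
         else if (is(series, "BinnedCounts")) length(counts(series)) * series@binWidth
         else length(series) * dt
  reliable <- dur >= 600
  band <- which(sp$freq > 0 & sp$freq < fMax)
  if (!length(band))
    return(list(peakPeriod = NA, fwhm = NA, present = FALSE,
                reliable = reliable, spectrum = sp))
  pk <- band[which.max(sp$power[band])]
  if (sp$power[pk] <= 0)  # degenerate (constant) input: no peak at all
    return(list(peakPeriod = NA, fwhm = NA, peakFreq = NA,
                peakPower = 0, present = FALSE, reliable = reliable,
                spectrum = sp))
  present <- sp$power[pk] > peakFactor * median(sp$power[band])
  half <- sp$power[pk] / 2
  # half-power crossing below the peak
  f_lo <- sp$freq[pk]; i <- pk
  while (i > 1 && sp$power[i - 1] > half) i <- i - 1
  f_lo <- if (i == 1) sp$freq[1] else {
    approx(sp$power[c(i - 1, i)], sp$freq[c(i - 1, i)], xout = half)$y
  }
  f_hi <- sp$freq[pk]; i <- pk
  while (i < length(sp$freq) && sp$power[i + 1] > half) i <- i + 1
  f_hi <- if (i == length(sp$freq)) sp$freq[i] else {
    approx(sp$power[c(i, i + 1)], sp$freq[c(i, i + 1)], xout = half)$y
  }
  fwhm <- abs(1 / f_lo - 1 / f_hi)
  list(peakPeriod = 1 / sp$freq[pk], fwhm = fwhm, peakFreq = sp$freq[pk],
       peakPower = sp$power[pk], present = present, reliable = reliable,
       spectrum = sp)
}

#' Interspike-interval variability summary
#'
#' @param train a \code{SpikeTrain} with at least 2 spikes.
#' @return List with \code{cv} (sd(ISI)/mean(ISI)), \code{meanIsi} (s),
#'   \code{sdIsi}, \code{nSpikes}. With fewer than 2 spikes, NA values with
#'   \code{defined = FALSE}.
#' @export
isiStats <- function(train) {
  tms <- spikeTimes(train)
  if (length(tms) < 2)
    return(list(cv = NA_real_, meanIsi = NA_real_, sdIsi = NA_real_,
                nSpikes = length(tms), defined = FALSE))
  isi <- diff(tms)
  list(cv = sd(isi) / mean(isi), meanIsi = mean(isi), sdIsi = sd(isi),
       nSpikes = length(tms), defined = TRUE)
}

#' Periodic-kernel GP negative log marginal likelihood period scan
#'
#' For each candidate period, computes the exact Gaussian-process negative
#' log marginal likelihood of the mean-centered rate under the periodic
#' kernel with fixed variance and lengthscale plus a fixed Gaussian noise
#' variance. Rhythmic inputs produce a sharp NLML minimum at the true period
#' (with subharmonic local minima at integer multiples); aperiodic inputs
#' give flat profiles.
#'
#' @param rate a \code{RateSeries} (typically 2 s smoothing/step) or numeric
#'   vector with \code{dt}.
#' @param periods candidate periods (s); default 200 log-spaced values over
#'   0.1-1500 s.
#' @param lengthscale fixed kernel lengthscale; default 1.0.
#' @param variance fixed kernel variance; default 5.0.
#' @param noiseVar Gaussian noise variance; default the sample variance of
#'   the centered rate.
#' @param dt sampling period when \code{rate} is a bare vector.
#' @param maxSamples cap on samples used (subsampled evenly when longer);
#'   default 800.
#' @return List with \code{periods}, \code{nlml}, \code{bestPeriod} (argmin),
#'   \code{flat} (profile range relative to its median absolute level).
#' @export
periodScan <- function(rate, periods = periodGrid(), lengthscale = 1.0,
                       variance = 5.0, noiseVar = NULL, dt = NULL,
                       maxSamples = 800) {
  if (is(rate, "RateSeries")) { dt <- rate@step; x <- rateValues(rate) }
  else { stopifnot(!is.null(dt)); x <- as.numeric(rate) }
  x <- x - mean(x)
  n <- length(x)
  if (n > maxSamples) {
    idx <- round(seq(1, n, length.out = maxSamples))
    x <- x[idx]; tg <- (idx - 1) * dt
  } else tg <- (seq_len(n) - 1) * dt
  if (is.null(noiseVar)) noiseVar <- max(var(x), 1e-8)
  nlml <- vapply(periods, function(p) {
    K <- periodicKernel(tg, tg, variance = variance, period = p,
                        lengthscale = lengthscale)
    diag(K) <- diag(K) + noiseVar + 1e-8 * variance
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) {  # ill-conditioned: add jitter and retry
      diag(K) <- diag(K) + 1e-4 * variance
      L <- chol(K)
    }
    a <- backsolve(L, forwardsolve(t(L), x))
    0.5 * sum(x * a) + sum(log(diag(L))) + 0.5 * length(x) * log(2 * pi)
  }, 0)
  rng <- diff(range(nlml))
  list(periods = periods, nlml = nlml,
       bestPeriod = periods[which.min(nlml)],
       flat = rng / max(abs(median(nlml)), 1e-12))
}

#' Default candidate-period grid
#'
#' 200 logarithmically spaced periods spanning 0.1-1500 s (resolving both
#' sub-second and multi-minute scales).
#'
#' @param from,to grid range (s).
#' @param n number of candidates; default 200.
#' @return Numeric vector of periods (s).
#' @export
periodGrid <- function(from = 0.1, to = 1500, n = 200) {
  exp(seq(log(from), log(to), length.out = n))
}
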