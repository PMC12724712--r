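#' @import methods
#' @importFrom stats rpois runif rnorm rgamma sd var quantile median fft mvfft
#'   dpois dnorm optim uniroot approx kruskal.test
#' @importFrom utils read.delim write.table head tail
#' @useDynLib mtspike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_CLASSES <- c("ON", "OFF", "NEUTRAL", "UNKNOWN")

#' SpikeTrain: spike times of one recorded unit
#'
#' Holds the sorted spike times of a single unit together with its animal and
#' functional cell-class labels and the recording span. Times are in seconds.
#'
#' @slot unitId character(1), unit identifier.
#' @slot animalId character(1), animal identifier.
#' @slot cellClass one of \code{"ON"}, \code{"OFF"}, \code{"NEUTRAL"},
#'   \code{"UNKNOWN"}.
#' @slot spikeTimes numeric, nondecreasing spike times (s) within the span.
#' @slot tStart,tStop numeric(1), recording span (s), \code{tStop > tStart}.
#'
#' @examples
#' st <- SpikeTrain(c(0.1, 0.4, 0.9), tStart = 0, tStop = 2)
#' nSpikes(st)
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", animalId = "character",
    cellClass = "character", spikeTimes = "numeric",
    tStart = "numeric", tStop = "numeric"),
  prototype(unitId = "u1", animalId = "a1", cellClass = "UNKNOWN"))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@cellClass) != 1L || !object@cellClass %in% VALID_CLASSES)
    msg <- c(msg, sprintf("cellClass must be one of %s",
                          paste(VALID_CLASSES, collapse = ", ")))
  if (length(object@tStart) != 1L || length(object@tStop) != 1L ||
      !is.finite(object@tStart) || !is.finite(object@tStop) ||
      object@tStop <= object@tStart)
    msg <- c(msg, "tStop must be a single finite value > tStart")
  ts <- object@spikeTimes
  if (length(ts)) {
    if (is.unsorted(ts)) msg <- c(msg, "spikeTimes must be nondecreasing")
    if (any(!is.finite(ts))) msg <- c(msg, "spikeTimes must be finite")
    else if (min(ts) < object@tStart || max(ts) > object@tStop)
      msg <- c(msg, "spikeTimes must lie within [tStart, tStop]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SpikeTrain-class
#' @param spikeTimes numeric vector of spike times (s); sorted if needed.
#' @param tStart,tStop recording span (s); default to the data range.
#' @param unitId,animalId,cellClass unit metadata.
#' @return A \code{SpikeTrain} object.
#' @export
SpikeTrain <- function(spikeTimes = numeric(0), tStart = NULL, tStop = NULL,
                       unitId = "u1", animalId = "a1", cellClass = "UNKNOWN") {
  spikeTimes <- as.numeric(spikeTimes)
  if (is.unsorted(spikeTimes)) spikeTimes <- sort(spikeTimes)
  if (is.null(tStart)) tStart <- if (length(spikeTimes)) min(spikeTimes) else 0
  if (is.null(tStop))
    tStop <- if (length(spikeTimes)) max(spikeTimes) + 1e-9 else 1
  new("SpikeTrain", unitId = as.character(unitId),
      animalId = as.character(animalId), cellClass = as.character(cellClass),
      spikeTimes = spikeTimes, tStart = as.numeric(tStart),
      tStop = as.numeric(tStop))
}

#' BinnedCounts: regularly binned spike counts
#'
#' Nonnegative integer counts on a regular half-open binning
#' \code{[t0 + (i-1) w, t0 + i w)}.
#'
#' @slot t0 numeric(1), left edge of the first bin (s).
#' @slot binWidth numeric(1), bin width (s), > 0.
#' @slot counts integer vector of counts per bin.
#' @export
setClass("BinnedCounts",
  representation(t0 = "numeric", binWidth = "numeric", counts = "integer"))

setValidity("BinnedCounts", function(object) {
  msg <- character(0)
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive value")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @rdname BinnedCounts-class
#' @param counts integer vector of per-bin counts.
#' @param t0 left edge of the first bin (s).
#' @param binWidth bin width (s).
#' @return A \code{BinnedCounts} object.
#' @export
BinnedCounts <- function(counts, t0 = 0, binWidth = 1) {
  ci <- as.integer(round(counts))
  if (any(abs(counts - ci) > 1e-6))
    stop("counts must be integers")
  new("BinnedCounts", t0 = as.numeric(t0), binWidth = as.numeric(binWidth),
      counts = ci)
}

#' RateSeries: regularly sampled firing-rate (or bpm) series
#'
#' @slot t0 numeric(1), time of the first sample (s).
#' @slot step numeric(1), sampling period (s).
#' @slot values numeric vector (spikes/s, or bpm for heart rate).
#' @slot smoothingWidth numeric(1), width of the smoothing kernel used (s);
#'   0 when unsmoothed.
#' @export
setClass("RateSeries",
  representation(t0 = "numeric", step = "numeric", values = "numeric",
                 smoothingWidth = "numeric"),
  prototype(smoothingWidth = 0))

setValidity("RateSeries", function(object) {
  msg <- character(0)
  if (length(object@step) != 1L || object@step <= 0)
    msg <- c(msg, "step must be a single positive value")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname RateSeries-class
#' @param values numeric samples.
#' @param t0 time of the first sample (s).
#' @param step sampling period (s).
#' @param smoothingWidth smoothing-kernel width (s).
#' @return A \code{RateSeries} object.
#' @export
RateSeries <- function(values, t0 = 0, step = 2, smoothingWidth = 0) {
  new("RateSeries", t0 = as.numeric(t0), step = as.numeric(step),
      values = as.numeric(values), smoothingWidth = as.numeric(smoothingWidth))
}

#' PSTH: peri-stimulus time histogram
#'
#' Spike counts summed element-wise across included aligned trial windows.
#'
#' @slot alignment \code{"withdrawal"} or \code{"heat_onset"}.
#' @slot window numeric(2), window relative to the alignment event (s).
#' @slot binWidth numeric(1), bin width (s).
#' @slot summedCounts integer vector, per-bin counts summed over trials.
#' @slot nTrials integer(1), number of included trial windows.
#' @slot nCells integer(1), number of distinct units contributing.
#' @export
setClass("PSTH",
  representation(alignment = "character", window = "numeric",
    binWidth = "numeric", summedCounts = "integer",
    nTrials = "integer", nCells = "integer"))

setValidity("PSTH", function(object) {
  msg <- character(0)
  if (!object@alignment %in% c("withdrawal", "heat_onset"))
    msg <- c(msg, "alignment must be 'withdrawal' or 'heat_onset'")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing pair of times")
  if (any(object@summedCounts < 0L))
    msg <- c(msg, "summedCounts must be nonnegative")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' Accessors for mtspike data classes
#'
#' \code{spikeTimes}, \code{nSpikes}, \code{cellClass}, \code{animalId},
#' \code{unitId}, \code{recordingSpan} extract the corresponding fields of a
#' \code{SpikeTrain}; \code{counts} and \code{binTimes} the contents of a
#' \code{BinnedCounts}; \code{rateValues} and \code{rateTimes} those of a
#' \code{RateSeries}.
#'
#' @param x the object.
#' @return The requested field; \code{binTimes}/\code{rateTimes} return bin
#'   centers / sample times in seconds.
#' @name accessors
#' @rdname accessors
#' @aliases spikeTimes
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikeTimes)

#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@spikeTimes))

#' @export
setGeneric("cellClass", function(x) standardGeneric("cellClass"))
#' @rdname accessors
#' @export
setMethod("cellClass", "SpikeTrain", function(x) x@cellClass)

#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setMethod("animalId", "SpikeTrain", function(x) x@animalId)

#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(x) x@unitId)

#' @export
setGeneric("recordingSpan", function(x) standardGeneric("recordingSpan"))
#' @rdname accessors
#' @export
setMethod("recordingSpan", "SpikeTrain", function(x) c(x@tStart, x@tStop))

#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "BinnedCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("counts", "PSTH", function(x) x@summedCounts)

#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))
#' @rdname accessors
#' @export
setMethod("binTimes", "BinnedCounts", function(x)
  x@t0 + (seq_along(x@counts) - 0.5) * x@binWidth)
#' @rdname accessors
#' @export
setMethod("binTimes", "PSTH", function(x)
  x@window[1] + (seq_along(x@summedCounts) - 0.5) * x@binWidth)

#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setMethod("rateValues", "RateSeries", function(x) x@values)

#' @export
setGeneric("rateTimes", function(x) standardGeneric("rateTimes"))
#' @rdname accessors
#' @export
setMethod("rateTimes", "RateSeries", function(x)
  x@t0 + (seq_along(x@values) - 1) * x@step)

## ---- show ----

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain %s/%s [%s]: %d spikes in [%.3f, %.3f] s (%.2f Hz)\n",
    object@animalId, object@unitId, object@cellClass,
    length(object@spikeTimes), object@tStart, object@tStop,
    length(object@spikeTimes) / (object@tStop - object@tStart)))
})

setMethod("show", "BinnedCounts", function(object) {
  cat(sprintf("BinnedCounts: %d bins of %.3g s from t0 = %.3f s (total %d)\n",
    length(object@counts), object@binWidth, object@t0, sum(object@counts)))
})

setMethod("show", "RateSeries", function(object) {
  cat(sprintf(
    "RateSeries: %d samples, step %.3g s, t0 = %.3f s, mean %.3f (smooth %.3g s)\n",
    length(object@values), object@step, object@t0, mean(object@values),
    object@smoothingWidth))
})

setMethod("show", "PSTH", function(object) {
  cat(sprintf(
    "PSTH (%s-aligned): [%g, %g] s, %d bins of %.3g s, %d trials, %d cells\n",
    object@alignment, object@window[1], object@window[2],
    length(object@summedCounts), object@binWidth, object@nTrials,
    object@nCells))
})
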