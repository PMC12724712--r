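## Delimited-text interchange, binning, smoothing, trial windows, PSTHs.
##
## Interchange files are UTF-8 tab-separated:
##   spikes.tsv: animal_id, unit_id, cell_class, spike_time_s
##   events.tsv: animal_id, trial_index, heat_onset_s, withdrawal_s ("" = none)
##   hr.tsv:     animal_id, time_s, bpm

#' Read a spike table into SpikeTrain objects
#'
#' Parses a tab-separated spike table (columns \code{animal_id},
#' \code{unit_id}, \code{cell_class}, \code{spike_time_s}) into one
#' \code{SpikeTrain} per (animal, unit) pair. An optional header comment line
#' \code{# t_start=<s> t_stop=<s>} fixes the recording span; otherwise the
#' span of each unit is taken from its own min/max spike time.
#'
#' @param path path to the spike table.
#' @return A list of \code{SpikeTrain} objects, ordered by (animal, unit).
#' @seealso [writeSpikeTable()]
#' @export
readSpikeTable <- function(path) {
  first <- readLines(path, n = 1L)
  span <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("-?[0-9.eE+]+", first))[[1]]
    if (length(m) >= 2) span <- as.numeric(m[1:2])
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("animal_id", "unit_id", "cell_class", "spike_time_s")
  if (!all(req %in% names(df)))
    stop("spike table must have columns ", paste(req, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$spike_time_s))))
  if (length(bad))
    stop("malformed spike_time_s at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  df$spike_time_s <- as.numeric(df$spike_time_s)
  key <- interaction(df$animal_id, df$unit_id, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(d) {
    tms <- d$spike_time_s
    if (is.unsorted(tms)) {
      warning("unsorted spike times for unit ", d$unit_id[1], "; sorting")
      tms <- sort(tms)
    }
    SpikeTrain(tms,
      tStart = if (is.null(span)) min(tms) else span[1],
      tStop  = if (is.null(span)) max(tms) + 1e-9 else span[2],
      unitId = d$unit_id[1], animalId = d$animal_id[1],
      cellClass = d$cell_class[1])
  })
  unname(out)
}

#' Write SpikeTrain objects to a spike table
#'
#' Inverse of [readSpikeTable()]. The common recording span is recorded in a
#' header comment so that a round trip preserves \code{tStart}/\code{tStop}.
#'
#' @param trains list of \code{SpikeTrain}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSpikeTable <- function(trains, path) {
  stopifnot(length(trains) > 0)
  span <- c(min(vapply(trains, function(s) s@tStart, 0)),
            max(vapply(trains, function(s) s@tStop, 0)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# t_start=%.9f t_stop=%.9f", span[1], span[2]), con)
  writeLines("animal_id\tunit_id\tcell_class\tspike_time_s", con)
  for (s in trains) {
    if (!nSpikes(s)) next
    writeLines(sprintf("%s\t%s\t%s\t%.9f", s@animalId, s@unitId,
                       s@cellClass, s@spikeTimes), con)
  }
  invisible(path)
}

#' Read an event table
#'
#' @param path tab-separated file with columns \code{animal_id},
#'   \code{trial_index}, \code{heat_onset_s}, \code{withdrawal_s} (empty when
#'   no withdrawal occurred).
#' @return data.frame ordered by animal then heat onset, with
#'   \code{withdrawal_s} as numeric (NA when absent).
#' @export
readEventTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("animal_id", "trial_index", "heat_onset_s", "withdrawal_s")
  if (!all(req %in% names(df)))
    stop("event table must have columns ", paste(req, collapse = ", "))
  df$heat_onset_s <- as.numeric(df$heat_onset_s)
  df$withdrawal_s <- suppressWarnings(as.numeric(df$withdrawal_s))
  if (any(!is.na(df$withdrawal_s) & df$withdrawal_s < df$heat_onset_s))
    stop("withdrawal_s must be >= heat_onset_s")
  df[order(df$animal_id, df$heat_onset_s), , drop = FALSE]
}

#' Write an event table
#' @param events data.frame as returned by [readEventTable()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEventTable <- function(events, path) {
  ev <- events
  ev$withdrawal_s <- ifelse(is.na(ev$withdrawal_s), "",
                            sprintf("%.9f", ev$withdrawal_s))
  ev$heat_onset_s <- sprintf("%.9f", ev$heat_onset_s)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("animal_id\ttrial_index\theat_onset_s\twithdrawal_s", con)
  writeLines(do.call(sprintf,
    c(list("%s\t%d\t%s\t%s"), ev[c("animal_id", "trial_index",
                                   "heat_onset_s", "withdrawal_s")])), con)
  invisible(path)
}

#' Read / write a heart-rate table
#'
#' Columns \code{animal_id}, \code{time_s}, \code{bpm}; one [RateSeries()] per
#' animal on reading (the grid is assumed regular per animal).
#'
#' @param path file path.
#' @return \code{readHeartRateTable}: named list of \code{RateSeries}, one per
#'   animal.
#' @export
readHeartRateTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("animal_id", "time_s", "bpm")
  if (!all(req %in% names(df)))
    stop("heart-rate table must have columns ", paste(req, collapse = ", "))
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$time_s), ]
    step <- if (nrow(d) > 1) median(diff(d$time_s)) else 2
    RateSeries(d$bpm, t0 = d$time_s[1], step = step)
  })
}

#' @rdname readHeartRateTable
#' @param series named list of \code{RateSeries} (names = animal ids).
#' @export
writeHeartRateTable <- function(series, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("animal_id\ttime_s\tbpm", con)
  for (a in names(series)) {
    rs <- series[[a]]
    writeLines(sprintf("%s\t%.9f\t%.9f", a, rateTimes(rs), rateValues(rs)),
               con)
  }
  invisible(path)
}

#' Bin spikes into regular half-open bins
#'
#' Bins are half-open \code{[edge, edge + width)}, left-anchored at \code{t0};
#' a trailing partial bin (when \code{t1 - t0} is not a multiple of
#' \code{width}) is dropped.
#'
#' @param train a \code{SpikeTrain}.
#' @param t0,t1 binning interval (s), \code{t1 > t0}.
#' @param width bin width (s), e.g. 0.05 for evoked-count modeling.
#' @return A \code{BinnedCounts}.
#' @examples
#' st <- SpikeTrain(c(0.01, 0.02, 0.06), tStart = 0, tStop = 0.2)
#' counts(binSpikes(st, 0, 0.1, 0.05))  # 2 1
#' @export
binSpikes <- function(train, t0, t1, width) {
  if (width <= 0) stop("width must be > 0")
  if (t1 <= t0) stop("t1 must be > t0")
  nb <- floor((t1 - t0) / width + 1e-9)
  if (nb < 1L) stop("interval shorter than one bin")
  tms <- spikeTimes(train)
  tms <- tms[tms >= t0 & tms < t0 + nb * width]
  idx <- floor((tms - t0) / width) + 1
  idx[idx > nb] <- nb  # guard against floating round-up at the right edge
  cnt <- tabulate(idx, nbins = nb)
  new("BinnedCounts", t0 = t0, binWidth = width, counts = as.integer(cnt))
}

#' Smooth a spike train into a firing-rate series
#'
#' Converts spikes to a rate (spikes/s) with a moving kernel of width
#' \code{width} sampled every \code{step} seconds; the first and last
#' \code{width} seconds are trimmed to avoid edge artifacts. The default
#' boxcar kernel counts spikes in \code{[t - width/2, t + width/2)} and
#' divides by \code{width}; a Gaussian kernel (sd = width/2) is available.
#'
#' @param train a \code{SpikeTrain}.
#' @param width kernel width (s); default 2.
#' @param step sampling period (s); default 2.
#' @param kernel \code{"boxcar"} (default) or \code{"gaussian"}.
#' @return A \code{RateSeries} with \code{smoothingWidth = width}.
#' @export
smoothRate <- function(train, width = 2, step = 2, kernel = c("boxcar",
                                                              "gaussian")) {
  kernel <- match.arg(kernel)
  span <- recordingSpan(train)
  if (diff(span) <= 2 * width)
    stop("recording span must exceed twice the smoothing width")
  tg <- seq(span[1] + width, span[2] - width, by = step)
  if (!length(tg)) stop("no samples left after trimming")
  tms <- spikeTimes(train)
  vals <- if (kernel == "boxcar") {
    lo <- findInterval(tg - width / 2, tms)
    hi <- findInterval(tg + width / 2, tms, left.open = TRUE)
    (hi - lo) / width
  } else {
    sdk <- width / 2
    vapply(tg, function(tc) sum(dnorm(tms, tc, sdk)), 0)
  }
  RateSeries(vals, t0 = tg[1], step = step, smoothingWidth = width)
}

#' Extract aligned trial windows with exclusion rules
#'
#' For each trial, spike times are shifted so that the alignment event
#' (withdrawal or heat onset) is at time 0 and the window \code{[-pre, post]}
#' is cut out. A window is marked excluded when the recording ends before
#' \code{event + post} or when the next trial's event falls inside the window;
#' trials lacking the alignment marker are skipped (with a message).
#'
#' @param train a \code{SpikeTrain}.
#' @param events event data.frame (see [readEventTable()]); only rows matching
#'   the train's animal are used.
#' @param alignment \code{"withdrawal"} or \code{"heat_onset"}.
#' @param pre,post window extent before/after the event (s); defaults 10, 100.
#' @return A list of windows; each has elements \code{times} (aligned spike
#'   times), \code{trialIndex}, \code{eventTime}, \code{included} (logical)
#'   and \code{pre}/\code{post}/\code{alignment}.
#' @export
trialWindows <- function(train, events, alignment = c("withdrawal",
                                                      "heat_onset"),
                         pre = 10, post = 100) {
  alignment <- match.arg(alignment)
  ev <- events[events$animal_id == animalId(train), , drop = FALSE]
  if (!nrow(ev)) stop("no events for animal ", animalId(train))
  ev <- ev[order(ev$heat_onset_s), , drop = FALSE]
  acol <- if (alignment == "withdrawal") ev$withdrawal_s else ev$heat_onset_s
  span <- recordingSpan(train)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    a <- acol[i]
    if (is.na(a)) {
      message("trial ", ev$trial_index[i], ": no ", alignment,
              " marker; skipped")
      next
    }
    nxt <- if (i < nrow(ev)) {
      min(ev$heat_onset_s[i + 1], ev$withdrawal_s[i + 1], na.rm = TRUE)
    } else Inf
    included <- (span[2] >= a + post) && (nxt >= a + post)
    tms <- spikeTimes(train)
    tms <- tms[tms >= a - pre & tms <= a + post] - a
    out[[length(out) + 1L]] <- list(times = tms,
      trialIndex = ev$trial_index[i], eventTime = a, included = included,
      pre = pre, post = post, alignment = alignment,
      unitId = unitId(train))
  }
  out
}

#' Build a PSTH from aligned trial windows
#'
#' Sums per-bin spike counts element-wise over all *included* windows.
#' Windows must share alignment and extent.
#'
#' @param windows list of aligned windows from [trialWindows()] (possibly
#'   concatenated over units/animals).
#' @param binWidth bin width (s); default 0.05.
#' @return A \code{PSTH}; with zero included windows, a PSTH of zeros with
#'   \code{nTrials = 0} is returned with a warning.
#' @export
buildPSTH <- function(windows, binWidth = 0.05) {
  stopifnot(length(windows) > 0)
  aligns <- unique(vapply(windows, `[[`, "", "alignment"))
  if (length(aligns) != 1L) stop("mixed alignments in window list")
  pre <- unique(vapply(windows, `[[`, 0, "pre"))
  post <- unique(vapply(windows, `[[`, 0, "post"))
  if (length(pre) != 1L || length(post) != 1L)
    stop("windows differ in extent")
  inc <- Filter(function(w) isTRUE(w$included), windows)
  nb <- floor((pre + post) / binWidth + 1e-9)
  total <- integer(nb)
  for (w in inc) {
    tms <- w$times
    tms <- tms[tms >= -pre & tms < -pre + nb * binWidth]
    idx <- floor((tms + pre) / binWidth) + 1
    idx[idx > nb] <- nb
    total <- total + tabulate(idx, nbins = nb)
  }
  if (!length(inc)) warning("no included windows; PSTH is empty")
  ncells <- length(unique(vapply(inc, function(w)
    as.character(w$unitId %||% ""), "")))
  new("PSTH", alignment = aligns, window = c(-pre, post),
      binWidth = binWidth, summedCounts = as.integer(total),
      nTrials = length(inc), nCells = ncells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
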