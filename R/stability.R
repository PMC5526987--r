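# Halo decay over timed image series: time-to-failure with censoring,
# surviving-fraction curves and mean time to decay.
#
# Failure is defined by the measurement itself: with a relative outer
# threshold, photo-induced DNA loss drops the local maximum until
# localMax - outerValue < 1 and the outer edge can no longer be measured;
# the cell "fails" to return a value at that frame.

#' Time to decay of one cell series
#'
#' Measures each frame and tracks the cell as the object nearest the
#' previous frame's centroid (nearest the image centre in the first frame),
#' within a displacement gate. The fail time is the time of the first frame
#' whose measurement status is not `measured` (or where the tracked object
#' vanishes); a series measurable at every frame is censored at
#' `censorTime`. Timing follows the first failure: later frames are not
#' revisited even if transiently measurable again.
#'
#' @param series a [CellTimeSeries-class].
#' @param config a [ThresholdConfig-class] with `outerMode = "relative"`
#'   (failure is defined by the relative outer threshold becoming
#'   unreachable).
#' @param censorTime sentinel fail time for series that never fail
#'   (default 70 s).
#' @param maxDisplacement tracking gate in pixels (default 50).
#' @return A one-row data.frame: `cell_id`, `fail_time_s`, `censored`,
#'   `note` (empty, or a tracking/detection diagnostic for failures not
#'   caused by thresholds).
#' @examples
#' sp <- phantomSpec(c(80, 80), rnRadius = 12, peak = 255, haloScale = 25)
#' ts <- renderTimeSeries(sp, decayRate = 0.02, 160, 160, outerValue = 180)
#' decayRecord(ts$series, parseThresholds("x75/x180", minObjectArea = 50))
#' @export
decayRecord <- function(series, config, censorTime = 70,
                        maxDisplacement = 50) {
  stopifnot(is(series, "CellTimeSeries"), is(config, "ThresholdConfig"))
  if (config@outerMode != "relative")
    stop("decay analysis requires a relative outer threshold (outerMode = 'relative')",
         call. = FALSE)
  prev <- NULL
  note <- ""
  fr <- frames(series)
  for (f in fr) {
    res <- measureField(f, config)
    m <- measurements(res)
    t <- frameTime(f)
    if (!nrow(m)) {
      note <- sprintf("no object detected at t = %g s", t)
      return(data.frame(cell_id = cellId(series), fail_time_s = t,
                        censored = FALSE, note = note))
    }
    ctr <- t(vapply(regions(res), function(r) r$centroid, numeric(2)))
    ref <- if (is.null(prev)) dim(pixels(f)) / 2 else prev
    d <- sqrt((ctr[, 1] - ref[1])^2 + (ctr[, 2] - ref[2])^2)
    i <- which.min(d)
    if (!is.null(prev) && d[i] > maxDisplacement) {
      note <- sprintf("tracking lost at t = %g s (nearest object %.1f px away)",
                      t, d[i])
      return(data.frame(cell_id = cellId(series), fail_time_s = t,
                        censored = FALSE, note = note))
    }
    if (m$status[i] != "measured")
      return(data.frame(cell_id = cellId(series), fail_time_s = t,
                        censored = FALSE, note = ""))
    prev <- ctr[i, ]
  }
  data.frame(cell_id = cellId(series), fail_time_s = censorTime,
             censored = TRUE, note = "")
}

#' Surviving-halo curve
#'
#' Percentage of the population still measurable at each time: a record
#' survives time `t` when its fail time is strictly greater than `t`;
#' censored records survive at every observed time.
#'
#' @param records data.frame of decay records (rows from [decayRecord()]).
#' @param times numeric vector of times, seconds (default 0 to 60 by 10).
#' @return data.frame with `time_s` and `percent_surviving`.
#' @examples
#' rec <- data.frame(fail_time_s = c(10, 20, 70, 70),
#'                   censored = c(FALSE, FALSE, TRUE, TRUE))
#' survivingFraction(rec, times = 15)  # 75%
#' @export
survivingFraction <- function(records, times = seq(0, 60, by = 10)) {
  if (!NROW(records))
    stop("empty population: no decay records", call. = FALSE)
  pct <- vapply(times, function(t)
    100 * mean(records$fail_time_s > t | records$censored), numeric(1))
  data.frame(time_s = times, percent_surviving = pct)
}

#' Mean time to decay
#'
#' Arithmetic mean and SEM of the per-cell fail times, with censored cells
#' contributing the sentinel value (70 s by default in [decayRecord()]).
#'
#' @param records data.frame of decay records.
#' @return A list with `mean_s`, `sem_s` (`NA` for a single record) and `n`.
#' @examples
#' meanTimeToDecay(data.frame(fail_time_s = c(10, 30, 70),
#'                            censored = c(FALSE, FALSE, TRUE)))
#' @export
meanTimeToDecay <- function(records) {
  if (!NROW(records))
    stop("empty population: no decay records", call. = FALSE)
  ms <- meanSem(records$fail_time_s)
  list(mean_s = ms$mean, sem_s = ms$sem, n = NROW(records))
}
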