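# Population summaries, the Student's t convention, percent-of-reference
# comparisons and the RN-threshold calibration against visual estimates.

#' Mean and standard error
#'
#' @param values numeric vector, length >= 1.
#' @return A list with `mean` and `sem` (sample SD over sqrt(n); `NA` for a
#'   single value) and `n`.
#' @examples
#' meanSem(c(2, 4, 6))  # mean 4, sem 1.1547
#' @export
meanSem <- function(values) {
  n <- length(values)
  if (n == 0L) stop("meanSem requires at least one value", call. = FALSE)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Significance stars at the field's cuts
#'
#' `*` for p < 0.05, `**` for p < 0.005, `***` for p < 0.0005.
#'
#' @param p p-value.
#' @return `""`, `"*"`, `"**"` or `"***"`.
#' @export
significanceStars <- function(p) {
  if (p < 0.0005) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else ""
}

#' Two-sample Student's t-test with star annotation
#'
#' Equal-variance two-sided Student's t, with significance stars at the
#' 0.05 / 0.005 / 0.0005 cuts. Degenerate zero-variance inputs are handled
#' explicitly: identical constant groups give t = 0, p = 1; constant groups
#' with different means give an infinite statistic and p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A list with `t`, `p`, `stars` and `df`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two values", call. = FALSE)
  df <- length(a) + length(b) - 2L
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, stars = "", df = df))
    tt <- sign(mean(a) - mean(b)) * Inf
    return(list(t = tt, p = 0, stars = "***", df = df))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       stars = significanceStars(ht$p.value), df = unname(ht$parameter))
}

#' Derived radii as a percentage of reference radii
#'
#' Per-pair percent (100 x derived / reference), then the mean and SEM of
#' the percents — the comparison underlying both the exposure calibration
#' against a nuclear-matrix marker and the RN-threshold calibration against
#' visual estimates.
#'
#' @param reference positive reference radii (NM-marker or visual), pixels.
#' @param derived measured radii, pixels.
#' @return A list with `meanPercent`, `semPercent` and `n`.
#' @examples
#' percentOfReference(c(10, 20), c(11, 19))  # mean of 110% and 95% = 102.5%
#' @export
percentOfReference <- function(reference, derived) {
  stopifnot(length(reference) == length(derived), length(reference) >= 1L)
  if (any(reference <= 0))
    stop("reference radii must be strictly positive", call. = FALSE)
  ms <- meanSem(100 * derived / reference)
  list(meanPercent = ms$mean, semPercent = ms$sem, n = ms$n)
}

#' Calibrate the RN offset against visual training estimates
#'
#' For each candidate offset `x`, measures every training field with
#' `rnOffset = x`, expresses the per-field mean RN radius as a percent of
#' that field's visually estimated RN radius, and averages over the
#' training set. The selected offset is the one whose mean percent is
#' closest to 100 (parity with the visual estimates); ties go to the
#' smaller offset. A candidate for which no training field yields a
#' measurable RN gets an `NA` percent and is excluded from selection.
#'
#' @param fields list of training [IntensityField-class] objects.
#' @param visualRadii numeric vector of visually estimated RN radii
#'   (pixels), one per field.
#' @param candidates integer vector of candidate RN offsets.
#' @param baseConfig [ThresholdConfig-class] supplying the remaining
#'   parameters.
#' @return A list with `bestOffset` and `table`, a data.frame
#'   (`candidate_x`, `n_measured`, `mean_percent`, `sem_percent`,
#'   `selected`).
#' @export
calibrateRnOffset <- function(fields, visualRadii, candidates,
                              baseConfig = thresholdConfig()) {
  stopifnot(length(fields) >= 1L, length(fields) == length(visualRadii),
            length(candidates) >= 1L)
  candidates <- as.integer(candidates)
  tab <- data.frame(candidate_x = candidates, n_measured = 0L,
                    mean_percent = NA_real_, sem_percent = NA_real_,
                    selected = FALSE)
  for (k in seq_along(candidates)) {
    cfg <- baseConfig
    cfg@rnOffset <- candidates[k]
    validObject(cfg)
    pct <- rep(NA_real_, length(fields))
    for (j in seq_along(fields)) {
      m <- measurements(measureField(fields[[j]], cfg))
      rr <- m$rn_radius_px[!is.na(m$rn_radius_px)]
      if (length(rr)) pct[j] <- 100 * mean(rr) / visualRadii[j]
    }
    ok <- !is.na(pct)
    tab$n_measured[k] <- sum(ok)
    if (any(ok)) {
      ms <- meanSem(pct[ok])
      tab$mean_percent[k] <- ms$mean
      tab$sem_percent[k] <- ms$sem
    }
  }
  eligible <- which(!is.na(tab$mean_percent))
  if (!length(eligible))
    stop("no candidate offset yielded a measurable RN on the training set",
         call. = FALSE)
  dev <- abs(tab$mean_percent[eligible] - 100)
  best <- eligible[order(dev, tab$candidate_x[eligible])][1]
  tab$selected[best] <- TRUE
  list(bestOffset = tab$candidate_x[best], table = tab)
}

# segment intersection test (proper or improper) for simple-polygon check
segmentsIntersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  onSeg <- function(a, b, c)
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && onSeg(p3, p4, p1)) || (d2 == 0 && onSeg(p3, p4, p2)) ||
  (d3 == 0 && onSeg(p1, p2, p3)) || (d4 == 0 && onSeg(p1, p2, p4))
}

#' Equal-area radius of a traced polygon
#'
#' Shoelace area of a simple polygon traced around a halo (the visual
#' "polygon" size estimate), converted to the equal-area-circle radius.
#'
#' @param vertices n x 2 matrix (or data.frame) of (x, y) vertices in
#'   order, n >= 3.
#' @return Radius in pixels.
#' @examples
#' polygonRadius(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # ~0.564
#' @export
polygonRadius <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  # simple-polygon check: non-adjacent edges must not intersect
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (nxt[i] == j || nxt[j] == i) next
      if (segmentsIntersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        stop("self-intersecting polygon", call. = FALSE)
    }
  }
  x <- v[, 1]; y <- v[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area == 0)
    stop("degenerate polygon: vertices are collinear", call. = FALSE)
  sqrt(area / pi)
}
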