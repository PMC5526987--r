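# Synthetic halo phantoms with analytic ground truth.
#
# The radial model is a flat (or Gaussian) core at peak intensity p over
# background b, with a Gaussian halo tail of scale s beyond the core radius:
#   I(r) = b + (p - b)                          for r <= r_RN  (plateau)
#   I(r) = b + (p - b) exp(-((r - r_RN)/s)^2)   for r >  r_RN
# so the radius at which the profile crosses a threshold t in (b, p] has the
# closed form r(t) = r_RN + s sqrt(log((p - b)/(t - b))), which is what lets
# rendered phantoms serve as an analytic oracle for the measurement pipeline.

# run expr with a temporarily seeded RNG, restoring prior RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Analytic threshold-crossing radius of a phantom
#'
#' Radius at which a phantom's noise-free radial profile crosses intensity
#' `threshold`: `rnRadius + haloScale * sqrt(log((peak - bg)/(t - bg)))` for
#' thresholds in `(background, peak]` (for a non-plateau phantom the core
#' radius term is 0). At `t = peak` this is the core radius itself. A
#' threshold at or below background never crosses (the profile stays above
#' it; returns `Inf`); a threshold above the peak is never reached
#' (returns `NA`).
#'
#' @param spec a [PhantomSpec-class].
#' @param threshold intensity threshold(s).
#' @return Crossing radius in pixels (vectorised over `threshold`).
#' @examples
#' sp <- phantomSpec(c(0, 0), rnRadius = 20, peak = 255, haloScale = 30,
#'                   background = 5)
#' crossingRadius(sp, 255)  # == rnRadius
#' @export
crossingRadius <- function(spec, threshold) {
  stopifnot(is(spec, "PhantomSpec"))
  b <- spec@background; p <- spec@peak
  core <- if (spec@plateau) spec@rnRadius else 0
  vapply(threshold, function(t) {
    if (t > p) return(NA_real_)
    if (t <= b) return(Inf)
    core + spec@haloScale * sqrt(log((p - b) / (t - b)))
  }, numeric(1))
}

# support radius beyond which the rendered (rounded) profile is background:
# excess drops below 0.5 above background
supportRadius <- function(spec) {
  core <- if (spec@plateau) spec@rnRadius else 0
  core + spec@haloScale * sqrt(log(2 * (spec@peak - spec@background)))
}

# noise-free profile of one phantom over a pixel grid, as a sparse patch
renderPhantomPatch <- function(spec, width, height) {
  rs <- supportRadius(spec)
  r0 <- max(1L, floor(spec@center[1] - rs)); r1 <- min(height, ceiling(spec@center[1] + rs))
  c0 <- max(1L, floor(spec@center[2] - rs)); c1 <- min(width, ceiling(spec@center[2] + rs))
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - spec@center[1]; dc <- cols - spec@center[2]
  r <- sqrt(outer(dr^2, dc^2, "+"))
  excess <- spec@peak - spec@background
  core <- if (spec@plateau) spec@rnRadius else 0
  val <- spec@background + excess * exp(-(pmax(r - core, 0) / spec@haloScale)^2)
  list(rows = rows, cols = cols, values = val)
}

#' Render a multi-phantom field with ground truth
#'
#' Renders the noise-free radial profile of each phantom onto a
#' `height x width` canvas (pixels take the maximum over phantoms and their
#' backgrounds), optionally adds Gaussian noise (the largest `noiseSd` among
#' the phantoms), clips to \[0, 255\] and rounds to integers. Rendering is
#' deterministic given `seed`. Phantoms must fit inside the frame and must
#' not overlap above background, otherwise the analytic ground truth would
#' be ill-defined and an error is raised.
#'
#' @param specs list of [PhantomSpec-class] objects.
#' @param width,height frame size in pixels.
#' @param seed integer seed for the noise (ignored when all phantoms are
#'   noise free).
#' @param sourceId identifier stored on the rendered field.
#' @return A list with `field` (an [IntensityField-class]) and `truth`, a
#'   data.frame with one row per phantom: centre, core radius, peak,
#'   background, halo scale, intended class, and the analytic support radius.
#' @seealso [crossingRadius()] for crossing radii at arbitrary thresholds.
#' @export
renderField <- function(specs, width, height, seed = 1L,
                        sourceId = "phantom_field") {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, is, logical(1), class2 = "PhantomSpec")))
  supp <- vapply(specs, supportRadius, numeric(1))
  ctr <- t(vapply(specs, function(s) s@center, numeric(2)))
  inFrame <- ctr[, 1] - supp >= 1 & ctr[, 1] + supp <= height &
             ctr[, 2] - supp >= 1 & ctr[, 2] + supp <= width
  if (!all(inFrame))
    stop("phantom support extends beyond the frame; enlarge the frame or shrink the phantom")
  if (length(specs) > 1L) {
    d <- as.matrix(stats::dist(ctr))
    lim <- outer(supp, supp, "+")
    if (any(d[upper.tri(d)] < lim[upper.tri(lim)]))
      stop("phantoms overlap above background; ground truth would be ill-defined")
  }
  canvas <- matrix(max(vapply(specs, function(s) s@background, integer(1))),
                   height, width)
  for (s in specs) {
    patch <- renderPhantomPatch(s, width, height)
    sub <- canvas[patch$rows, patch$cols]
    canvas[patch$rows, patch$cols] <- pmax(sub, patch$values)
  }
  sd <- max(vapply(specs, function(s) s@noiseSd, numeric(1)))
  if (sd > 0)
    canvas <- canvas + withSeed(seed,
      matrix(stats::rnorm(length(canvas), 0, sd), height, width))
  canvas <- matrix(as.integer(pmin(255, pmax(0, round(canvas)))),
                   height, width)
  truth <- data.frame(
    phantom = seq_along(specs),
    center_row = ctr[, 1], center_col = ctr[, 2],
    rn_radius_px = vapply(specs, function(s) s@rnRadius, numeric(1)),
    peak = vapply(specs, function(s) s@peak, integer(1)),
    background = vapply(specs, function(s) s@background, integer(1)),
    halo_scale_px = vapply(specs, function(s) s@haloScale, numeric(1)),
    plateau = vapply(specs, function(s) s@plateau, logical(1)),
    class_intent = vapply(specs, function(s) s@classIntent, character(1)),
    support_radius_px = supp)
  list(field = intensityField(canvas, sourceId = sourceId), truth = truth)
}

#' Render a decaying time series of one phantom
#'
#' Renders frames of a single phantom whose intensity excess decays
#' exponentially, `peak(t) = background + (peak - background) exp(-rate t)`,
#' emulating photo-induced halo decay under repeated imaging. The analytic
#' fail time is the first frame time at which the rendered peak makes a
#' relative outer threshold unreachable (`peak(t) - outerValue < 1`); if no
#' frame fails the series is censored at `censorTime`.
#'
#' @param spec a [PhantomSpec-class]; the frame-0 phantom.
#' @param decayRate exponential decay rate per second (>= 0; 0 means no
#'   decay).
#' @param width,height frame size in pixels.
#' @param outerValue the relative outer-threshold offset against which the
#'   analytic fail time is computed (e.g. 180 for `x75/x180`).
#' @param frameTimes acquisition times in seconds (default 0 to 60 by 10).
#' @param censorTime sentinel fail time for series that never fail
#'   (default 70 s).
#' @param seed integer seed (per-frame noise seeds are derived from it).
#' @param cellId identifier for the series.
#' @return A list with `series` (a [CellTimeSeries-class]),
#'   `analyticFailTime` (seconds) and `censored` (logical).
#' @export
renderTimeSeries <- function(spec, decayRate, width, height, outerValue,
                             frameTimes = seq(0, 60, by = 10),
                             censorTime = 70, seed = 1L, cellId = "cell") {
  stopifnot(is(spec, "PhantomSpec"), decayRate >= 0,
            length(frameTimes) >= 1L, all(diff(frameTimes) > 0))
  b <- spec@background
  frames <- vector("list", length(frameTimes))
  renderedPeaks <- integer(length(frameTimes))
  for (i in seq_along(frameTimes)) {
    t <- frameTimes[i]
    pk <- b + (spec@peak - b) * exp(-decayRate * t)
    renderedPeaks[i] <- as.integer(pmin(255, pmax(0, round(pk))))
    # keep the frame's spec at the decayed peak; peak must stay > background
    pkInt <- max(renderedPeaks[i], b + 1L)
    spI <- phantomSpec(spec@center, spec@rnRadius, pkInt, spec@haloScale,
                       background = b, plateau = spec@plateau,
                       noiseSd = spec@noiseSd, classIntent = spec@classIntent)
    fr <- renderField(list(spI), width, height,
                      seed = seed + i, sourceId = sprintf("%s_t%02d", cellId, t))
    frames[[i]] <- intensityField(pixels(fr$field),
                                  sourceId = sourceId(fr$field), frameTime = t)
  }
  failIdx <- which(renderedPeaks - outerValue < 1L)
  censored <- length(failIdx) == 0L
  list(series = cellTimeSeries(frames, cellId = cellId),
       analyticFailTime = if (censored) censorTime else frameTimes[min(failIdx)],
       censored = censored)
}
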