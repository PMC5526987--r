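#' Parse the "xA/B" threshold shorthand
#'
#' The field shorthand names a setting by its two thresholds: `"x55/15"` is an
#' RN threshold 55 below the local maximum with an absolute outer threshold of
#' 15; `"x75/x180"` uses a relative outer threshold 180 below the local
#' maximum. The classification form `"RNx55/RN220"` parses to a
#' [ClassConfig-class].
#'
#' @param shorthand a string such as `"x55/15"`, `"x75/x180"` or
#'   `"RNx75/RN220"`.
#' @param ... further arguments (detection nuisance parameters) passed to
#'   [thresholdConfig()] or [classConfig()].
#' @return A [ThresholdConfig-class], or a [ClassConfig-class] for the
#'   `RNxA/RNB` form.
#' @examples
#' parseThresholds("x55/15")
#' parseThresholds("x75/x180")
#' parseThresholds("RNx75/RN220")
#' @seealso [formatThresholds()]
#' @export
parseThresholds <- function(shorthand, ...) {
  s <- trimws(shorthand)
  m <- regmatches(s, regexec("^RNx([0-9]+)/RN([0-9]+)$", s))[[1]]
  if (length(m) == 3L)
    return(classConfig(rnOffset = as.integer(m[2]),
                       brightCut = as.integer(m[3]), ...))
  m <- regmatches(s, regexec("^x([0-9]+)/(x?)([0-9]+)$", s))[[1]]
  if (length(m) != 4L)
    stop(sprintf("cannot parse threshold shorthand '%s' (expected 'xA/B', 'xA/xB' or 'RNxA/RNB')",
                 shorthand), call. = FALSE)
  thresholdConfig(rnOffset = as.integer(m[2]),
                  outerMode = if (nzchar(m[3])) "relative" else "absolute",
                  outerValue = as.integer(m[4]), ...)
}

#' Render a config back to its shorthand
#'
#' @param config a [ThresholdConfig-class] or [ClassConfig-class].
#' @return The shorthand string; `parseThresholds(formatThresholds(x))`
#'   recovers the thresholds of `x`.
#' @examples
#' formatThresholds(thresholdConfig(75, "relative", 180))  # "x75/x180"
#' @export
formatThresholds <- function(config) {
  if (is(config, "ClassConfig"))
    return(sprintf("RNx%d/RN%d", config@rnOffset, config@brightCut))
  stopifnot(is(config, "ThresholdConfig"))
  sprintf("x%d/%s%d", config@rnOffset,
          if (config@outerMode == "relative") "x" else "",
          config@outerValue)
}

#' Compute the RN and outer thresholds for one object
#'
#' The RN threshold is the object's local maximum minus the configured
#' offset; the outer threshold is either the absolute configured level or,
#' in relative mode, the local maximum minus the outer offset. A threshold
#' that would fall below 1 is unmeasurable and returned as `NA` — for the
#' relative outer threshold this is the decay "fail" condition: once the
#' local maximum has dropped below `outerValue + 1` the outer edge can no
#' longer be measured.
#'
#' @param localMax integer in \[0, 255\]; the object's local maximum.
#' @param config a [ThresholdConfig-class].
#' @return Named numeric vector `c(rn =, outer =)`; `NA` marks an
#'   unmeasurable threshold.
#' @examples
#' computeThresholds(255, parseThresholds("x55/15"))    # rn 200, outer 15
#' computeThresholds(255, parseThresholds("x75/x180"))  # rn 180, outer 75
#' computeThresholds(150, parseThresholds("x75/x180"))  # outer NA: unmeasurable
#' @export
computeThresholds <- function(localMax, config) {
  stopifnot(is(config, "ThresholdConfig"),
            length(localMax) == 1L, localMax >= 0, localMax <= 255)
  localMax <- as.integer(localMax)
  rn <- localMax - config@rnOffset
  if (rn < 1L) rn <- NA_integer_
  outer <- if (config@outerMode == "absolute") {
    config@outerValue
  } else {
    o <- localMax - config@outerValue
    if (o < 1L) NA_integer_ else o
  }
  c(rn = as.integer(rn), outer = as.integer(outer))
}
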