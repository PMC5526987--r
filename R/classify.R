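# Halo stability classes from RN measurability and RN brightness.
#
# Class II: the RN cannot be segmented at the classifier's thresholds
# (ill-defined RN with poor structure). Class I halos have a defined RN and
# split by brightness: Ia when more than half of the RN pixels exceed the
# 220 brightness cut (strictly), Ib otherwise — a tie at exactly 50% is Ib,
# since Ia requires a strict majority.

#' Classify a single halo
#'
#' @param field the [IntensityField-class] the measurement came from.
#' @param measurement one row of [measurements()] from a result produced
#'   with the classifier's RN offset.
#' @param rnPixels linear pixel indices of the RN region (from
#'   [regions()]); may be empty/`NULL` only for `rn_fail` measurements.
#' @param config a [ClassConfig-class].
#' @return A list with `label` (`"Ia"`, `"Ib"` or `"II"`) and
#'   `brightFraction` (fraction of RN pixels strictly above the brightness
#'   cut; `NA` for class II).
#' @examples
#' # a bright RN: all pixels at 255 -> Ia with bright fraction 1
#' f <- intensityField(matrix(255L, 10, 10))
#' m <- data.frame(status = "measured")
#' classifyHalo(f, m, seq_len(100), classConfig())
#' @export
classifyHalo <- function(field, measurement, rnPixels, config = classConfig()) {
  stopifnot(is(field, "IntensityField"), is(config, "ClassConfig"))
  if (measurement$status == "rn_fail")
    return(list(label = "II", brightFraction = NA_real_))
  if (is.null(rnPixels) || !length(rnPixels))
    stop("measurement has a measurable RN but no RN pixels were supplied")
  v <- pixels(field)[rnPixels]
  f <- mean(v > config@brightCut)
  list(label = if (f > config@brightFractionCut) "Ia" else "Ib",
       brightFraction = f)
}

#' Classify every halo in a field
#'
#' Segments RN regions with the classifier's own RN offset (the "RN HIM"
#' variants are named `RNx55`, `RNx75`, implying independent segmentation)
#' and applies the brightness rule. An object whose RN cannot be segmented
#' is class II regardless of its outer region.
#'
#' @param field an [IntensityField-class].
#' @param config a [ClassConfig-class].
#' @param baseConfig a [ThresholdConfig-class] supplying the detection
#'   nuisance parameters (seed threshold, minimum area, border policy); its
#'   RN offset is overridden by the classifier's.
#' @return A [FieldResult-class] whose measurement table has the `class`
#'   column filled, plus a `bright_fraction` column.
#' @export
classifyField <- function(field, config = classConfig(),
                          baseConfig = thresholdConfig()) {
  stopifnot(is(config, "ClassConfig"), is(baseConfig, "ThresholdConfig"))
  cfg <- thresholdConfig(rnOffset = config@rnOffset,
                         outerMode = baseConfig@outerMode,
                         outerValue = baseConfig@outerValue,
                         seedThreshold = baseConfig@seedThreshold,
                         minObjectArea = baseConfig@minObjectArea,
                         borderPolicy = baseConfig@borderPolicy,
                         maximaMode = baseConfig@maximaMode)
  res <- measureField(field, cfg)
  m <- measurements(res)
  bf <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    cl <- classifyHalo(field, m[i, ], regions(res)[[i]]$rn, config)
    m$class[i] <- cl$label
    bf[i] <- cl$brightFraction
  }
  m$bright_fraction <- bf
  res@measurements <- m
  res
}

#' Class distribution of a halo population
#'
#' @param classes character vector of class labels (`"Ia"`, `"Ib"`, `"II"`).
#' @return Named numeric vector `c(Ia =, Ib =, II =)` of fractions summing
#'   to 1.
#' @examples
#' classDistribution(c("Ia", "Ia", "Ib", "II"))  # 0.50 0.25 0.25
#' @export
classDistribution <- function(classes) {
  if (!length(classes))
    stop("empty population: no classes to summarise", call. = FALSE)
  if (!all(classes %in% c("Ia", "Ib", "II")))
    stop("class labels must be 'Ia', 'Ib' or 'II'", call. = FALSE)
  tab <- table(factor(classes, levels = c("Ia", "Ib", "II")))
  stats::setNames(as.vector(tab) / length(classes), c("Ia", "Ib", "II"))
}
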