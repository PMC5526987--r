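#' @import methods
NULL

#' IntensityField: one 8-bit grayscale micrograph
#'
#' Container for a single-channel 8-bit intensity image — one MFHR micrograph
#' or one frame of a timed series. Pixel values are integers in \[0, 255\];
#' a frame time is carried only for stability (time-series) analysis.
#'
#' @slot pixels integer matrix (rows x cols) with values in \[0, 255\].
#' @slot sourceId character scalar identifying the image origin (file name,
#'   phantom id, ...).
#' @slot frameTime numeric scalar, seconds; `NA` for single-shot images.
#'
#' @seealso [intensityField()], [loadField()]
#' @exportClass IntensityField
setClass("IntensityField",
  representation(
    pixels = "matrix",
    sourceId = "character",
    frameTime = "numeric"
  ),
  prototype(sourceId = "", frameTime = NA_real_)
)

setValidity("IntensityField", function(object) {
  px <- object@pixels
  msg <- character()
  if (!is.numeric(px)) {
    msg <- c(msg, "pixels must be a numeric/integer matrix")
  } else {
    if (nrow(px) < 1L || ncol(px) < 1L)
      msg <- c(msg, "pixels must have at least one row and one column")
    if (anyNA(px))
      msg <- c(msg, "pixels must not contain NA")
    else if (min(px) < 0 || max(px) > 255)
      msg <- c(msg, "pixel values must lie in [0, 255]")
    else if (any(px != as.integer(px)))
      msg <- c(msg, "pixel values must be integers")
  }
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (length(object@frameTime) != 1L)
    msg <- c(msg, "frameTime must be a single number (or NA)")
  if (!is.na(object@frameTime) && object@frameTime < 0)
    msg <- c(msg, "frameTime must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityField
#'
#' @param pixels integer matrix of intensities in \[0, 255\].
#' @param sourceId identifier recorded in downstream tables.
#' @param frameTime acquisition time in seconds (`NA` for single images).
#' @return An [IntensityField-class] object.
#' @examples
#' f <- intensityField(matrix(0L, 10, 10), sourceId = "blank")
#' dim(pixels(f))
#' @export
intensityField <- function(pixels, sourceId = "", frameTime = NA_real_) {
  storage.mode(pixels) <- "integer"
  new("IntensityField", pixels = pixels, sourceId = as.character(sourceId),
      frameTime = as.numeric(frameTime))
}

#' ThresholdConfig: the "xA/B" threshold parameterisation
#'
#' Holds the two measurement thresholds — the RN threshold offset from the
#' per-object local maximum (the "x" in `x55`) and the outer-halo threshold,
#' either an absolute 8-bit level (e.g. `15`) or an offset from the local
#' maximum (e.g. `x180`) — together with detection nuisance parameters.
#'
#' @slot rnOffset integer in \[1, 254\]; RN threshold = local maximum - rnOffset.
#' @slot outerMode `"absolute"` or `"relative"`.
#' @slot outerValue integer in \[1, 254\]; absolute level or offset from the
#'   local maximum depending on `outerMode`.
#' @slot seedThreshold integer; coarse detection level for candidate objects.
#' @slot minObjectArea integer; candidate objects (and RN regions) smaller
#'   than this are rejected as debris / unmeasurable.
#' @slot borderPolicy `"exclude_touching"` (drop objects touching the frame
#'   border, whose areas would be truncated) or `"keep"`.
#' @slot maximaMode `"object"` (per-object local maxima, the default) or
#'   `"image"` (one maximum for the whole frame).
#'
#' @seealso [thresholdConfig()], [parseThresholds()]
#' @exportClass ThresholdConfig
setClass("ThresholdConfig",
  representation(
    rnOffset = "integer",
    outerMode = "character",
    outerValue = "integer",
    seedThreshold = "integer",
    minObjectArea = "integer",
    borderPolicy = "character",
    maximaMode = "character"
  )
)

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  chk1 <- function(v, nm, lo, hi) {
    if (length(v) != 1L || is.na(v) || v < lo || v > hi)
      sprintf("%s must be a single integer in [%d, %d]", nm, lo, hi)
    else character()
  }
  msg <- c(msg,
    chk1(object@rnOffset, "rnOffset", 1L, 254L),
    chk1(object@outerValue, "outerValue", 1L, 254L),
    chk1(object@seedThreshold, "seedThreshold", 1L, 254L))
  if (length(object@minObjectArea) != 1L || is.na(object@minObjectArea) ||
      object@minObjectArea < 0L)
    msg <- c(msg, "minObjectArea must be a single non-negative integer")
  if (!object@outerMode %in% c("absolute", "relative"))
    msg <- c(msg, "outerMode must be 'absolute' or 'relative'")
  if (!object@borderPolicy %in% c("exclude_touching", "keep"))
    msg <- c(msg, "borderPolicy must be 'exclude_touching' or 'keep'")
  if (!object@maximaMode %in% c("object", "image"))
    msg <- c(msg, "maximaMode must be 'object' or 'image'")
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdConfig
#'
#' Defaults reproduce the `x55/15` setting: RN threshold 55 below the local
#' maximum and an absolute outer threshold of 15, which confidently includes
#' the outermost DNA-loop edge across a population.
#'
#' @param rnOffset RN threshold offset below the local maximum (default 55).
#' @param outerMode `"absolute"` or `"relative"` outer threshold.
#' @param outerValue outer threshold level (absolute) or offset (relative).
#' @param seedThreshold detection level for candidate objects (default 15).
#' @param minObjectArea minimum object/RN area in pixels (default 500,
#'   a debris filter for full-size 1388x1040 frames; reduce for small
#'   synthetic frames).
#' @param borderPolicy drop (`"exclude_touching"`, default) or keep objects
#'   touching the image border.
#' @param maximaMode `"object"` (default) or `"image"` maxima.
#' @return A [ThresholdConfig-class] object.
#' @examples
#' thresholdConfig(75, "relative", 180)   # the x75/x180 setting
#' @export
thresholdConfig <- function(rnOffset = 55, outerMode = c("absolute", "relative"),
                            outerValue = 15, seedThreshold = 15,
                            minObjectArea = 500,
                            borderPolicy = c("exclude_touching", "keep"),
                            maximaMode = c("object", "image")) {
  new("ThresholdConfig",
      rnOffset = as.integer(rnOffset),
      outerMode = match.arg(outerMode),
      outerValue = as.integer(outerValue),
      seedThreshold = as.integer(seedThreshold),
      minObjectArea = as.integer(minObjectArea),
      borderPolicy = match.arg(borderPolicy),
      maximaMode = match.arg(maximaMode))
}

#' ClassConfig: halo classification thresholds
#'
#' Parameters of the classification variant ("RN HIM"): an RN segmentation
#' offset of its own plus a brightness rule. A halo whose RN cannot be
#' segmented is class II; otherwise it is class Ia (bright) when more than
#' `brightFractionCut` of its RN pixels exceed `brightCut`, else Ib (pale).
#' The defaults reproduce the `RNx55/RN220` setting; set `rnOffset = 75` for
#' `RNx75/RN220`.
#'
#' @slot brightCut integer in \[0, 255\]; RN pixels strictly above this count
#'   as bright (default 220).
#' @slot brightFractionCut numeric in (0, 1); strict lower bound on the bright
#'   fraction for class Ia (default 0.5; a tie at exactly 0.5 is Ib).
#' @slot rnOffset integer; the classifier's own RN offset.
#'
#' @seealso [classConfig()], [classifyField()]
#' @exportClass ClassConfig
setClass("ClassConfig",
  representation(
    brightCut = "integer",
    brightFractionCut = "numeric",
    rnOffset = "integer"
  )
)

setValidity("ClassConfig", function(object) {
  msg <- character()
  if (length(object@brightCut) != 1L || object@brightCut < 0L ||
      object@brightCut > 255L)
    msg <- c(msg, "brightCut must be a single integer in [0, 255]")
  if (length(object@brightFractionCut) != 1L ||
      object@brightFractionCut <= 0 || object@brightFractionCut >= 1)
    msg <- c(msg, "brightFractionCut must lie in (0, 1)")
  if (length(object@rnOffset) != 1L || object@rnOffset < 1L ||
      object@rnOffset > 254L)
    msg <- c(msg, "rnOffset must be a single integer in [1, 254]")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassConfig
#'
#' @param brightCut RN brightness level (default 220).
#' @param brightFractionCut bright-pixel fraction above which a measurable RN
#'   is class Ia (default 0.5).
#' @param rnOffset the classifier's RN segmentation offset (default 55,
#'   i.e. `RNx55/RN220`; use 75 for `RNx75/RN220`).
#' @return A [ClassConfig-class] object.
#' @examples
#' classConfig(rnOffset = 75)   # RNx75/RN220
#' @export
classConfig <- function(brightCut = 220, brightFractionCut = 0.5,
                        rnOffset = 55) {
  new("ClassConfig", brightCut = as.integer(brightCut),
      brightFractionCut = as.numeric(brightFractionCut),
      rnOffset = as.integer(rnOffset))
}

#' FieldResult: linked halo measurements for one field
#'
#' The result of [measureField()] on one [IntensityField-class]: one row per
#' detected object with its local maximum, thresholds, linked RN/outer areas,
#' equal-area-circle radii and a measurement status, plus the segmented pixel
#' sets needed for overlays and classification.
#'
#' @slot sourceId character; identifier of the measured field.
#' @slot frameTime numeric; frame time of the field (NA for single images).
#' @slot fieldDim integer vector (rows, cols) of the measured field.
#' @slot config the [ThresholdConfig-class] used.
#' @slot measurements data.frame, one row per object: `object_index`,
#'   `local_max`, `rn_threshold`, `outer_threshold`, `rn_area_px`,
#'   `outer_area_px`, `rn_radius_px`, `outer_radius_px`, `halo_radius_px`,
#'   `status` (`measured`, `rn_fail` or `outer_fail`), `class` (NA until
#'   classified).
#' @slot regions list, one element per object: linear pixel indices of the
#'   object support, RN region and outer region, plus centroid and seed pixel.
#'
#' @seealso [measureField()], [writeMeasurementsCSV()]
#' @exportClass FieldResult
setClass("FieldResult",
  representation(
    sourceId = "character",
    frameTime = "numeric",
    fieldDim = "integer",
    config = "ThresholdConfig",
    measurements = "data.frame",
    regions = "list"
  )
)

setValidity("FieldResult", function(object) {
  msg <- character()
  m <- object@measurements
  need <- c("object_index", "local_max", "rn_threshold", "outer_threshold",
            "rn_area_px", "outer_area_px", "rn_radius_px", "outer_radius_px",
            "halo_radius_px", "status", "class")
  if (!all(need %in% names(m)))
    msg <- c(msg, "measurements is missing required columns")
  else {
    if (anyDuplicated(m$object_index))
      msg <- c(msg, "object_index values must be unique")
    if (nrow(m) && !all(m$status %in% c("measured", "rn_fail", "outer_fail")))
      msg <- c(msg, "invalid status value")
  }
  if (length(object@regions) != nrow(m))
    msg <- c(msg, "regions must have one element per measurement row")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: analytic halo phantom parameters
#'
#' Parameters of one synthetic halo phantom: a bright near-circular core (the
#' residual nucleus) of radius `rnRadius` at `peak` intensity, surrounded by
#' a radially decaying diffuse halo
#' \deqn{I(r) = b + (p - b)\,e^{-((r - r_{RN})/s)^2}, \quad r > r_{RN},}
#' on background \eqn{b}. The Gaussian tail gives a closed-form radius at
#' which the profile crosses any threshold (see [crossingRadius()]), which is
#' what makes rendered phantoms an analytic ground truth for the measurement
#' pipeline.
#'
#' @slot center numeric length-2 (row, col) centre in pixel coordinates.
#' @slot rnRadius positive numeric; core (RN) radius in pixels.
#' @slot peak integer in \[1, 255\]; peak intensity.
#' @slot plateau logical; `TRUE` (default) renders a flat core at `peak`,
#'   `FALSE` a pure Gaussian peak (equivalent to `rnRadius` = 0 in the
#'   crossing formula).
#' @slot haloScale positive numeric; decay length `s` of the halo tail.
#' @slot background integer in \[0, 255\].
#' @slot noiseSd non-negative numeric; additive Gaussian noise SD.
#' @slot classIntent `"Ia"`, `"Ib"`, `"II"` or `NA`; the class the phantom is
#'   built to exhibit (recorded in ground truth, not used for rendering).
#'
#' @seealso [phantomSpec()], [renderField()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    center = "numeric",
    rnRadius = "numeric",
    peak = "integer",
    plateau = "logical",
    haloScale = "numeric",
    background = "integer",
    noiseSd = "numeric",
    classIntent = "character"
  ),
  prototype(plateau = TRUE, background = 5L, noiseSd = 0,
            classIntent = NA_character_)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2L || anyNA(object@center))
    msg <- c(msg, "center must be a (row, col) pair")
  if (length(object@rnRadius) != 1L || object@rnRadius <= 0)
    msg <- c(msg, "rnRadius must be a single positive number")
  if (length(object@peak) != 1L || object@peak < 1L || object@peak > 255L)
    msg <- c(msg, "peak must be in [1, 255]")
  if (length(object@background) != 1L || object@background < 0L ||
      object@background > 255L)
    msg <- c(msg, "background must be in [0, 255]")
  if (!is.na(object@peak) && !is.na(object@background) &&
      object@peak <= object@background)
    msg <- c(msg, "peak must exceed background")
  if (length(object@haloScale) != 1L || object@haloScale <= 0)
    msg <- c(msg, "haloScale must be a single positive number")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (!is.na(object@classIntent) &&
      !object@classIntent %in% c("Ia", "Ib", "II"))
    msg <- c(msg, "classIntent must be Ia, Ib, II or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param center (row, col) centre in pixels.
#' @param rnRadius core (RN) radius in pixels.
#' @param peak peak intensity in \[1, 255\].
#' @param haloScale Gaussian decay length of the halo tail, pixels.
#' @param background background intensity (default 5).
#' @param plateau flat core at `peak` (default) or pure Gaussian peak.
#' @param noiseSd additive Gaussian noise SD (default 0, noise free).
#' @param classIntent intended class label recorded in ground truth.
#' @return A [PhantomSpec-class] object.
#' @examples
#' phantomSpec(c(100, 100), rnRadius = 20, peak = 255, haloScale = 30)
#' @export
phantomSpec <- function(center, rnRadius, peak, haloScale, background = 5,
                        plateau = TRUE, noiseSd = 0,
                        classIntent = NA_character_) {
  new("PhantomSpec", center = as.numeric(center),
      rnRadius = as.numeric(rnRadius), peak = as.integer(peak),
      plateau = as.logical(plateau), haloScale = as.numeric(haloScale),
      background = as.integer(background), noiseSd = as.numeric(noiseSd),
      classIntent = as.character(classIntent))
}

#' CellTimeSeries: timed frames of one cell
#'
#' An ordered series of frames of a single cell used for halo-stability
#' analysis; typically 7 frames at 0, 10, ..., 60 s.
#'
#' @slot cellId character identifier.
#' @slot frames list of [IntensityField-class] objects with strictly
#'   increasing `frameTime` and identical dimensions.
#'
#' @seealso [cellTimeSeries()], [decayRecord()]
#' @exportClass CellTimeSeries
setClass("CellTimeSeries",
  representation(cellId = "character", frames = "list")
)

setValidity("CellTimeSeries", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L)
    msg <- c(msg, "cellId must be a single string")
  if (length(object@frames) < 1L)
    msg <- c(msg, "at least one frame is required")
  else {
    ok <- vapply(object@frames, is, logical(1), class2 = "IntensityField")
    if (!all(ok)) {
      msg <- c(msg, "frames must all be IntensityField objects")
    } else {
      tt <- vapply(object@frames, frameTime, numeric(1))
      if (anyNA(tt) || any(diff(tt) <= 0))
        msg <- c(msg, "frame times must be present and strictly increasing")
      dd <- vapply(object@frames, function(f) dim(pixels(f)), integer(2))
      if (any(dd[1, ] != dd[1, 1]) || any(dd[2, ] != dd[2, 1]))
        msg <- c(msg, "all frames must share dimensions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellTimeSeries
#'
#' @param frames list of [IntensityField-class] frames with strictly
#'   increasing frame times.
#' @param cellId identifier for the tracked cell.
#' @return A [CellTimeSeries-class] object.
#' @export
cellTimeSeries <- function(frames, cellId = "cell") {
  new("CellTimeSeries", cellId = as.character(cellId), frames = frames)
}
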