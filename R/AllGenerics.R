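#' Accessors for haloquant classes
#'
#' `pixels()`, `sourceId()` and `frameTime()` access the slots of an
#' [IntensityField-class]; `measurements()` and `regions()` access a
#' [FieldResult-class]; `frames()` and `cellId()` a [CellTimeSeries-class].
#'
#' @param x the object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setMethod("pixels", "IntensityField", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("sourceId", "IntensityField", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("frameTime", "IntensityField", function(x) x@frameTime)

#' @rdname accessors
#' @export
setMethod("sourceId", "FieldResult", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("frameTime", "FieldResult", function(x) x@frameTime)

#' @rdname accessors
#' @export
setMethod("measurements", "FieldResult", function(x) x@measurements)

#' @rdname accessors
#' @export
setMethod("regions", "FieldResult", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("frames", "CellTimeSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("cellId", "CellTimeSeries", function(x) x@cellId)

#' @describeIn accessors image dimensions (rows, cols).
#' @export
setMethod("dim", "IntensityField", function(x) dim(x@pixels))

setMethod("show", "IntensityField", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IntensityField '%s': %d x %d px, range [%d, %d]%s\n",
              object@sourceId, d[1], d[2],
              min(object@pixels), max(object@pixels),
              if (is.na(object@frameTime)) ""
              else sprintf(", t = %g s", object@frameTime)))
})

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf(
    "ThresholdConfig %s (seed %d, minArea %d, border %s, maxima per %s)\n",
    formatThresholds(object), object@seedThreshold, object@minObjectArea,
    object@borderPolicy, object@maximaMode))
})

setMethod("show", "ClassConfig", function(object) {
  cat(sprintf("ClassConfig RNx%d/RN%d (Ia when bright fraction > %g)\n",
              object@rnOffset, object@brightCut, object@brightFractionCut))
})

setMethod("show", "FieldResult", function(object) {
  m <- object@measurements
  cat(sprintf("FieldResult '%s' (%s): %d object(s); %d measured, %d rn_fail, %d outer_fail\n",
              object@sourceId, formatThresholds(object@config), nrow(m),
              sum(m$status == "measured"), sum(m$status == "rn_fail"),
              sum(m$status == "outer_fail")))
  if (nrow(m)) print(utils::head(m, 8))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec at (%g, %g): rn %g px, peak %d on bg %d, halo scale %g px%s\n",
    object@center[1], object@center[2], object@rnRadius, object@peak,
    object@background, object@haloScale,
    if (is.na(object@classIntent)) "" else paste0(" [", object@classIntent, "]")))
})

setMethod("show", "CellTimeSeries", function(object) {
  tt <- vapply(object@frames, frameTime, numeric(1))
  cat(sprintf("CellTimeSeries '%s': %d frames at t = %s s\n", object@cellId,
              length(object@frames), paste(tt, collapse = ", ")))
})
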