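# Reading micrographs into IntensityFields; writing overlays, fields and
# measurement tables.

pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(NA_integer_)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

collapseChannels <- function(arr, channelPolicy) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch == 2L) return(arr[, , 1L])              # gray + alpha
  r <- arr[, , 1L]; g <- arr[, , 2L]; b <- arr[, , 3L]
  switch(channelPolicy,
    max = pmax(r, g, b),
    red = r, green = g, blue = b,
    luminance = round(0.299 * r + 0.587 * g + 0.114 * b),
    stop("unknown channel policy: ", channelPolicy))
}

#' Load a micrograph as an IntensityField
#'
#' Reads an 8-bit grayscale or RGB TIFF (or PNG) and collapses RGB input to
#' one 8-bit channel under the chosen policy. All measurement thresholds are
#' defined on the 0-255 scale, so deeper bit depths are rejected outright
#' rather than silently rescaled.
#'
#' @param path file path to a TIFF or PNG image.
#' @param channelPolicy how to collapse RGB to one channel: `"max"`
#'   (default; robust to which channel carries the fluorescence signal),
#'   `"red"`, `"green"`, `"blue"`, or `"luminance"` (Rec. 601 weights).
#' @param frameTime optional acquisition time in seconds for time-series
#'   frames.
#' @return An [IntensityField-class]; `sourceId` is the file name.
#' @export
loadField <- function(path, channelPolicy = c("max", "red", "green", "blue",
                                              "luminance"),
                      frameTime = NA_real_) {
  channelPolicy <- match.arg(channelPolicy)
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e)
                      stop("cannot read image file: ", path, " (",
                           conditionMessage(e), ")", call. = FALSE))
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && bps > 8L)
      stop("unsupported format: ", path,
           " has bit depth > 8; thresholds are defined on the 0-255 scale",
           call. = FALSE)
    if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
      arr <- arr[, , 1:3]                          # drop alpha
    arr <- round(arr * 255)
  } else if (ext == "png") {
    if (isTRUE(pngBitDepth(path) > 8L))
      stop("unsupported format: ", path,
           " has bit depth > 8; thresholds are defined on the 0-255 scale",
           call. = FALSE)
    arr <- tryCatch(png::readPNG(path),
                    error = function(e)
                      stop("cannot read image file: ", path, " (",
                           conditionMessage(e), ")", call. = FALSE))
    if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
      arr <- arr[, , 1:3]                          # drop alpha
    arr <- round(arr * 255)
  } else {
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  }
  px <- collapseChannels(arr, channelPolicy)
  px <- matrix(as.integer(px), nrow(px), ncol(px))
  intensityField(px, sourceId = basename(path), frameTime = frameTime)
}

#' Write an IntensityField as an 8-bit grayscale TIFF
#'
#' Round-trips pixel-exactly with [loadField()].
#'
#' @param field an [IntensityField-class].
#' @param path output path (`.tif`/`.tiff`).
#' @return Invisibly, `path`.
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "IntensityField"))
  ok <- tryCatch({
    tiff::writeTIFF(pixels(field) / 255, path, bits.per.sample = 8L)
    TRUE
  }, error = function(e) FALSE, warning = function(w) TRUE)
  if (!ok || !file.exists(path))
    stop("cannot write image file: ", path, call. = FALSE)
  invisible(path)
}

# boundary pixels of a region: members with an 8-neighbour outside the region
regionBoundary <- function(pix, nr, nc) {
  if (!length(pix)) return(integer(0))
  inReg <- logical(nr * nc)
  inReg[pix] <- TRUE
  rows <- (pix - 1L) %% nr + 1L
  cols <- (pix - 1L) %/% nr + 1L
  isBoundary <- rows == 1L | rows == nr | cols == 1L | cols == nc
  inner <- !isBoundary
  if (any(inner)) {
    p <- pix[inner]
    nbh <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
    edge <- rep(FALSE, length(p))
    for (d in nbh) edge <- edge | !inReg[p + d]
    isBoundary[inner] <- edge
  }
  pix[isBoundary]
}

#' Write RN and outer threshold analysis pictures
#'
#' Writes two RGB PNG overlays of the measured field — one with the RN
#' boundaries, one with the outer boundaries — with boundary pixels drawn in
#' saturated red (RN) or green (outer) over the grayscale image. These are
#' the per-image "threshold analysis pictures" used to audit threshold
#' placement by eye.
#'
#' @param field the measured [IntensityField-class].
#' @param result the [FieldResult-class] produced from `field`.
#' @param path output stem; `<stem>_rn.png` and `<stem>_outer.png` are
#'   written (a trailing `.png` on `path` is stripped).
#' @return Invisibly, the two paths written.
#' @export
writeOverlay <- function(field, result, path) {
  stopifnot(is(field, "IntensityField"), is(result, "FieldResult"))
  px <- pixels(field)
  if (!identical(dim(px), result@fieldDim))
    stop("result was not produced from this field (dimension mismatch)")
  stem <- sub("\\.png$", "", path, ignore.case = TRUE)
  paths <- c(rn = paste0(stem, "_rn.png"), outer = paste0(stem, "_outer.png"))
  gray <- px / 255
  for (what in c("rn", "outer")) {
    img <- array(gray, c(nrow(px), ncol(px), 3L))
    bnd <- unlist(lapply(regions(result), function(rg)
      regionBoundary(rg[[what]], nrow(px), ncol(px))))
    if (length(bnd)) {
      npix <- length(px)
      chan <- if (what == "rn") 1L else 2L
      for (k in 1:3) {
        v <- if (k == chan) 1 else 0
        img[bnd + (k - 1L) * npix] <- v
      }
    }
    ok <- tryCatch({ png::writePNG(img, paths[[what]]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write overlay: ", paths[[what]], call. = FALSE)
  }
  invisible(paths)
}

measurementColumns <- c("source_id", "object_index", "frame_time_s",
                        "local_max", "rn_area_px", "outer_area_px",
                        "rn_radius_px", "outer_radius_px", "halo_radius_px",
                        "status", "class")

#' Collect measurements from field results into one table
#'
#' @param results a [FieldResult-class] or list of them.
#' @return A data.frame with one row per detected object and the columns
#'   written by [writeMeasurementsCSV()].
#' @export
measurementTable <- function(results) {
  if (is(results, "FieldResult")) results <- list(results)
  stopifnot(all(vapply(results, is, logical(1), class2 = "FieldResult")))
  rows <- lapply(results, function(r) {
    m <- measurements(r)
    if (!nrow(m)) return(NULL)
    data.frame(source_id = sourceId(r), object_index = m$object_index,
               frame_time_s = frameTime(r), local_max = m$local_max,
               rn_area_px = m$rn_area_px, outer_area_px = m$outer_area_px,
               rn_radius_px = m$rn_radius_px,
               outer_radius_px = m$outer_radius_px,
               halo_radius_px = m$halo_radius_px,
               status = m$status, class = m$class)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(measurementColumns), logical(0), simplify = FALSE),
      measurementColumns))
    return(out)
  }
  do.call(rbind, rows)
}

#' Write the measurement CSV
#'
#' One row per detected object across all submitted fields, comma-separated
#' with a fixed header; numeric cells of failed measurements are left empty
#' and the `status` column records the failure mode.
#'
#' @param results a [FieldResult-class] or list of them.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeMeasurementsCSV <- function(results, path) {
  tab <- measurementTable(results)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = ",", dec = ".", na = "", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write CSV: ", path, call. = FALSE)
  invisible(path)
}
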