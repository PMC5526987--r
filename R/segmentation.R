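# Connected-component labelling, candidate detection and the linked
# RN/outer measurement that is the heart of the halo pipeline.

# 8-connected labelling of a logical mask. EBImage::bwlabel is 4-connected;
# diagonally adjacent labels are merged afterwards with a union-find pass,
# which is cheap because only label pairs (not pixels) are unioned.
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nr, nc)
  nlab <- max(lab)
  if (nlab > 1L && nr > 1L && nc > 1L) {
    parent <- seq_len(nlab)
    findRoot <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # / diagonal
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (k in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), findRoot, integer(1))
      newid <- match(root, sort(unique(root)))
      pos <- lab > 0L
      lab[pos] <- newid[lab[pos]]
    }
  }
  lab
}

# topmost-then-leftmost pixel among linear indices attaining the maximum
maxSeedPixel <- function(px, idx) {
  nr <- nrow(px)
  v <- px[idx]
  cand <- idx[v == max(v)]
  rows <- (cand - 1L) %% nr + 1L
  cols <- (cand - 1L) %/% nr + 1L
  top <- rows == min(rows)
  c(min(rows), min(cols[top]))
}

#' Detect candidate halo objects in a field
#'
#' Candidate objects are the 8-connected components of pixels at or above the
#' configured seed threshold, filtered by minimum area and (optionally) by
#' contact with the image border, whose truncated areas would bias radii.
#' Each object carries its pixel set, centroid, local maximum and the seed
#' pixel (topmost-then-leftmost maximum pixel) anchoring its thresholds.
#'
#' @param field an [IntensityField-class].
#' @param config a [ThresholdConfig-class]; `seedThreshold`, `minObjectArea`,
#'   `borderPolicy` and `maximaMode` are used here.
#' @return A list with one element per object, ordered by topmost pixel then
#'   leftmost column; each element is a list with `index`, `pixels` (linear
#'   indices into the pixel matrix), `area`, `centroid` (row, col),
#'   `localMax` and `seed` (row, col of the maximum pixel). An empty list if
#'   nothing is detected.
#' @examples
#' f <- intensityField(matrix(5L, 20, 20))
#' detectObjects(f, thresholdConfig(minObjectArea = 1))  # empty: all below 15
#' @export
detectObjects <- function(field, config = thresholdConfig()) {
  stopifnot(is(field, "IntensityField"), is(config, "ThresholdConfig"))
  px <- pixels(field)
  nr <- nrow(px); nc <- ncol(px)
  lab <- labelComponents(px >= config@seedThreshold)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  keep <- rep(TRUE, nlab)
  if (config@borderPolicy == "exclude_touching") {
    onBorder <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keep[onBorder[onBorder > 0L]] <- FALSE
  }
  idx <- which(lab > 0L)
  bylab <- split(idx, lab[idx])
  globalMax <- max(px)
  objs <- list()
  for (id in seq_len(nlab)) {
    if (!keep[id]) next
    pix <- bylab[[as.character(id)]]
    if (length(pix) < config@minObjectArea) next
    rows <- (pix - 1L) %% nr + 1L
    cols <- (pix - 1L) %/% nr + 1L
    lm <- if (config@maximaMode == "image") globalMax else max(px[pix])
    objs[[length(objs) + 1L]] <- list(
      pixels = pix, area = length(pix),
      centroid = c(mean(rows), mean(cols)),
      localMax = as.integer(lm),
      seed = maxSeedPixel(px, pix),
      topLeft = c(min(rows), min(cols[rows == min(rows)])))
  }
  if (!length(objs)) return(list())
  ord <- order(vapply(objs, function(o) o$topLeft[1], numeric(1)),
               vapply(objs, function(o) o$topLeft[2], numeric(1)))
  objs <- objs[ord]
  for (i in seq_along(objs)) {
    objs[[i]]$index <- i
    objs[[i]]$topLeft <- NULL
  }
  objs
}

#' Segment the thresholded region containing an object's maximum
#'
#' Returns the 8-connected component of pixels at or above `threshold` that
#' contains the object's seed pixel (its topmost-then-leftmost maximum).
#' If the seed itself is below the threshold no pixel of the object reaches
#' it and the empty region is returned.
#'
#' @param field an [IntensityField-class].
#' @param object one element of the list returned by [detectObjects()] (any
#'   list with a `seed` (row, col) entry works).
#' @param threshold integer in \[1, 255\].
#' @return A list with `pixels` (linear indices) and `area` (pixel count).
#' @export
segmentRegion <- function(field, object, threshold) {
  stopifnot(is(field, "IntensityField"),
            length(threshold) == 1L, threshold >= 1, threshold <= 255)
  px <- pixels(field)
  seed <- object$seed
  if (px[seed[1], seed[2]] < threshold)
    return(list(pixels = integer(0), area = 0L))
  lab <- labelComponents(px >= threshold)
  pix <- which(lab == lab[seed[1], seed[2]])
  list(pixels = pix, area = length(pix))
}

#' Equal-area-circle radius
#'
#' Converts a pixel area to the radius of the circle of equal area,
#' \eqn{r = \sqrt{A/\pi}} — the convention used throughout for RN and outer
#' radii, consistent with polygon-area visual estimates.
#'
#' @param areaPx non-negative area(s) in pixels.
#' @return Radius (radii) in pixels.
#' @examples
#' areaToRadius(314)  # ~ 10
#' @export
areaToRadius <- function(areaPx) {
  stopifnot(all(areaPx >= 0))
  sqrt(areaPx / pi)
}

#' Measure all halos in a field
#'
#' For every detected object, computes its RN and outer thresholds from its
#' local maximum ([computeThresholds()]), segments the RN region at the RN
#' threshold and the outer region at the outer threshold, links the two by
#' position (the outer component is the one containing the RN seed pixel),
#' and derives equal-area radii and the halo radius (outer minus RN). A
#' per-object `status` records failure modes instead of raising: `rn_fail`
#' when the RN threshold is unreachable or the RN region is smaller than
#' `minObjectArea`; `outer_fail` when the outer threshold is unreachable
#' (the decay "fail" condition in relative mode) or the outer region is
#' empty.
#'
#' @param field an [IntensityField-class].
#' @param config a [ThresholdConfig-class].
#' @return A [FieldResult-class].
#' @examples
#' sp <- phantomSpec(c(64, 64), rnRadius = 12, peak = 255, haloScale = 15,
#'                   background = 5)
#' f <- renderField(list(sp), 127, 127, seed = 1)$field
#' res <- measureField(f, thresholdConfig(minObjectArea = 50))
#' measurements(res)
#' @export
measureField <- function(field, config = thresholdConfig()) {
  stopifnot(is(field, "IntensityField"), is(config, "ThresholdConfig"))
  px <- pixels(field)
  objs <- detectObjects(field, config)

  labCache <- new.env(parent = emptyenv())
  labAt <- function(t) {
    k <- as.character(t)
    if (is.null(labCache[[k]])) labCache[[k]] <- labelComponents(px >= t)
    labCache[[k]]
  }
  compAt <- function(t, seed) {
    if (px[seed[1], seed[2]] < t) return(integer(0))
    lab <- labAt(t)
    which(lab == lab[seed[1], seed[2]])
  }

  n <- length(objs)
  m <- data.frame(
    object_index = integer(n), local_max = integer(n),
    rn_threshold = integer(n), outer_threshold = integer(n),
    rn_area_px = integer(n), outer_area_px = integer(n),
    rn_radius_px = numeric(n), outer_radius_px = numeric(n),
    halo_radius_px = numeric(n),
    status = character(n), class = rep(NA_character_, n))
  regs <- vector("list", n)
  nestWarned <- FALSE

  for (i in seq_len(n)) {
    o <- objs[[i]]
    th <- computeThresholds(o$localMax, config)
    rnPix <- integer(0); outPix <- integer(0)
    rnOK <- FALSE; outOK <- FALSE
    if (!is.na(th["rn"])) {
      rnPix <- compAt(th["rn"], o$seed)
      rnOK <- length(rnPix) >= config@minObjectArea
    }
    if (!is.na(th["outer"])) {
      outPix <- compAt(th["outer"], o$seed)
      outOK <- length(outPix) > 0L
    }
    if (!is.na(th["rn"]) && !is.na(th["outer"]) &&
        th["rn"] < th["outer"] && !nestWarned) {
      warning(sprintf(
        "RN threshold (%d) below outer threshold (%d): RN/outer nesting does not hold for this config",
        th["rn"], th["outer"]), call. = FALSE)
      nestWarned <- TRUE
    }
    status <- if (!rnOK) "rn_fail" else if (!outOK) "outer_fail" else "measured"
    measured <- status == "measured"
    m$object_index[i] <- o$index
    m$local_max[i] <- o$localMax
    m$rn_threshold[i] <- th["rn"]
    m$outer_threshold[i] <- th["outer"]
    m$rn_area_px[i] <- if (rnOK) length(rnPix) else NA_integer_
    m$outer_area_px[i] <- if (outOK) length(outPix) else NA_integer_
    m$rn_radius_px[i] <- if (rnOK) areaToRadius(length(rnPix)) else NA_real_
    m$outer_radius_px[i] <- if (outOK) areaToRadius(length(outPix)) else NA_real_
    m$halo_radius_px[i] <- if (measured)
      m$outer_radius_px[i] - m$rn_radius_px[i] else NA_real_
    m$status[i] <- status
    regs[[i]] <- list(object = o$pixels,
                      rn = if (rnOK) rnPix else integer(0),
                      outer = if (outOK) outPix else integer(0),
                      centroid = o$centroid, seed = o$seed,
                      localMax = o$localMax)
  }

  new("FieldResult", sourceId = sourceId(field), frameTime = frameTime(field),
      fieldDim = dim(px), config = config, measurements = m, regions = regs)
}
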