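#' Construct an ROI specification
#'
#' @param widthUm,heightUm physical extent in micrometres.
#' @param pixelScale pixels per micrometre (default 9.6679).
#' @return a \code{\linkS4class{RoiSpec}}.
#' @examples
#' roi <- roiSpec(52, 52)
#' gridDim(roi)
#' @export
roiSpec <- function(widthUm, heightUm = widthUm, pixelScale = 9.6679) {
    new("RoiSpec", widthUm = as.numeric(widthUm),
        heightUm = as.numeric(heightUm), pixelScale = as.numeric(pixelScale))
}

#' Pixel grid dimensions of an ROI
#'
#' Rows correspond to y (downward), columns to x (rightward):
#' \code{c(round(heightUm * pixelScale), round(widthUm * pixelScale))}.
#'
#' @param x a \code{\linkS4class{RoiSpec}} or an object carrying one.
#' @return integer vector \code{c(nrow, ncol)}.
#' @rdname gridDim
#' @export
setMethod("gridDim", "RoiSpec", function(x) {
    c(as.integer(round(x@heightUm * x@pixelScale)),
      as.integer(round(x@widthUm * x@pixelScale)))
})

#' @rdname gridDim
#' @export
setMethod("gridDim", "BinaryMask", function(x) dim(x@grid))

## um <-> 0-based pixel index conversions. A pixel (row, col) covers
## [col/s,(col+1)/s) x [row/s,(row+1)/s); its centre is ((col+.5)/s,(row+.5)/s).
.umToPix <- function(u, scale) as.integer(floor(u * scale))
.pixCenterUm <- function(i, scale) (i + 0.5) / scale

setMethod("show", "RoiSpec", function(object) {
    d <- gridDim(object)
    cat(sprintf("RoiSpec: %.6g x %.6g um at %.6g px/um (%d x %d px grid)\n",
                object@widthUm, object@heightUm, object@pixelScale,
                d[1], d[2]))
})

#' Construct a PunctaSet
#'
#' @param channel channel label.
#' @param roi a \code{\linkS4class{RoiSpec}}.
#' @param puncta data.frame with columns \code{id}, \code{x_um}, \code{y_um},
#'   \code{area_um2}, \code{feret_um}, \code{total_intensity},
#'   \code{mean_intensity}.  Missing intensity columns default to NA.
#' @param pixels optional list of integer matrices (columns \code{row},
#'   \code{col}; 0-based), one per punctum.
#' @param provenance free-text origin string.
#' @return a \code{\linkS4class{PunctaSet}}.
#' @export
punctaSet <- function(channel, roi, puncta, pixels = list(),
                      provenance = "constructed") {
    puncta <- as.data.frame(puncta)
    for (cc in .punctaCols)
        if (!cc %in% names(puncta)) puncta[[cc]] <- NA_real_
    puncta <- puncta[.punctaCols]
    rownames(puncta) <- NULL
    new("PunctaSet", channel = channel, roi = roi, puncta = puncta,
        pixels = pixels, provenance = provenance)
}

#' Accessors for PunctaSet
#'
#' @param x a \code{\linkS4class{PunctaSet}}.
#' @name punctaAccessors
#' @rdname punctaAccessors
NULL

#' @rdname punctaAccessors
#' @export
setMethod("nPuncta", "PunctaSet", function(x) nrow(x@puncta))

#' @rdname punctaAccessors
#' @export
setMethod("punctaTable", "PunctaSet", function(x) x@puncta)

#' @rdname punctaAccessors
#' @export
setMethod("channelName", "PunctaSet", function(x) x@channel)

#' @rdname punctaAccessors
#' @export
setMethod("roiOf", "PunctaSet", function(x) x@roi)

#' @rdname punctaAccessors
#' @export
setMethod("roiOf", "BinaryMask", function(x) x@roi)

#' @rdname punctaAccessors
#' @export
setMethod("pixelSets", "PunctaSet", function(x) x@pixels)

setMethod("show", "PunctaSet", function(object) {
    cat(sprintf("PunctaSet '%s': %d puncta in %.6g x %.6g um ROI%s\n",
                object@channel, nrow(object@puncta),
                object@roi@widthUm, object@roi@heightUm,
                if (length(object@pixels)) " (pixel-backed)" else ""))
    if (nrow(object@puncta) > 0)
        cat(sprintf("  median area %.3g um2, median Feret %.3g um\n",
                    stats::median(object@puncta$area_um2),
                    stats::median(object@puncta$feret_um)))
    cat("  provenance:", object@provenance, "\n")
})

#' Subset a PunctaSet by row index or punctum id
#'
#' @param x a \code{\linkS4class{PunctaSet}}.
#' @param i integer row indices or logical vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PunctaSet", function(x, i, j, ..., drop = FALSE) {
    idx <- seq_len(nrow(x@puncta))[i]
    px <- if (length(x@pixels)) x@pixels[idx] else list()
    punctaSet(x@channel, x@roi, x@puncta[idx, , drop = FALSE], px,
              x@provenance)
})

#' Pixel footprint of a disc
#'
#' Returns the 0-based grid pixels whose centres lie within
#' \code{diameter / 2} of the centroid, clipped to the ROI.  At least one
#' pixel (the one containing or nearest the centroid) is always returned, so
#' sub-pixel puncta keep a footprint.
#'
#' @param centroidXy numeric length-2, centroid (x, y) in micrometres.
#' @param diameter disc diameter in micrometres (> 0).
#' @param roi a \code{\linkS4class{RoiSpec}}.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @examples
#' nrow(discPixels(c(5, 5), 0.4, roiSpec(10, 10)))
#' @export
discPixels <- function(centroidXy, diameter, roi) {
    stopifnot(diameter > 0)
    x <- centroidXy[1]; y <- centroidXy[2]
    if (x < 0 || x > roi@widthUm || y < 0 || y > roi@heightUm)
        stop("centroid lies outside the ROI")
    s <- roi@pixelScale
    d <- gridDim(roi)
    r <- diameter / 2
    c0 <- max(0L, .umToPix(x - r, s)); c1 <- min(d[2] - 1L, .umToPix(x + r, s))
    r0 <- max(0L, .umToPix(y - r, s)); r1 <- min(d[1] - 1L, .umToPix(y + r, s))
    rows <- integer(0); cols <- integer(0)
    if (c1 >= c0 && r1 >= r0) {
        g <- expand.grid(row = r0:r1, col = c0:c1)
        cx <- .pixCenterUm(g$col, s); cy <- .pixCenterUm(g$row, s)
        keep <- (cx - x)^2 + (cy - y)^2 <= r^2
        rows <- g$row[keep]; cols <- g$col[keep]
    }
    if (length(rows) == 0L) {
        ## nearest in-grid pixel to the centroid
        cc <- min(max(.umToPix(x, s), 0L), d[2] - 1L)
        rr <- min(max(.umToPix(y, s), 0L), d[1] - 1L)
        rows <- rr; cols <- cc
    }
    cbind(row = as.integer(rows), col = as.integer(cols))
}

#' Feret's diameter of a pixel set
#'
#' Maximum caliper diameter: the largest pairwise distance between member-
#' pixel corner points, computed over the convex hull, reported in
#' micrometres.  This matches the standard particle-analysis definition; a
#' single pixel has Feret equal to its diagonal.
#'
#' @param px integer matrix with columns \code{row}, \code{col} (0-based).
#' @param scale pixels per micrometre.
#' @return Feret's diameter in micrometres.
#' @export
feretDiameter <- function(px, scale) {
    ## corner points of every pixel, in um
    cc <- px[, "col"]; rr <- px[, "row"]
    corners <- unique(cbind(
        x = c(cc, cc + 1L, cc, cc + 1L) / scale,
        y = c(rr, rr, rr + 1L, rr + 1L) / scale))
    h <- grDevices::chull(corners)
    hp <- corners[h, , drop = FALSE]
    dmat <- as.matrix(stats::dist(hp))
    max(dmat)
}

#' Rasterise a PunctaSet to a binary mask
#'
#' A mask pixel is TRUE iff it belongs to at least one punctum.  Every
#' punctum must carry a pixel set; coordinate-table puncta should first be
#' materialised with \code{\link{materializePixels}}.
#'
#' @param x a pixel-backed \code{\linkS4class{PunctaSet}}.
#' @return a \code{\linkS4class{BinaryMask}}.
#' @rdname punctaToMask
#' @export
setMethod("punctaToMask", "PunctaSet", function(x) {
    d <- gridDim(x@roi)
    g <- matrix(FALSE, d[1], d[2])
    if (nPuncta(x) > 0) {
        if (length(x@pixels) != nPuncta(x))
            stop("punctaToMask: puncta lack pixel sets; ",
                 "call materializePixels() first")
        for (i in seq_len(nPuncta(x))) {
            px <- x@pixels[[i]]
            if (is.null(px) || nrow(px) == 0L)
                stop(sprintf("punctum id %s has no pixels",
                             x@puncta$id[i]))
            g[px[, c("row", "col"), drop = FALSE] + 1L] <- TRUE
        }
    }
    new("BinaryMask", grid = g, roi = x@roi)
})

#' Materialise disc pixel footprints for coordinate-table puncta
#'
#' Pixel-overlap operations need a pixel footprint.  Puncta loaded from
#' coordinate tables (centroid/area/Feret only) are materialised as discs of
#' their recorded Feret diameter centred on the centroid; pixel-backed sets
#' are returned unchanged.
#'
#' @param x a \code{\linkS4class{PunctaSet}}.
#' @return a pixel-backed \code{\linkS4class{PunctaSet}}.
#' @export
materializePixels <- function(x) {
    if (length(x@pixels) == nPuncta(x)) return(x)
    p <- x@puncta
    px <- lapply(seq_len(nrow(p)), function(i) {
        if (is.na(p$feret_um[i]))
            stop(sprintf("punctum id %s lacks a Feret diameter; cannot ",
                         p$id[i]), "materialise a disc footprint")
        discPixels(c(p$x_um[i], p$y_um[i]), p$feret_um[i], x@roi)
    })
    punctaSet(x@channel, x@roi, p, px,
              paste0(x@provenance, "; discs materialised from Feret"))
}

#' Construct a BinaryMask
#'
#' @param grid logical matrix with dimensions \code{gridDim(roi)}.
#' @param roi a \code{\linkS4class{RoiSpec}}.
#' @export
binaryMask <- function(grid, roi) new("BinaryMask", grid = grid, roi = roi)

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask: %d / %d pixels set (%.2f%%)\n",
                sum(object@grid), length(object@grid),
                100 * mean(object@grid)))
})
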