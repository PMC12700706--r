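## 8-connected component labeling.  EBImage::bwlabel is 4-connected, so we
## label with it and then merge labels that touch diagonally (union-find
## over the label graph).  Returns list(labels = integer matrix, n = count).
.labelComponents8 <- function(mask) {
    if (!any(mask)) return(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                                n = 0L))
    lab <- EBImage::bwlabel(mask * 1L)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    nr <- nrow(lab); nc <- ncol(lab)
    ## diagonally adjacent distinct labels
    p1a <- lab[-nr, -nc]; p1b <- lab[-1, -1]     # down-right
    p2a <- lab[-nr, -1];  p2b <- lab[-1, -nc]    # down-left
    sel1 <- p1a > 0L & p1b > 0L & p1a != p1b
    sel2 <- p2a > 0L & p2b > 0L & p2a != p2b
    edges <- unique(rbind(cbind(p1a[sel1], p1b[sel1]),
                          cbind(p2a[sel2], p2b[sel2])))
    nlab <- max(lab)
    parent <- seq_len(nlab)
    if (nrow(edges)) for (e in seq_len(nrow(edges))) {
        ra <- edges[e, 1]; while (parent[ra] != ra) ra <- parent[ra]
        rb <- edges[e, 2]; while (parent[rb] != rb) rb <- parent[rb]
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), function(i) {
        while (parent[i] != i) i <- parent[i]; i
    }, integer(1))
    newid <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0L] <- newid[lab[lab > 0L]]
    list(labels = out, n = length(unique(newid)))
}

.countPuncta <- function(image, threshold) {
    .labelComponents8(image >= threshold)$n
}

#' Segment a channel image into puncta
#'
#' Pixels at or above the threshold form the foreground; its 8-connected
#' components become puncta.  Per punctum: area is pixel count divided by
#' the squared pixel scale, the centroid is the unweighted mean of pixel
#' centres, Feret's diameter is the maximum caliper over pixel corners, and
#' total/mean intensity come from the raw pixel values.  Single-pixel
#' components are retained unless \code{minAreaPx} is raised; the filter is
#' recorded in provenance.
#'
#' @param image intensity matrix (rows = y, cols = x).
#' @param threshold intensity threshold (from
#'   \code{\link{calibrateThreshold}} or explicit).
#' @param roi the \code{\linkS4class{RoiSpec}} the image covers.
#' @param channel channel label for the result.
#' @param minAreaPx minimum component size in pixels (default 1).
#' @return a pixel-backed \code{\linkS4class{PunctaSet}} (empty image gives
#'   an empty set, not an error).
#' @export
segmentChannel <- function(image, threshold, roi, channel = "channel",
                           minAreaPx = 1L) {
    d <- gridDim(roi)
    if (!all(dim(image) == d))
        stop(sprintf("image is %d x %d but the ROI grid is %d x %d",
                     nrow(image), ncol(image), d[1], d[2]))
    lab <- .labelComponents8(image >= threshold)
    prov <- sprintf("segmented at threshold %.6g, minAreaPx %d", threshold,
                    as.integer(minAreaPx))
    if (lab$n == 0L)
        return(punctaSet(channel, roi, data.frame(
            id = integer(0), x_um = numeric(0), y_um = numeric(0),
            area_um2 = numeric(0), feret_um = numeric(0),
            total_intensity = numeric(0), mean_intensity = numeric(0)),
            provenance = prov))
    idx <- which(lab$labels > 0L)
    comp <- lab$labels[idx]
    rc <- arrayInd(idx, dim(image))
    s <- roi@pixelScale
    bylab <- split(seq_along(idx), comp)
    keep <- lengths(bylab) >= minAreaPx
    bylab <- bylab[keep]
    rows <- lapply(seq_along(bylab), function(k) {
        ii <- bylab[[k]]
        px <- cbind(row = rc[ii, 1] - 1L, col = rc[ii, 2] - 1L)
        vals <- image[idx[ii]]
        data.frame(
            id = k,
            x_um = mean(.pixCenterUm(px[, "col"], s)),
            y_um = mean(.pixCenterUm(px[, "row"], s)),
            area_um2 = nrow(px) / s^2,
            feret_um = feretDiameter(px, s),
            total_intensity = sum(vals),
            mean_intensity = mean(vals))
    })
    pixels <- lapply(bylab, function(ii)
        cbind(row = rc[ii, 1] - 1L, col = rc[ii, 2] - 1L))
    names(pixels) <- NULL
    punctaSet(channel, roi, do.call(rbind, rows), pixels, prov)
}

#' Calibrate a segmentation threshold on the negative control
#'
#' Returns the lowest threshold at which the puncta detected on the
#' negative-control image are at most \code{maxAllowed} (default 3 percent,
#' the looser of the printed 1--3 percent bounds) of the puncta detected on
#' the experimental image.  Candidate thresholds are scanned over quantiles
#' of the pooled positive pixel values; raising \code{maxAllowed} never
#' raises the returned threshold.
#'
#' @param expImage experimental intensity matrix.
#' @param negImage negative-control intensity matrix (same dimensions).
#' @param maxAllowed maximum allowed negative/experimental puncta ratio,
#'   in (0, 1).
#' @param channel channel label for the result.
#' @param nCandidates number of candidate thresholds scanned.
#' @return a \code{\linkS4class{ThresholdCalibration}}.
#' @export
calibrateThreshold <- function(expImage, negImage, maxAllowed = 0.03,
                               channel = "channel", nCandidates = 100L) {
    if (!all(dim(expImage) == dim(negImage)))
        stop("experimental and negative images must share dimensions")
    if (maxAllowed <= 0 || maxAllowed >= 1)
        stop("maxAllowed must be in (0, 1)")
    ## Candidate thresholds: body quantiles of the pooled positive values
    ## plus a dense upper tail (the working threshold usually sits just
    ## above the negative-control noise ceiling) and a value just past the
    ## negative image's maximum, which always zeroes the control.
    vals <- c(expImage, negImage)
    vals <- vals[vals > 0]
    if (length(vals) == 0) stop("no positive pixel values to calibrate on")
    body <- seq(0, 0.98, length.out = max(nCandidates - 12L, 5L))
    tail <- c(0.985, 0.99, 0.995, 0.998, 0.999, 0.9995, 0.9999, 1)
    cand <- c(stats::quantile(vals, probs = c(body, tail), names = FALSE),
              stats::quantile(negImage[negImage > 0],
                              probs = c(0.999, 0.9999), names = FALSE),
              max(negImage) * (1 + 1e-9) + 1e-9)
    cand <- sort(unique(cand))
    for (thr in cand) {
        nExp <- .countPuncta(expImage, thr)
        if (nExp == 0L) break
        nNeg <- .countPuncta(negImage, thr)
        if (nNeg / nExp <= maxAllowed)
            return(new("ThresholdCalibration", channel = channel,
                       threshold = thr,
                       negControlFraction = nNeg / nExp,
                       maxAllowed = maxAllowed))
    }
    stop("no threshold keeps the negative control below ",
         sprintf("%.1f%%", 100 * maxAllowed),
         " of experimental puncta; the negative control resembles the ",
         "experimental image -- inspect both images")
}

setMethod("show", "ThresholdCalibration", function(object) {
    cat(sprintf(
        "ThresholdCalibration '%s': threshold %.6g (neg fraction %.4f <= %.2f)\n",
        object@channel, object@threshold, object@negControlFraction,
        object@maxAllowed))
})

#' Otsu threshold initialiser
#'
#' Convenience wrapper around the standard between-class-variance threshold,
#' offered as an alternative starting point when no negative control is
#' available.  Negative-control calibration remains the primary route.
#'
#' @param image intensity matrix.
#' @return scalar threshold on the image's intensity scale.
#' @export
otsuThreshold <- function(image) {
    rng <- range(image)
    EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
}

#' Remove puncta overlapping (expanded) nuclei
#'
#' Each nucleus component of the DAPI mask is expanded so its area grows by
#' \code{expansionFraction} (isotropic dilation by the radius r solving
#' pi (R + r)^2 = (1 + f) pi R^2 for the component's equivalent-circle
#' radius R), and any punctum sharing at least one pixel with the expanded
#' mask is removed.  The removal count is reported via \code{message()} and
#' recorded in the returned set's provenance.
#'
#' @param set a \code{\linkS4class{PunctaSet}} (materialised to discs if it
#'   has no pixel footprints).
#' @param dapiMask nuclear \code{\linkS4class{BinaryMask}} on the same ROI.
#' @param expansionFraction fractional area growth (default 0.10).
#' @return the filtered \code{\linkS4class{PunctaSet}}.
#' @export
excludeNuclear <- function(set, dapiMask, expansionFraction = 0.10) {
    d <- gridDim(set@roi)
    if (!all(dim(dapiMask@grid) == d))
        stop("mask and puncta must share the ROI grid")
    if (!any(dapiMask@grid) || nPuncta(set) == 0L) return(set)
    lab <- .labelComponents8(dapiMask@grid)
    expanded <- dapiMask@grid
    idx <- which(lab$labels > 0L)
    rc <- arrayInd(idx, d)
    comps <- split(seq_along(idx), lab$labels[idx])
    for (ii in comps) {
        n <- length(ii)
        R <- sqrt(n / pi)
        r <- R * (sqrt(1 + expansionFraction) - 1)
        w <- floor(r)
        offs <- expand.grid(dr = -(w + 1L):(w + 1L), dc = -(w + 1L):(w + 1L))
        offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, , drop = FALSE]
        if (nrow(offs) == 0) next
        rr <- outer(rc[ii, 1], offs$dr, `+`)
        cc <- outer(rc[ii, 2], offs$dc, `+`)
        ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
        expanded[cbind(rr[ok], cc[ok])] <- TRUE
    }
    set <- materializePixels(set)
    hit <- vapply(set@pixels, function(px)
        any(expanded[px[, c("row", "col"), drop = FALSE] + 1L]),
        logical(1))
    message(sprintf("excludeNuclear: removed %d of %d puncta", sum(hit),
                    nPuncta(set)))
    out <- set[!hit]
    out@provenance <- paste0(set@provenance,
                             sprintf("; nuclear exclusion removed %d",
                                     sum(hit)))
    out
}
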