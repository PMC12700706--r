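#' Construct an overlap criterion
#'
#' @param mode \code{"pixel"} (shared-pixel overlap, the lenient default
#'   matching segmented-object intersection) or \code{"centroid"}
#'   (centroid-to-centroid distance against a fraction of the summed radii).
#' @param fraction centroid-mode multiplier on the summed radii: 0.99 for
#'   the lenient ">1 percent overlap" definition, 0.50 for the stringent
#'   ">50 percent overlap" definition.
#' @param minPixels pixel-mode minimum shared pixels (default 1).
#' @return an \code{\linkS4class{OverlapCriterion}}.
#' @examples
#' overlapCriterion("centroid", fraction = 0.5)
#' @export
overlapCriterion <- function(mode = c("pixel", "centroid"), fraction = 0.99,
                             minPixels = 1L) {
    mode <- match.arg(mode)
    new("OverlapCriterion", mode = mode, fraction = fraction,
        minPixels = as.integer(minPixels))
}

setMethod("show", "OverlapCriterion", function(object) {
    if (object@mode == "pixel")
        cat(sprintf("OverlapCriterion: pixel mode, >= %d shared pixel(s)\n",
                    object@minPixels))
    else
        cat(sprintf(
            "OverlapCriterion: centroid mode, dist < %.2f x summed radii\n",
            object@fraction))
})

## All (a, b) candidate index pairs with dist(a, b) <= maxDist, found by
## binning b into square cells of side maxDist and scanning the 3x3 cell
## neighbourhood of every a.  Vectorised over the 9 offsets.
.pairsWithin <- function(ax, ay, bx, by, maxDist) {
    na <- length(ax); nb <- length(bx)
    if (na == 0L || nb == 0L)
        return(list(a = integer(0), b = integer(0), d = numeric(0)))
    cs <- max(maxDist, 1e-9)
    acx <- floor(ax / cs); acy <- floor(ay / cs)
    bcx <- floor(bx / cs); bcy <- floor(by / cs)
    span <- max(acy, bcy) - min(acy, bcy) + 3
    key <- function(cx, cy) cx * span + cy
    bkey <- key(bcx, bcy)
    bgroups <- split(seq_len(nb), bkey)
    gsize <- lengths(bgroups)
    ai <- vector("list", 9L); bi <- vector("list", 9L)
    k <- 0L
    for (dx in -1:1) for (dy in -1:1) {
        k <- k + 1L
        akey <- key(acx + dx, acy + dy)
        m <- match(as.character(akey), names(bgroups))
        hit <- which(!is.na(m))
        if (length(hit) == 0L) next
        g <- m[hit]
        ai[[k]] <- rep(hit, gsize[g])
        bi[[k]] <- unlist(bgroups[g], use.names = FALSE)
    }
    a <- unlist(ai, use.names = FALSE); b <- unlist(bi, use.names = FALSE)
    if (is.null(a))
        return(list(a = integer(0), b = integer(0), d = numeric(0)))
    d <- sqrt((ax[a] - bx[b])^2 + (ay[a] - by[b])^2)
    keep <- d <= maxDist
    list(a = a[keep], b = b[keep], d = d[keep])
}

#' Reference puncta colocalized with a target channel
#'
#' Pixel mode: ids of reference puncta whose footprint shares at least
#' \code{minPixels} pixels with the union mask of the target channel
#' (coordinate-table puncta are materialised as Feret-diameter discs).
#' Centroid mode: ids of reference puncta having some target punctum at
#' centroid distance strictly less than
#' \code{fraction * (feretA + feretB) / 2}.  Each reference punctum is
#' counted at most once however many partners it has.
#'
#' @param A reference \code{\linkS4class{PunctaSet}}.
#' @param B target \code{\linkS4class{PunctaSet}} (same ROI).
#' @param crit an \code{\linkS4class{OverlapCriterion}}.
#' @return vector of colocalized reference punctum ids.
#' @export
colocalizedReferenceIds <- function(A, B, crit = overlapCriterion()) {
    if (!isTRUE(all.equal(c(A@roi@widthUm, A@roi@heightUm),
                          c(B@roi@widthUm, B@roi@heightUm))))
        stop("A and B must share the ROI")
    if (nPuncta(A) == 0L || nPuncta(B) == 0L)
        return(A@puncta$id[integer(0)])
    if (crit@mode == "centroid") {
        pa <- A@puncta; pb <- B@puncta
        if (anyNA(pa$feret_um))
            stop("centroid criterion needs Feret diameters; missing for ",
                 "punctum id ", pa$id[which(is.na(pa$feret_um))[1]],
                 " in channel ", A@channel)
        if (anyNA(pb$feret_um))
            stop("centroid criterion needs Feret diameters; missing for ",
                 "punctum id ", pb$id[which(is.na(pb$feret_um))[1]],
                 " in channel ", B@channel)
        maxD <- crit@fraction * (max(pa$feret_um) + max(pb$feret_um)) / 2
        pr <- .pairsWithin(pa$x_um, pa$y_um, pb$x_um, pb$y_um, maxD)
        thr <- crit@fraction * (pa$feret_um[pr$a] + pb$feret_um[pr$b]) / 2
        sort(unique(pa$id[pr$a[pr$d < thr]]))
    } else {
        A <- materializePixels(A)
        B <- materializePixels(B)
        mask <- punctaToMask(B)@grid
        hits <- vapply(seq_len(nPuncta(A)), function(i) {
            px <- A@pixels[[i]]
            sum(mask[px[, c("row", "col"), drop = FALSE] + 1L])
        }, numeric(1))
        sort(A@puncta$id[hits >= crit@minPixels])
    }
}

#' Percent colocalization relative to the reference channel
#'
#' The displayed-equation normalization: 100 times the number of reference
#' puncta colocalized with the target channel, divided by the total number
#' of reference puncta.  Undefined (NA) for an empty reference channel.
#'
#' @inheritParams colocalizedReferenceIds
#' @return percentage in [0, 100], or NA if the reference set is empty.
#' @examples
#' ## 85 of 107 reference puncta colocalized -> 79.4%
#' @export
percentOfReference <- function(A, B, crit = overlapCriterion()) {
    if (nPuncta(A) == 0L) return(NA_real_)
    100 * length(colocalizedReferenceIds(A, B, crit)) / nPuncta(A)
}

#' Percent colocalization relative to the combined pair
#'
#' The symmetric normalization: 100 times the number of colocalized puncta
#' counted on both sides, divided by the combined puncta count of the two
#' channels.  Counting colocalized ids on each side (rather than twice the
#' pair count) keeps hub puncta from being double-counted.  Undefined (NA)
#' when both channels are empty.
#'
#' @inheritParams colocalizedReferenceIds
#' @return percentage in [0, 100], or NA if both sets are empty.
#' @export
percentOfPair <- function(A, B, crit = overlapCriterion()) {
    nA <- nPuncta(A); nB <- nPuncta(B)
    if (nA + nB == 0L) return(NA_real_)
    100 * (length(colocalizedReferenceIds(A, B, crit)) +
           length(colocalizedReferenceIds(B, A, crit))) / (nA + nB)
}

#' Pairwise colocalization matrix across channels
#'
#' Fills \code{counts[ref, tgt]} with the number of reference puncta
#' colocalized with the target channel for every ordered pair (12 channels
#' give 66 unordered pairs).  Percentages under either normalization are
#' obtained with \code{\link{colocPercent}}.
#'
#' @param sets list of \code{\linkS4class{PunctaSet}} (>= 2 channels,
#'   unique labels).
#' @param crit an \code{\linkS4class{OverlapCriterion}}.
#' @param normalization \code{"percent_of_reference"} or
#'   \code{"percent_of_pair"}.
#' @return a \code{\linkS4class{ColocalizationMatrix}}.
#' @export
pairwiseMatrix <- function(sets, crit = overlapCriterion(),
                           normalization = c("percent_of_reference",
                                             "percent_of_pair")) {
    normalization <- match.arg(normalization)
    if (length(sets) < 2) stop("need at least 2 channels")
    nms <- vapply(sets, channelName, character(1))
    if (anyDuplicated(nms)) stop("duplicated channel labels")
    names(sets) <- nms
    k <- length(sets)
    cnt <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        cnt[i, j] <- length(colocalizedReferenceIds(sets[[i]], sets[[j]],
                                                    crit))
    }
    tot <- vapply(sets, nPuncta, numeric(1))
    new("ColocalizationMatrix", channels = nms, counts = cnt,
        totals = tot, normalization = normalization)
}

#' @rdname colocAccessors
#' @export
setMethod("colocCounts", "ColocalizationMatrix", function(x) x@counts)

#' @rdname colocAccessors
#' @export
setMethod("colocTotals", "ColocalizationMatrix", function(x) x@totals)

#' @rdname colocAccessors
#' @export
setMethod("channelNames", "ColocalizationMatrix", function(x) x@channels)

#' Accessors for ColocalizationMatrix
#'
#' \code{colocPercent} converts the raw counts to percentages under the
#' matrix's normalization.  \code{percent_of_reference} divides each
#' reference row by the reference total; \code{percent_of_pair} returns the
#' symmetric matrix \code{100 (c[a,b] + c[b,a]) / (n_a + n_b)}.  Cells with
#' an empty denominator are NA (missing, not zero).
#'
#' @param x a \code{\linkS4class{ColocalizationMatrix}}.
#' @name colocAccessors
#' @rdname colocAccessors
#' @export
setMethod("colocPercent", "ColocalizationMatrix", function(x) {
    k <- length(x@channels)
    cnt <- x@counts; tot <- x@totals
    out <- matrix(NA_real_, k, k, dimnames = dimnames(cnt))
    if (x@normalization == "percent_of_reference") {
        for (i in seq_len(k))
            if (tot[i] > 0) out[i, ] <- 100 * cnt[i, ] / tot[i]
        diag(out) <- NA_real_
    } else {
        for (i in seq_len(k)) for (j in seq_len(k)) {
            if (i == j) next
            den <- tot[i] + tot[j]
            if (den > 0) out[i, j] <- 100 * (cnt[i, j] + cnt[j, i]) / den
        }
    }
    out
})

setMethod("show", "ColocalizationMatrix", function(object) {
    cat(sprintf("ColocalizationMatrix: %d channels, %s\n",
                length(object@channels), object@normalization))
    print(round(colocPercent(object), 1))
})

#' Reference puncta colocalized with any of several channels
#'
#' The union-layer operation: ids of reference puncta colocalized with at
#' least one punctum from any of the \code{others} channels.  Equals the
#' union of the per-channel \code{\link{colocalizedReferenceIds}} calls.
#'
#' @param A reference \code{\linkS4class{PunctaSet}}.
#' @param others non-empty list of partner \code{\linkS4class{PunctaSet}}.
#' @param crit an \code{\linkS4class{OverlapCriterion}}.
#' @return vector of colocalized reference punctum ids.
#' @export
colocalizedWithAny <- function(A, others, crit = overlapCriterion()) {
    if (length(others) == 0) stop("others must be non-empty")
    ids <- lapply(others, function(B) colocalizedReferenceIds(A, B, crit))
    sort(unique(unlist(ids)))
}
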