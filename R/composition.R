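#' Classify focal puncta as singleton, dimer or multimer
#'
#' Each focal-channel punctum is assigned to exactly one category with
#' respect to the partner panel: \code{singleton} (colocalized with no
#' partner channel), \code{dimer_<P>} (exactly one partner channel, P),
#' \code{multimer_with_special} (two or more partner channels including the
#' special partner) or \code{multimer_without_special}.  "Dimer/multimer"
#' counts distinct partner channels, not partner puncta: a focal punctum
#' overlapping two puncta of one channel is a dimer of that channel.
#'
#' @param focal focal \code{\linkS4class{PunctaSet}}.
#' @param partners list of partner \code{\linkS4class{PunctaSet}} (non-empty,
#'   unique labels, not containing the focal channel).
#' @param special label of the distinguished partner (must be in the panel).
#' @param crit an \code{\linkS4class{OverlapCriterion}}.
#' @return list with \code{perPunctum} (data.frame: id, category,
#'   comma-separated partner channels) and \code{summary}
#'   (a \code{\linkS4class{CompositionSummary}}).
#' @export
classifyComposition <- function(focal, partners,
                                special, crit = overlapCriterion()) {
    if (length(partners) == 0) stop("partner panel must be non-empty")
    pnames <- vapply(partners, channelName, character(1))
    if (anyDuplicated(pnames)) stop("duplicated partner labels")
    if (!special %in% pnames)
        stop("special partner '", special, "' is not in the panel")
    names(partners) <- pnames
    ids <- punctaTable(focal)$id
    if (length(ids) == 0) {
        levelsAll <- c("singleton", paste0("dimer_", pnames),
                       "multimer_with_special", "multimer_without_special")
        frac <- rep(NA_real_, length(levelsAll)); names(frac) <- levelsAll
        cnt <- rep(0, length(levelsAll)); names(cnt) <- levelsAll
        return(list(
            perPunctum = data.frame(id = integer(0), category = character(0),
                                    partners = character(0)),
            summary = new("CompositionSummary", focal = channelName(focal),
                          partners = pnames, special = special,
                          fractions = frac, counts = cnt, nFocal = 0)))
    }
    hit <- sapply(partners, function(B)
        ids %in% colocalizedReferenceIds(focal, B, crit))
    hit <- matrix(hit, nrow = length(ids),
                  dimnames = list(NULL, pnames))
    nchan <- rowSums(hit)
    withSpecial <- hit[, special]
    category <- character(length(ids))
    category[nchan == 0] <- "singleton"
    one <- which(nchan == 1)
    category[one] <- paste0("dimer_", pnames[apply(
        hit[one, , drop = FALSE], 1, which)])
    category[nchan >= 2 & withSpecial] <- "multimer_with_special"
    category[nchan >= 2 & !withSpecial] <- "multimer_without_special"
    partnersStr <- apply(hit, 1, function(h)
        paste(pnames[h], collapse = ","))
    levelsAll <- c("singleton", paste0("dimer_", pnames),
                   "multimer_with_special", "multimer_without_special")
    cnt <- table(factor(category, levels = levelsAll))
    n <- length(ids)
    frac <- if (n > 0) 100 * as.numeric(cnt) / n else
        rep(NA_real_, length(levelsAll))
    names(frac) <- levelsAll
    counts <- as.numeric(cnt); names(counts) <- levelsAll
    summ <- new("CompositionSummary", focal = channelName(focal),
                partners = pnames, special = special, fractions = frac,
                counts = counts, nFocal = as.numeric(n))
    list(perPunctum = data.frame(id = ids, category = category,
                                 partners = partnersStr),
         summary = summ)
}

#' @rdname compositionAccessors
#' @export
setMethod("compositionFractions", "CompositionSummary",
          function(x) x@fractions)

#' Accessors for CompositionSummary
#'
#' @param x a \code{\linkS4class{CompositionSummary}}.
#' @name compositionAccessors
#' @rdname compositionAccessors
NULL

setMethod("show", "CompositionSummary", function(object) {
    cat(sprintf("CompositionSummary: %s vs %d partners (special: %s), n = %d\n",
                object@focal, length(object@partners), object@special,
                as.integer(object@nFocal)))
    f <- object@fractions
    for (nm in names(f))
        if (f[nm] > 0 || !startsWith(nm, "dimer_"))
            cat(sprintf("  %-28s %6.2f%%\n", nm, f[nm]))
})

#' Composition under the rotation null
#'
#' Repeats \code{\link{classifyComposition}} with the focal channel rotated
#' about the ROI centre while partner channels stay in place, giving the
#' composition expected from chance overlap.
#'
#' @inheritParams classifyComposition
#' @param angle 90 or 180 degrees.
#' @return as \code{\link{classifyComposition}}.
#' @export
compositionNull <- function(focal, partners, special,
                            crit = overlapCriterion(), angle = 90) {
    classifyComposition(rotatePuncta(focal, angle), partners, special, crit)
}

#' Gate channels by a protein marker
#'
#' Reduces every channel to the puncta colocalized with the marker signal --
#' e.g. restricting mRNA puncta to those inside protein-positive granules.
#' The marker may be a segmented \code{\linkS4class{PunctaSet}} or a
#' \code{\linkS4class{BinaryMask}} (an immunostain mask); for a mask the
#' pixel-overlap criterion applies (a punctum passes when its footprint
#' shares at least \code{crit@minPixels} pixels with the mask).
#'
#' @param sets list of \code{\linkS4class{PunctaSet}}.
#' @param marker a \code{\linkS4class{PunctaSet}} or
#'   \code{\linkS4class{BinaryMask}}.
#' @param crit an \code{\linkS4class{OverlapCriterion}} (default: pixel
#'   overlap, matching immunostain-mask gating).
#' @return list of gated \code{\linkS4class{PunctaSet}}, same order.
#' @export
gateByMarker <- function(sets, marker, crit = overlapCriterion()) {
    gateOne <- function(A) {
        if (is(marker, "BinaryMask")) {
            A2 <- materializePixels(A)
            keep <- vapply(A2@pixels, function(px)
                sum(marker@grid[px[, c("row", "col"), drop = FALSE] + 1L]) >=
                    crit@minPixels, logical(1))
            A2[keep]
        } else {
            ids <- colocalizedReferenceIds(A, marker, crit)
            A[punctaTable(A)$id %in% ids]
        }
    }
    lapply(sets, gateOne)
}
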