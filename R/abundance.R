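#' Augment a channel to a target abundance with bootstrap puncta
#'
#' Adds synthetic puncta to a channel until it reaches \code{targetCount}:
#' attributes (area, Feret's diameter, total intensity) are resampled with
#' replacement from the observed puncta of the channel (so synthetic values
#' stay within the observed minimum-to-maximum range by construction;
#' \code{method = "uniform"} instead draws uniformly over that range);
#' centroids are uniform over the ROI with no duplicate coordinates among
#' observed plus synthetic puncta.  Observed puncta are untouched, and no
#' nuclear mask is applied at this stage (augmentation samples the full
#' ROI).
#'
#' @param set the \code{\linkS4class{PunctaSet}} to augment.
#' @param targetCount desired total puncta count (>= current count; there
#'   is no removal mode).
#' @param seed integer seed.
#' @param method \code{"resample"} (bootstrap, default) or
#'   \code{"uniform"} (uniform over the observed min--max range).
#' @return the augmented \code{\linkS4class{PunctaSet}}.
#' @export
augmentChannel <- function(set, targetCount, seed = 1,
                           method = c("resample", "uniform")) {
    method <- match.arg(method)
    nCur <- nPuncta(set)
    if (targetCount < nCur)
        stop(sprintf("targetCount (%d) < current count (%d): no removal mode",
                     as.integer(targetCount), nCur))
    nAdd <- as.integer(targetCount) - nCur
    if (nAdd == 0L) return(set)
    if (nCur == 0L) stop("cannot bootstrap attributes from an empty channel")
    p <- punctaTable(set)
    roi <- roiOf(set)
    .withSeed(seed, {
        if (method == "resample") {
            ri <- sample.int(nCur, nAdd, replace = TRUE)
            area <- p$area_um2[ri]; feret <- p$feret_um[ri]
            total <- p$total_intensity[ri]; meani <- p$mean_intensity[ri]
        } else {
            area <- stats::runif(nAdd, min(p$area_um2), max(p$area_um2))
            feret <- stats::runif(nAdd, min(p$feret_um), max(p$feret_um))
            total <- stats::runif(nAdd, min(p$total_intensity),
                                  max(p$total_intensity))
            meani <- rep(NA_real_, nAdd)
        }
        ## uniform centroids, rejecting exact duplicates of any coordinate
        seen <- paste(p$x_um, p$y_um)
        xs <- numeric(0); ys <- numeric(0)
        while (length(xs) < nAdd) {
            m <- nAdd - length(xs)
            x <- stats::runif(m, 0, roi@widthUm)
            y <- stats::runif(m, 0, roi@heightUm)
            key <- paste(x, y)
            ok <- !key %in% seen & !duplicated(key)
            xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
            seen <- c(seen, key[ok])
        }
        add <- data.frame(id = as.integer(max(p$id, 0)) + seq_len(nAdd),
                          x_um = xs,
                          y_um = ys, area_um2 = area, feret_um = feret,
                          total_intensity = total, mean_intensity = meani)
        punctaSet(channelName(set), roi, rbind(p, add),
                  provenance = paste0(set@provenance,
                                      sprintf("; augmented +%d (%s, seed %d)",
                                              nAdd, method, seed)))
    })
}

#' Simulated colocalization after abundance augmentation
#'
#' The abundance-matching experiment: the chosen channel is augmented to
#' \code{targetCount} with bootstrap puncta, its colocalization with the
#' partner channel is measured, and the procedure is repeated for
#' \code{nIterations} bootstrap iterations (default 10); the per-iteration
#' percentages are averaged.  The partner channel and the observed puncta
#' are never altered.
#'
#' @param set the \code{\linkS4class{PunctaSet}} to augment.
#' @param partner partner \code{\linkS4class{PunctaSet}}.
#' @param targetCount target abundance for \code{set}.
#' @param crit an \code{\linkS4class{OverlapCriterion}} (default centroid
#'   mode at 0.99, the lenient ">1 percent overlap" definition used for
#'   coordinate tables).
#' @param normalization \code{"percent_of_pair"} (default, the conventional
#'   comparison) or \code{"percent_of_reference"}.
#' @param nIterations bootstrap iterations (default 10).
#' @param seed integer seed; iteration i uses \code{seed + i - 1}.
#' @return list with \code{mean} percentage and \code{perIteration} vector.
#' @export
simulatedColocalization <- function(set, partner, targetCount,
                                    crit = overlapCriterion("centroid",
                                                            fraction = 0.99),
                                    normalization = c("percent_of_pair",
                                                      "percent_of_reference"),
                                    nIterations = 10, seed = 1) {
    normalization <- match.arg(normalization)
    stopifnot(nIterations >= 1)
    per <- vapply(seq_len(nIterations), function(i) {
        aug <- augmentChannel(set, targetCount, seed = seed + i - 1)
        if (normalization == "percent_of_pair")
            percentOfPair(aug, partner, crit)
        else percentOfReference(aug, partner, crit)
    }, numeric(1))
    list(mean = mean(per), perIteration = per)
}
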