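#' Normalized total intensity of puncta
#'
#' Total punctum intensity divided by its mean pixel intensity.  On pixel-
#' backed puncta this equals the pixel count exactly, so the normalized
#' value is an area surrogate on a common scale across channels whose
#' acquisition parameters differ -- the basis for comparing intensity
#' distributions across mRNAs.  The per-punctum reading is used (a
#' per-channel mean normalization is available via \code{perChannel}).
#'
#' @param x a \code{\linkS4class{PunctaSet}}.
#' @param perChannel if TRUE, divide by the channel-wide mean intensity
#'   instead of each punctum's own mean.
#' @return numeric vector, one value per punctum.
#' @export
normalizedTotalIntensity <- function(x, perChannel = FALSE) {
    p <- punctaTable(x)
    if (any(is.na(p$mean_intensity) | p$mean_intensity <= 0))
        stop("mean_intensity must be positive for every punctum")
    if (perChannel) p$total_intensity / mean(p$mean_intensity)
    else p$total_intensity / p$mean_intensity
}

#' Relative-percent histogram with an open tail bin
#'
#' Counts values into half-open bins \code{[k w, (k+1) w)} up to
#' \code{openTailFrom}, plus a final open bin \code{[openTailFrom, Inf)},
#' and converts to percent of total.  When \code{values} is a list (one
#' vector per replicate), per-replicate relative percentages are averaged
#' -- mass stays at 100 percent -- and the SEM across replicates is
#' reported.
#'
#' @param values numeric vector, or list of numeric vectors (replicates).
#' @param binWidth bin width (default 0.1, the area convention in square
#'   micrometres).
#' @param openTailFrom lower edge of the open tail bin (default 1.0).
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi} (Inf for
#'   the tail), \code{percent} and, for replicates, \code{sem}.
#' @export
relativeHistogram <- function(values, binWidth = 0.1, openTailFrom = 1.0) {
    stopifnot(binWidth > 0, openTailFrom > 0)
    if (!is.list(values)) values <- list(values)
    if (any(lengths(values) == 0)) stop("values must be non-empty")
    edges <- round(seq(0, openTailFrom, by = binWidth), 12)
    if (abs(edges[length(edges)] - openTailFrom) > 1e-9)
        edges <- c(edges, openTailFrom)
    lo <- edges
    hi <- c(edges[-1], Inf)
    pct <- vapply(values, function(v) {
        idx <- pmin(findInterval(v, edges), length(edges))
        idx[v < 0] <- NA
        tab <- tabulate(idx, nbins = length(edges))
        100 * tab / length(v)
    }, numeric(length(edges)))
    pct <- matrix(pct, nrow = length(edges))
    out <- data.frame(bin_lo = lo, bin_hi = hi,
                      percent = rowMeans(pct))
    if (length(values) > 1)
        out$sem <- apply(pct, 1, stats::sd) / sqrt(length(values))
    out
}

#' Hierarchically cluster distribution or colocalization profiles
#'
#' Agglomerative clustering of profile rows under the stated distance
#' metric with Ward-D2 linkage -- manhattan distance for relative-percent
#' area/intensity distributions (robust on skewed distributions), euclidean
#' for colocalization profiles.  Ward's criterion formally assumes squared
#' euclidean geometry; the manhattan/Ward pairing is retained deliberately
#' because it is the analysis convention this package reproduces.
#' \code{stats::hclust} is deterministic given the input order; ties merge
#' lowest index first.
#'
#' @param profiles numeric matrix, one profile per row (rownames label the
#'   items), or the data.frame returned by stacking
#'   \code{\link{relativeHistogram}} percents.
#' @param metric \code{"manhattan"} or \code{"euclidean"}.
#' @param k optional number of clusters to cut at.
#' @return list with \code{hclust} (the merge tree), \code{dist} metric
#'   used, and \code{clusters} (named cut labels, when \code{k} given).
#' @export
clusterProfiles <- function(profiles, metric = c("manhattan", "euclidean"),
                            k = NULL) {
    metric <- match.arg(metric)
    m <- as.matrix(profiles)
    if (nrow(m) < 2) stop("need at least 2 profiles")
    if (any(!is.finite(m))) stop("profiles contain non-finite values")
    d <- stats::dist(m, method = metric)
    hc <- stats::hclust(d, method = "ward.D2")
    out <- list(hclust = hc, metric = metric)
    if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
    out
}

#' Dendrogram as a Newick string
#'
#' @param hc an \code{hclust} object (e.g. from
#'   \code{\link{clusterProfiles}}).
#' @return single Newick-format string with branch lengths.
#' @export
dendrogramNewick <- function(hc) {
    n <- length(hc$labels)
    height <- hc$height
    node <- function(i, parentH) {
        if (i < 0) {
            lab <- hc$labels[-i]
            sprintf("%s:%.6g", lab, parentH)
        } else {
            l <- node(hc$merge[i, 1], height[i])
            r <- node(hc$merge[i, 2], height[i])
            sprintf("(%s,%s):%.6g", l, r, parentH - height[i])
        }
    }
    paste0("(", node(hc$merge[n - 1, 1], height[n - 1]), ",",
           node(hc$merge[n - 1, 2], height[n - 1]), ");")
}

#' Correlate colocalization with partner abundance
#'
#' Ordinary least squares of a reference channel's (random-subtracted)
#' colocalization percentages against partner-channel abundances -- the
#' quantitative form of the claim that colocalization scales with neuropil
#' abundance.
#'
#' @param percentages named numeric: percent of the reference channel
#'   colocalized with each partner (e.g. a row of a random-subtracted
#'   matrix), or a \code{\linkS4class{RotationNull}} /
#'   \code{\linkS4class{ColocalizationMatrix}} from which the reference row
#'   is taken.
#' @param abundances named per-channel puncta counts.
#' @param reference reference channel label (needed when a matrix object is
#'   supplied).
#' @return list with \code{slope}, \code{intercept}, \code{r.squared},
#'   \code{n}; all NA with fewer than 3 partners.
#' @export
abundanceCorrelation <- function(percentages, abundances, reference = NULL) {
    if (is(percentages, "RotationNull"))
        percentages <- percentages@subtracted[reference, ]
    else if (is(percentages, "ColocalizationMatrix"))
        percentages <- colocPercent(percentages)[reference, ]
    common <- intersect(names(percentages), names(abundances))
    common <- setdiff(common, reference)
    y <- percentages[common]; x <- abundances[common]
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3)
        return(list(slope = NA_real_, intercept = NA_real_,
                    r.squared = NA_real_, n = sum(ok)))
    fit <- stats::lm(y[ok] ~ x[ok])
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r.squared = summary(fit)$r.squared, n = sum(ok))
}
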