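## FNV-1a over a string; enough to stamp outputs with a config fingerprint.
.configHash <- function(x) {
    bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
    h <- 2166136261
    for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
    sprintf("%08x", h)
}

#' Run the full spatial-organization analysis
#'
#' Orchestrates the analysis stages on a set of segmented channels (or a
#' synthetic scene): pairwise colocalization under both the pixel-overlap
#' and the lenient centroid criteria, rotation-null estimation and
#' random subtraction, singleton/dimer/multimer composition of a focal
#' channel, relative-percent area histograms with hierarchical profile
#' clustering, abundance--colocalization correlation and, optionally, the
#' bootstrap abundance-matching simulation.  Outputs are stamped with a
#' configuration hash, the seed and the package version; identical inputs
#' and seed give identical results.
#'
#' @param channels named list of \code{\linkS4class{PunctaSet}}, or a
#'   \code{\linkS4class{SyntheticScene}}.
#' @param focal focal channel label for the composition stage (default:
#'   first channel).
#' @param special special partner for the composition stage (default: most
#'   abundant other channel).
#' @param nullAngle rotation-null angle, 90 or 180.
#' @param binWidth,openTailFrom area histogram parameters (square um).
#' @param augment optional list \code{(channel, targetCount, partner,
#'   nIterations)} enabling the abundance simulation stage.
#' @param crit criterion for matrix/composition stages (default pixel
#'   overlap); the centroid criterion at 0.99 is always computed alongside.
#' @param seed integer seed for the stochastic stages.
#' @return named list of stage results plus a \code{meta} stamp.
#' @export
runPipeline <- function(channels, focal = NULL, special = NULL,
                        nullAngle = 90, binWidth = 0.1, openTailFrom = 1.0,
                        augment = NULL, crit = overlapCriterion(),
                        seed = 1) {
    if (is(channels, "SyntheticScene")) channels <- channels@channels
    nms <- vapply(channels, channelName, character(1))
    names(channels) <- nms
    if (length(channels) < 2) stop("pipeline needs at least 2 channels")
    if (is.null(focal)) focal <- nms[1]
    tot <- vapply(channels, nPuncta, numeric(1))
    if (is.null(special))
        special <- names(which.max(tot[setdiff(nms, focal)]))
    cfg <- list(focal = focal, special = special, nullAngle = nullAngle,
                binWidth = binWidth, openTailFrom = openTailFrom,
                augment = augment, mode = crit@mode,
                fraction = crit@fraction, seed = seed)
    critCentroid <- overlapCriterion("centroid", fraction = 0.99)
    msg <- function(stage, txt) message(sprintf("[%s] %s", stage, txt))

    msg("coloc", sprintf("%d channels, %s puncta total", length(channels),
                         format(sum(tot), big.mark = ",")))
    null <- randomSubtractedMatrix(channels, crit, angle = nullAngle,
                                   normalization = "percent_of_reference")
    nullCentroid <- randomSubtractedMatrix(
        channels, critCentroid, angle = nullAngle,
        normalization = "percent_of_reference")

    msg("composition", sprintf("focal %s, special %s", focal, special))
    comp <- classifyComposition(channels[[focal]],
                                channels[setdiff(nms, focal)], special, crit)
    compNull <- compositionNull(channels[[focal]],
                                channels[setdiff(nms, focal)], special,
                                crit, angle = nullAngle)

    msg("distributions", "area histograms and profile clustering")
    hists <- lapply(channels, function(ch)
        relativeHistogram(punctaTable(ch)$area_um2, binWidth, openTailFrom))
    prof <- t(vapply(hists, function(h) h$percent,
                     numeric(nrow(hists[[1]]))))
    areaClusters <- if (nrow(prof) >= 2)
        clusterProfiles(prof, "manhattan",
                        k = min(4, nrow(prof))) else NULL
    corr <- abundanceCorrelation(null, tot, reference = focal)

    sim <- NULL
    if (!is.null(augment)) {
        msg("simulate", sprintf("augment %s to %d vs %s", augment$channel,
                                augment$targetCount, augment$partner))
        sim <- simulatedColocalization(
            channels[[augment$channel]], channels[[augment$partner]],
            augment$targetCount,
            nIterations = if (is.null(augment$nIterations)) 10
                          else augment$nIterations,
            seed = seed)
    }
    list(abundances = tot,
         null = null, nullCentroid = nullCentroid,
         composition = comp, compositionNull = compNull,
         areaHistograms = hists, areaClusters = areaClusters,
         abundanceCorrelation = corr, simulation = sim,
         meta = list(configHash = .configHash(cfg), seed = seed,
                     version = as.character(utils::packageVersion(
                         "punctacoloc"))))
}
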