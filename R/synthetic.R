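## Table of size-class area targets: median area (um2) and the relative mass
## expected in the 0.6-1.0 um2 bin and above 1.0 um2.  Medians are the
## across-RNA averages of the four empirical clusters; the log-normal log-sd
## is fitted so the two tail masses are matched as closely as a two-parameter
## family allows.
.sizeClassTargets <- list(
    small       = c(median = 0.23,  p06_1 = 0.0929, p1 = 0.0250),
    small_broad = c(median = 0.27,  p06_1 = 0.1589, p1 = 0.0938),
    large_broad = c(median = 0.285, p06_1 = 0.1447, p1 = 0.0269),
    large       = c(median = 0.346, p06_1 = 0.1632, p1 = 0.0314))

#' Log-normal parameters of a punctum size class
#'
#' Median fixes the log-mean; the log-sd is chosen by least squares against
#' the class's expected relative mass in the 0.6--1.0 um2 area bin and above
#' 1.0 um2.
#'
#' @param sizeClass one of \code{"small"}, \code{"small_broad"},
#'   \code{"large_broad"}, \code{"large"}.
#' @return named vector \code{c(meanlog, sdlog)}.
#' @export
sizeClassParams <- function(sizeClass) {
    t <- .sizeClassTargets[[sizeClass]]
    if (is.null(t)) stop("unknown size class: ", sizeClass)
    mu <- log(t[["median"]])
    obj <- function(s) {
        p1 <- stats::plnorm(1, mu, s, lower.tail = FALSE)
        p06 <- stats::plnorm(1, mu, s) - stats::plnorm(0.6, mu, s)
        (p1 - t[["p1"]])^2 + (p06 - t[["p06_1"]])^2
    }
    s <- stats::optimize(obj, c(0.1, 2))$minimum
    c(meanlog = mu, sdlog = s)
}

#' Construct a channel generator specification
#'
#' @param name channel label.
#' @param expectedCount mean puncta per ROI (Poisson mean, >= 0).
#' @param sizeClass area size class (see \code{\link{sizeClassParams}}), or
#'   \code{"custom"} with explicit \code{areaMeanlog}/\code{areaSdlog}.
#' @param areaMeanlog,areaSdlog explicit log-normal area parameters
#'   (override the size class).
#' @param copyNumber,copyNumberProb transcripts-per-punctum distribution
#'   (default: a single transcript per punctum).
#' @return a \code{\linkS4class{ChannelSpec}}.
#' @export
channelSpec <- function(name, expectedCount, sizeClass = "small",
                        areaMeanlog = NULL, areaSdlog = NULL,
                        copyNumber = 1L, copyNumberProb = NULL) {
    stopifnot(expectedCount >= 0)
    if (is.null(areaMeanlog) || is.null(areaSdlog)) {
        p <- sizeClassParams(sizeClass)
        areaMeanlog <- p[["meanlog"]]; areaSdlog <- p[["sdlog"]]
    } else {
        sizeClass <- "custom"
    }
    if (is.null(copyNumberProb))
        copyNumberProb <- rep(1 / length(copyNumber), length(copyNumber))
    new("ChannelSpec", name = name, expectedCount = as.numeric(expectedCount),
        sizeClass = sizeClass, areaMeanlog = areaMeanlog,
        areaSdlog = areaSdlog, copyNumber = as.integer(copyNumber),
        copyNumberProb = copyNumberProb / sum(copyNumberProb))
}

#' Construct a planted-colocalization plan
#'
#' @param channelA,channelB channel labels; a fraction of A puncta is
#'   co-placed next to distinct B puncta.
#' @param plantedFraction fraction of channel-A puncta to co-place, in [0,1].
#' @param jitterUm placement offset scale (um); the default 0.1 keeps
#'   planted pairs colocalized under both the 1-pixel and the >50 percent
#'   centroid criteria.
#' @return a \code{\linkS4class{GranulePlan}}.
#' @export
granulePlan <- function(channelA, channelB, plantedFraction,
                        jitterUm = 0.1) {
    new("GranulePlan", channelA = channelA, channelB = channelB,
        plantedFraction = plantedFraction, jitterUm = jitterUm)
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.nucleiMask <- function(roi, nucleiCount, diameterUm = 8) {
    d <- gridDim(roi)
    g <- matrix(FALSE, d[1], d[2])
    centers <- NULL
    if (nucleiCount > 0) {
        cx <- stats::runif(nucleiCount, 0, roi@widthUm)
        cy <- stats::runif(nucleiCount, 0, roi@heightUm)
        centers <- cbind(x = cx, y = cy)
        for (i in seq_len(nucleiCount)) {
            px <- discPixels(c(cx[i], cy[i]), diameterUm, roi)
            g[px[, c("row", "col"), drop = FALSE] + 1L] <- TRUE
        }
    }
    list(mask = new("BinaryMask", grid = g, roi = roi), centers = centers)
}

## Uniform centroids over the ROI, rejection-sampled outside the nuclei mask.
.uniformOutside <- function(n, roi, mask) {
    if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
    out <- matrix(NA_real_, n, 2)
    got <- 0L
    g <- mask@grid
    s <- roi@pixelScale
    d <- dim(g)
    while (got < n) {
        m <- (n - got) * 2L + 10L
        x <- stats::runif(m, 0, roi@widthUm)
        y <- stats::runif(m, 0, roi@heightUm)
        rr <- pmin(.umToPix(y, s), d[1] - 1L)
        cc <- pmin(.umToPix(x, s), d[2] - 1L)
        ok <- !g[cbind(rr + 1L, cc + 1L)]
        keep <- which(ok)[seq_len(min(sum(ok), n - got))]
        if (length(keep)) {
            out[(got + 1L):(got + length(keep)), ] <- cbind(x[keep], y[keep])
            got <- got + length(keep)
        }
    }
    colnames(out) <- c("x", "y")
    out
}

#' Generate a multi-channel puncta scene with known ground truth
#'
#' Per-channel puncta counts are Poisson with the spec's expected count;
#' centroids are uniform over the ROI outside the nuclear mask; areas are
#' log-normal draws from the channel's size class; Feret's diameter is the
#' equivalent-circle diameter times a shape factor uniform on [1, 1.3].
#' Granule plans then co-place the stated fraction of channel-A puncta
#' within \code{jitterUm} of distinct channel-B partners, recording granule
#' ids in the truth table.  All randomness is governed by \code{seed}.
#'
#' @param specs list of \code{\linkS4class{ChannelSpec}} (unique names).
#' @param roi a \code{\linkS4class{RoiSpec}}.
#' @param plans list of \code{\linkS4class{GranulePlan}}.
#' @param nucleiCount number of ~8 um nuclei to place (default 0).
#' @param seed integer seed.
#' @param perTranscriptIntensity fluorescence per transcript copy (a.u.).
#' @return a \code{\linkS4class{SyntheticScene}}.
#' @examples
#' sc <- generateScene(list(channelSpec("A", 50), channelSpec("B", 80)),
#'                     roiSpec(52, 52), seed = 1)
#' nPuncta(sc@channels$A)
#' @export
generateScene <- function(specs, roi, plans = list(), nucleiCount = 0,
                          seed = 1, perTranscriptIntensity = 100) {
    nms <- vapply(specs, function(s) s@name, character(1))
    if (anyDuplicated(nms)) stop("channel names must be unique")
    .withSeed(seed, {
        nuc <- .nucleiMask(roi, nucleiCount)
        chans <- list()
        truth <- list()
        for (sp in specs) {
            n <- stats::rpois(1, sp@expectedCount)
            xy <- .uniformOutside(n, roi, nuc$mask)
            area <- stats::rlnorm(n, sp@areaMeanlog, sp@areaSdlog)
            shape <- stats::runif(n, 1, 1.3)
            feret <- 2 * sqrt(area / pi) * shape
            copies <- sp@copyNumber[sample.int(length(sp@copyNumber), n,
                                               replace = TRUE,
                                               prob = sp@copyNumberProb)]
            total <- copies * perTranscriptIntensity
            npx <- pmax(1, round(area * roi@pixelScale^2))
            p <- data.frame(id = seq_len(n), x_um = xy[, "x"],
                            y_um = xy[, "y"], area_um2 = area,
                            feret_um = feret, total_intensity = total,
                            mean_intensity = total / npx)
            chans[[sp@name]] <- punctaSet(
                sp@name, roi, p,
                provenance = sprintf("generateScene seed=%d class=%s",
                                     seed, sp@sizeClass))
            truth[[sp@name]] <- data.frame(
                channel = rep(sp@name, n), id = seq_len(n),
                size_class = rep(sp@sizeClass, n), copy_number = copies,
                granule_id = rep(NA_integer_, n))
        }
        gid <- 0L
        for (pl in plans) {
            if (!all(c(pl@channelA, pl@channelB) %in% names(chans)))
                stop("granule plan names a channel missing from specs")
            A <- chans[[pl@channelA]]; B <- chans[[pl@channelB]]
            nPlant <- round(pl@plantedFraction * nPuncta(A))
            if (nPlant > nPuncta(B))
                stop(sprintf(
                    "plantedFraction %.2f demands %d partners but channel %s has only %d puncta",
                    pl@plantedFraction, nPlant, pl@channelB, nPuncta(B)))
            if (nPlant == 0) next
            ai <- sample.int(nPuncta(A), nPlant)
            bi <- sample.int(nPuncta(B), nPlant)
            pa <- A@puncta; pb <- B@puncta
            theta <- stats::runif(nPlant, 0, 2 * pi)
            rad <- pl@jitterUm * sqrt(stats::runif(nPlant))
            pa$x_um[ai] <- pmin(pmax(pb$x_um[bi] + rad * cos(theta), 0),
                                roi@widthUm)
            pa$y_um[ai] <- pmin(pmax(pb$y_um[bi] + rad * sin(theta), 0),
                                roi@heightUm)
            ids <- gid + seq_len(nPlant)
            gid <- gid + nPlant
            truth[[pl@channelA]]$granule_id[ai] <- ids
            truth[[pl@channelB]]$granule_id[bi] <- ids
            chans[[pl@channelA]] <- punctaSet(
                pl@channelA, roi, pa, provenance = A@provenance)
        }
        new("SyntheticScene", roi = roi, channels = chans,
            truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
            nuclei = nuc$mask, seed = as.numeric(seed))
    })
}

setMethod("show", "SyntheticScene", function(object) {
    cat(sprintf("SyntheticScene (seed %d): %d channel(s) in %.6g x %.6g um\n",
                as.integer(object@seed), length(object@channels),
                object@roi@widthUm, object@roi@heightUm))
    for (ch in object@channels)
        cat(sprintf("  %-10s %6d puncta\n", channelName(ch), nPuncta(ch)))
    cat(sprintf("  planted granules: %d\n",
                length(unique(stats::na.omit(object@truth$granule_id)))))
})

#' Render a scene to per-channel images with matched negative controls
#'
#' Each punctum is drawn as a disc of its area carrying its total intensity
#' (split evenly over member pixels), optionally blurred with a Gaussian
#' point-spread function, on a constant background with additive Gaussian
#' noise.  The negative control is background plus noise only, with the same
#' parameters -- emulating the no-probe control used to calibrate
#' segmentation thresholds.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param psfSigmaUm Gaussian PSF sigma in micrometres (0 disables blur).
#' @param background constant background level (a.u.).
#' @param noiseSd additive Gaussian noise sd (a.u.).
#' @param seed integer seed for the noise draws.
#' @return list with named lists \code{images} and \code{negatives} of
#'   intensity matrices.
#' @export
renderImages <- function(scene, psfSigmaUm = 0.05, background = 100,
                         noiseSd = 10, seed = 1) {
    stopifnot(psfSigmaUm >= 0)
    roi <- scene@roi
    d <- gridDim(roi)
    .withSeed(seed, {
        images <- list(); negatives <- list()
        for (ch in scene@channels) {
            img <- matrix(0, d[1], d[2])
            p <- punctaTable(ch)
            for (i in seq_len(nrow(p))) {
                dia <- 2 * sqrt(p$area_um2[i] / pi)
                px <- discPixels(c(p$x_um[i], p$y_um[i]), dia, roi)
                idx <- px[, c("row", "col"), drop = FALSE] + 1L
                img[idx] <- img[idx] + p$total_intensity[i] / nrow(px)
            }
            if (psfSigmaUm > 0)
                img <- as.matrix(EBImage::gblur(
                    img, sigma = psfSigmaUm * roi@pixelScale))
            img <- img + background +
                stats::rnorm(length(img), 0, noiseSd)
            neg <- background + matrix(stats::rnorm(length(img), 0, noiseSd),
                                       d[1], d[2])
            images[[channelName(ch)]] <- img
            negatives[[channelName(ch)]] <- neg
        }
        list(images = images, negatives = negatives,
             psfSigmaUm = psfSigmaUm, background = background,
             noiseSd = noiseSd)
    })
}

#' Construct a probe-dilution specification
#'
#' @param labeledFractions dilution series (e.g. \code{c(1, .5, .25, .125)}).
#' @param perTranscriptIntensity fluorescence per labeled transcript (a.u.).
#' @param detectionThreshold minimum punctum fluorescence for detection.
#' @param copyNumber,copyNumberProb transcript copy-number distribution.
#' @return a \code{\linkS4class{DilutionSpec}}.
#' @export
dilutionSpec <- function(labeledFractions = c(1, 0.5, 0.25, 0.125),
                         perTranscriptIntensity = 100,
                         detectionThreshold = 100,
                         copyNumber = 1L, copyNumberProb = NULL) {
    if (is.null(copyNumberProb))
        copyNumberProb <- rep(1 / length(copyNumber), length(copyNumber))
    new("DilutionSpec", labeledFractions = labeledFractions,
        perTranscriptIntensity = perTranscriptIntensity,
        detectionThreshold = detectionThreshold,
        copyNumber = as.integer(copyNumber),
        copyNumberProb = copyNumberProb / sum(copyNumberProb))
}

#' Simulate a serial probe-dilution experiment
#'
#' Each punctum draws a transcript copy number from the population; at each
#' dilution its labeled copies are Binomial(copies, labeledFraction) and the
#' punctum is detected when labeled copies times the per-transcript
#' intensity reach the detection threshold.  Apparent diameter is a fixed
#' monotone (cube-root) map of detected intensity, so single-copy
#' populations lose count while keeping intensity, and high-copy
#' populations keep count while losing intensity -- the two diagnostic
#' branches of the dilution logic.
#'
#' @param spec a \code{\linkS4class{DilutionSpec}}.
#' @param nPuncta number of puncta to simulate (> 0).
#' @param seed integer seed.
#' @return data.frame with one row per dilution: \code{labeled_fraction},
#'   \code{detected_count}, \code{detected_fraction},
#'   \code{mean_intensity} and \code{mean_apparent_diameter_um} of detected
#'   puncta.
#' @export
simulateDilution <- function(spec, nPuncta, seed = 1) {
    stopifnot(nPuncta > 0)
    .withSeed(seed, {
        copies <- spec@copyNumber[sample.int(length(spec@copyNumber),
                                             nPuncta, replace = TRUE,
                                             prob = spec@copyNumberProb)]
        res <- lapply(spec@labeledFractions, function(f) {
            labeled <- stats::rbinom(nPuncta, copies, f)
            intensity <- labeled * spec@perTranscriptIntensity
            det <- intensity >= spec@detectionThreshold
            data.frame(
                labeled_fraction = f,
                detected_count = sum(det),
                detected_fraction = mean(det),
                mean_intensity = if (any(det)) mean(intensity[det])
                                 else NA_real_,
                mean_apparent_diameter_um = if (any(det))
                    mean(0.2 * (intensity[det] /
                                spec@perTranscriptIntensity)^(1 / 3))
                    else NA_real_)
        })
        do.call(rbind, res)
    })
}
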