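#' @import methods
NULL

#' Physical region-of-interest specification
#'
#' An ROI is a rectangle of physical extent \code{widthUm} x \code{heightUm}
#' micrometres, discretised on a pixel grid at \code{pixelScale} pixels per
#' micrometre (default 9.6679, the scale of the 63x acquisitions this package
#' was designed around).  The pixel grid has
#' \code{round(heightUm * pixelScale)} rows and
#' \code{round(widthUm * pixelScale)} columns; pixel \code{(row, col)} is
#' 0-based and covers the half-open square
#' \code{[col/s, (col+1)/s) x [row/s, (row+1)/s)} with \code{s = pixelScale}.
#' The continuous coordinate origin is the ROI top-left corner, x rightward,
#' y downward.
#'
#' @slot widthUm,heightUm physical extent in micrometres.
#' @slot pixelScale pixels per micrometre.
#' @export
setClass("RoiSpec", representation(
    widthUm = "numeric", heightUm = "numeric", pixelScale = "numeric"))

setValidity("RoiSpec", function(object) {
    if (length(object@widthUm) != 1 || length(object@heightUm) != 1 ||
        length(object@pixelScale) != 1)
        return("widthUm, heightUm, pixelScale must be scalar")
    if (!all(c(object@widthUm, object@heightUm, object@pixelScale) > 0))
        return("widthUm, heightUm and pixelScale must be positive")
    TRUE
})

#' A set of segmented puncta from one channel in one ROI
#'
#' The central container: all puncta of one RNA channel in one ROI.  Per-
#' punctum geometry and intensity live in a data.frame (one row per punctum)
#' with columns \code{id}, \code{x_um}, \code{y_um}, \code{area_um2},
#' \code{feret_um}, \code{total_intensity}, \code{mean_intensity}.  When the
#' puncta were segmented from an image, \code{pixels} holds one integer
#' matrix per punctum (columns \code{row}, \code{col}, 0-based grid
#' coordinates); puncta loaded from coordinate tables have an empty
#' \code{pixels} list and are materialised as discs of their Feret diameter
#' on demand (see \code{\link{materializePixels}}).
#'
#' @slot channel channel label.
#' @slot roi a \code{\linkS4class{RoiSpec}}.
#' @slot puncta data.frame of per-punctum measurements.
#' @slot pixels list of integer matrices (may be empty).
#' @slot provenance free-text origin (segmentation parameters or
#'   \code{"external table"}).
#' @export
setClass("PunctaSet", representation(
    channel = "character", roi = "RoiSpec", puncta = "data.frame",
    pixels = "list", provenance = "character"))

.punctaCols <- c("id", "x_um", "y_um", "area_um2", "feret_um",
                 "total_intensity", "mean_intensity")

setValidity("PunctaSet", function(object) {
    p <- object@puncta
    if (!all(.punctaCols %in% names(p)))
        return(paste("puncta must contain columns:",
                     paste(.punctaCols, collapse = ", ")))
    if (anyDuplicated(p$id)) return("punctum ids must be unique")
    if (nrow(p) > 0) {
        if (any(p$area_um2 <= 0)) return("area must be positive")
        r <- object@roi
        if (any(p$x_um < 0 | p$x_um > r@widthUm |
                p$y_um < 0 | p$y_um > r@heightUm))
            return("all centroids must lie inside the ROI")
    }
    if (length(object@pixels) > 0 && length(object@pixels) != nrow(p))
        return("pixels list must be empty or parallel to the puncta table")
    TRUE
})

#' Binary mask on an ROI pixel grid
#'
#' @slot grid logical matrix with \code{gridDim(roi)} dimensions.
#' @slot roi a \code{\linkS4class{RoiSpec}}.
#' @export
setClass("BinaryMask", representation(grid = "matrix", roi = "RoiSpec"))

setValidity("BinaryMask", function(object) {
    d <- gridDim(object@roi)
    if (!is.logical(object@grid)) return("grid must be logical")
    if (!all(dim(object@grid) == d))
        return(sprintf("grid must be %d x %d for this ROI", d[1], d[2]))
    TRUE
})

#' Spatial overlap criterion for object-based colocalization
#'
#' Two definitions of colocalization are supported.  In \code{pixel} mode a
#' reference punctum is colocalized when its pixel footprint shares at least
#' \code{minPixels} pixels (default 1) with any target punctum.  In
#' \code{centroid} mode it is colocalized when some target punctum lies at a
#' centroid-to-centroid distance strictly less than
#' \code{fraction * (feretRef + feretTarget) / 2}; \code{fraction = 0.99}
#' corresponds to the lenient ">1 percent overlap" definition and
#' \code{fraction = 0.50} to the stringent ">50 percent overlap" definition.
#'
#' @slot mode \code{"pixel"} or \code{"centroid"}.
#' @slot fraction multiplier on the summed radii (centroid mode).
#' @slot minPixels minimum shared pixels (pixel mode).
#' @export
setClass("OverlapCriterion", representation(
    mode = "character", fraction = "numeric", minPixels = "integer"))

setValidity("OverlapCriterion", function(object) {
    if (!object@mode %in% c("pixel", "centroid"))
        return("mode must be 'pixel' or 'centroid'")
    if (object@fraction <= 0 || object@fraction > 1)
        return("fraction must be in (0, 1]")
    if (object@minPixels < 1L) return("minPixels must be >= 1")
    TRUE
})

#' Reference-by-target colocalization matrix
#'
#' \code{counts[ref, tgt]} is the number of reference-channel puncta
#' colocalized with at least one target-channel punctum; the matrix need not
#' be symmetric.  \code{totals} holds per-channel puncta counts.  Percentages
#' under the requested normalization are computed by
#' \code{\link{colocPercent}}: \code{percent_of_reference} divides each row
#' by the reference channel total; \code{percent_of_pair} is the symmetric
#' normalization by the combined count of the two channels.
#'
#' @slot channels ordered channel labels.
#' @slot counts integer matrix, reference rows by target columns (NA diagonal).
#' @slot totals named per-channel puncta counts.
#' @slot normalization \code{"percent_of_reference"} or
#'   \code{"percent_of_pair"}.
#' @export
setClass("ColocalizationMatrix", representation(
    channels = "character", counts = "matrix", totals = "numeric",
    normalization = "character"))

setValidity("ColocalizationMatrix", function(object) {
    k <- length(object@channels)
    if (!all(dim(object@counts) == c(k, k)))
        return("counts must be a square channels x channels matrix")
    if (length(object@totals) != k) return("one total per channel required")
    if (!object@normalization %in% c("percent_of_reference",
                                     "percent_of_pair"))
        return("unknown normalization")
    cnt <- object@counts
    tot <- object@totals
    bad <- which(!is.na(cnt) & (cnt < 0 | cnt > tot[row(cnt)]))
    if (length(bad)) return("counts must satisfy 0 <= count <= totals[ref]")
    TRUE
})

#' Rotation-based random-colocalization null
#'
#' Holds the experimental matrix, the random matrix obtained after rotating
#' the reference channel of each cell about the ROI centre, and their
#' cell-wise difference.  Negative subtracted cells are retained (clipping
#' would bias averages across replicates).
#'
#' @slot angle rotation angle in degrees (90 or 180).
#' @slot experimental,random,subtracted percentage matrices
#'   (channels x channels, NA diagonal).
#' @slot normalization the normalization both matrices were computed under.
#' @export
setClass("RotationNull", representation(
    angle = "numeric", experimental = "matrix", random = "matrix",
    subtracted = "matrix", normalization = "character"))

#' Singleton/dimer/multimer composition of a focal channel
#'
#' Every focal punctum falls in exactly one category: \code{singleton}
#' (no colocalized partner channel), \code{dimer_<P>} (exactly one partner
#' channel, P), \code{multimer_with_special} (two or more partner channels
#' including the special partner) or \code{multimer_without_special}.
#' Fractions are percentages of the focal puncta and sum to 100.
#'
#' @slot focal focal channel label.
#' @slot partners partner panel labels.
#' @slot special the distinguished partner (e.g. the most abundant mRNA).
#' @slot fractions named percentages summing to 100.
#' @slot counts named integer counts in the same order.
#' @slot nFocal number of focal puncta.
#' @export
setClass("CompositionSummary", representation(
    focal = "character", partners = "character", special = "character",
    fractions = "numeric", counts = "numeric", nFocal = "numeric"))

setValidity("CompositionSummary", function(object) {
    if (object@nFocal > 0 && abs(sum(object@fractions) - 100) > 0.01)
        return("fractions must sum to 100")
    if (!identical(names(object@fractions), names(object@counts)))
        return("fractions and counts must be parallel")
    TRUE
})

#' Negative-control calibrated segmentation threshold
#'
#' @slot channel channel label.
#' @slot threshold calibrated intensity threshold (a.u.).
#' @slot negControlFraction puncta detected on the negative control divided
#'   by puncta detected on the experimental image at this threshold.
#' @slot maxAllowed the target bound the calibration satisfied.
#' @export
setClass("ThresholdCalibration", representation(
    channel = "character", threshold = "numeric",
    negControlFraction = "numeric", maxAllowed = "numeric"))

#' Per-channel generator specification
#'
#' @slot name channel label.
#' @slot expectedCount mean puncta per ROI (Poisson mean).
#' @slot sizeClass one of \code{"small"}, \code{"small_broad"},
#'   \code{"large_broad"}, \code{"large"}, or \code{"custom"}.
#' @slot areaMeanlog,areaSdlog log-normal parameters for punctum area
#'   (square micrometres); filled from the size class unless custom.
#' @slot copyNumber integer vector of transcripts-per-punctum outcomes.
#' @slot copyNumberProb matching probabilities.
#' @export
setClass("ChannelSpec", representation(
    name = "character", expectedCount = "numeric", sizeClass = "character",
    areaMeanlog = "numeric", areaSdlog = "numeric",
    copyNumber = "integer", copyNumberProb = "numeric"))

#' Planted heterotypic colocalization plan
#'
#' Ground truth for validating the colocalization estimators: a fraction of
#' channel-A puncta is co-placed within \code{jitterUm} of a distinct
#' channel-B partner punctum.
#'
#' @slot channelA,channelB the pair of channels.
#' @slot plantedFraction fraction of channel-A puncta to co-place.
#' @slot jitterUm placement offset scale in micrometres.
#' @export
setClass("GranulePlan", representation(
    channelA = "character", channelB = "character",
    plantedFraction = "numeric", jitterUm = "numeric"))

setValidity("GranulePlan", function(object) {
    if (object@plantedFraction < 0 || object@plantedFraction > 1)
        return("plantedFraction must be in [0, 1]")
    TRUE
})

#' A generated multi-channel puncta scene with ground truth
#'
#' @slot roi the shared \code{\linkS4class{RoiSpec}}.
#' @slot channels named list of \code{\linkS4class{PunctaSet}}.
#' @slot truth data.frame with one row per punctum: \code{channel},
#'   \code{id}, \code{size_class}, \code{copy_number}, \code{granule_id}.
#' @slot nuclei \code{\linkS4class{BinaryMask}} of nuclear exclusion zones.
#' @slot seed the seed the scene was generated from.
#' @export
setClass("SyntheticScene", representation(
    roi = "RoiSpec", channels = "list", truth = "data.frame",
    nuclei = "BinaryMask", seed = "numeric"))

#' Probe-dilution experiment specification
#'
#' Models serial dilution of a labeled probe with unlabeled probe: each
#' transcript in a punctum carries label with probability
#' \code{labeledFraction}; a punctum is detected when its labeled-copy
#' fluorescence reaches the detection threshold.
#'
#' @slot labeledFractions dilution series, each in (0, 1].
#' @slot perTranscriptIntensity fluorescence per labeled transcript (a.u.).
#' @slot detectionThreshold minimum punctum intensity for detection (a.u.).
#' @slot copyNumber,copyNumberProb transcript copy-number distribution of
#'   the punctum population.
#' @export
setClass("DilutionSpec", representation(
    labeledFractions = "numeric", perTranscriptIntensity = "numeric",
    detectionThreshold = "numeric", copyNumber = "integer",
    copyNumberProb = "numeric"))

setValidity("DilutionSpec", function(object) {
    if (any(object@labeledFractions <= 0 | object@labeledFractions > 1))
        return("labeledFractions must be in (0, 1]")
    if (object@detectionThreshold < 0)
        return("detectionThreshold must be >= 0")
    TRUE
})
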