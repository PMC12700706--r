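#' Rotate a PunctaSet about the ROI centre
#'
#' Estimates of chance colocalization are obtained by rotating one channel
#' about the ROI centre and re-measuring overlap.  Rotation acts on
#' coordinates (and pixel sets when present), not on rendered images, so
#' the null is equally available for coordinate-table input; areas, Feret
#' diameters and intensities are unchanged.  "90 degrees" means clockwise
#' in image coordinates, \code{(x, y) -> (W - y, x)}, and requires a square
#' ROI; 180 degrees, \code{(x, y) -> (W - x, H - y)}, works for any ROI and
#' is an involution.
#'
#' @param x a \code{\linkS4class{PunctaSet}}.
#' @param angle 90 or 180 (degrees).
#' @return the rotated \code{\linkS4class{PunctaSet}}.
#' @rdname rotatePuncta
#' @export
setMethod("rotatePuncta", "PunctaSet", function(x, angle) {
    if (!angle %in% c(90, 180)) stop("angle must be 90 or 180")
    roi <- x@roi
    if (angle == 90 && !isTRUE(all.equal(roi@widthUm, roi@heightUm)))
        stop("90 degree rotation requires a square ROI")
    p <- x@puncta
    d <- gridDim(roi)
    if (angle == 180) {
        nx <- roi@widthUm - p$x_um
        ny <- roi@heightUm - p$y_um
        rot <- function(px) cbind(row = d[1] - 1L - px[, "row"],
                                  col = d[2] - 1L - px[, "col"])
    } else {
        nx <- roi@widthUm - p$y_um
        ny <- p$x_um
        rot <- function(px) cbind(row = px[, "col"],
                                  col = d[1] - 1L - px[, "row"])
    }
    p$x_um <- pmin(pmax(nx, 0), roi@widthUm)
    p$y_um <- pmin(pmax(ny, 0), roi@heightUm)
    px <- if (length(x@pixels)) lapply(x@pixels, rot) else list()
    punctaSet(x@channel, roi, p, px,
              paste0(x@provenance, sprintf("; rotated %d deg", angle)))
})

#' Random (chance) colocalization percentage by rotation
#'
#' Colocalization of the rotated reference channel against the unrotated
#' target, under the stated criterion and normalization.  On a spatially
#' uniform point pattern rotation preserves the process, so the random
#' percentage matches the experimental one in expectation; structured
#' scenes give the chance level that experimental percentages are compared
#' against.
#'
#' @param A reference \code{\linkS4class{PunctaSet}} (this one is rotated).
#' @param B target \code{\linkS4class{PunctaSet}}.
#' @param crit an \code{\linkS4class{OverlapCriterion}}.
#' @param angle 90 or 180 degrees.
#' @param normalization \code{"percent_of_reference"} or
#'   \code{"percent_of_pair"}.
#' @return percentage, or NA where undefined.
#' @export
randomPercent <- function(A, B, crit = overlapCriterion(), angle = 90,
                          normalization = c("percent_of_reference",
                                            "percent_of_pair")) {
    normalization <- match.arg(normalization)
    Ar <- rotatePuncta(A, angle)
    if (normalization == "percent_of_reference") percentOfReference(Ar, B, crit)
    else percentOfPair(Ar, B, crit)
}

#' Experimental, random and random-subtracted colocalization matrices
#'
#' Computes the pairwise experimental percentage matrix, the random matrix
#' in which the reference channel of each cell is rotated about the ROI
#' centre before re-measuring, and their cell-wise difference.  Negative
#' subtracted cells are reported as-is with a warning; clipping them would
#' bias averages across replicates.
#'
#' @inheritParams pairwiseMatrix
#' @param angle 90 or 180 degrees.
#' @return a \code{\linkS4class{RotationNull}}.
#' @export
randomSubtractedMatrix <- function(sets, crit = overlapCriterion(),
                                   angle = 90,
                                   normalization = c("percent_of_reference",
                                                     "percent_of_pair")) {
    normalization <- match.arg(normalization)
    if (length(sets) < 2) stop("need at least 2 channels")
    nms <- vapply(sets, channelName, character(1))
    if (anyDuplicated(nms)) stop("duplicated channel labels")
    names(sets) <- nms
    exp <- colocPercent(pairwiseMatrix(sets, crit, normalization))
    rotated <- lapply(sets, rotatePuncta, angle = angle)
    k <- length(sets)
    rnd <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        rnd[i, j] <- if (normalization == "percent_of_reference")
            percentOfReference(rotated[[i]], sets[[j]], crit)
        else percentOfPair(rotated[[i]], sets[[j]], crit)
    }
    sub <- exp - rnd
    if (any(sub < 0, na.rm = TRUE))
        warning("some random-subtracted cells are negative; ",
                "they are reported unclipped")
    new("RotationNull", angle = angle, experimental = exp, random = rnd,
        subtracted = sub, normalization = normalization)
}

setMethod("show", "RotationNull", function(object) {
    cat(sprintf("RotationNull: %d degree rotation, %s\n",
                as.integer(object@angle), object@normalization))
    cat("random-subtracted percentages:\n")
    print(round(object@subtracted, 1))
})
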