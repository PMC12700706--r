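#' Read a puncta coordinate table
#'
#' Reads the package CSV dialect: header
#' \code{channel,id,x_um,y_um,area_um2,feret_um,total_intensity,mean_intensity},
#' one row per punctum, UTF-8, "." decimal.  A single file may carry several
#' channels; one \code{\linkS4class{PunctaSet}} is returned per channel.
#'
#' Coordinate units are sniffed: if the largest coordinate exceeds the ROI
#' extent in micrometres the table is taken to be in pixels and converted
#' (areas by the squared scale); the decision is recorded in the set's
#' provenance.
#'
#' @param path CSV file path.
#' @param roi the \code{\linkS4class{RoiSpec}} the coordinates live in.
#' @return named list of \code{\linkS4class{PunctaSet}} objects.
#' @seealso \code{\link{writePunctaCsv}}
#' @export
readPunctaCsv <- function(path, roi) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("channel", .punctaCols)
    if (!all(need %in% names(df)))
        stop("puncta CSV must have columns: ", paste(need, collapse = ", "))
    unit <- "um"
    if (nrow(df) > 0 &&
        max(df$x_um, df$y_um, na.rm = TRUE) > max(roi@widthUm, roi@heightUm)) {
        s <- roi@pixelScale
        df$x_um <- df$x_um / s
        df$y_um <- df$y_um / s
        df$area_um2 <- df$area_um2 / s^2
        df$feret_um <- df$feret_um / s
        unit <- "pixel (converted to um)"
    }
    out <- lapply(split(df, df$channel), function(d)
        punctaSet(d$channel[1], roi, d[.punctaCols],
                  provenance = sprintf("external table '%s'; units: %s",
                                       basename(path), unit)))
    out[unique(df$channel)]
}

#' Write puncta sets to the package CSV dialect
#'
#' @param sets a \code{\linkS4class{PunctaSet}} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePunctaCsv <- function(sets, path) {
    if (is(sets, "PunctaSet")) sets <- list(sets)
    rows <- lapply(sets, function(s)
        cbind(channel = rep(channelName(s), nPuncta(s)), punctaTable(s)))
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a scene's ground truth to CSV
#'
#' Columns: \code{channel,id,size_class,copy_number,granule_id}.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param path output CSV path.
#' @export
writeTruthCsv <- function(scene, path) {
    utils::write.csv(scene@truth, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a single-channel TIFF image
#'
#' Accepts 8/16-bit single-channel TIFFs and returns the intensity matrix on
#' the stored integer scale.  Multi-page stacks are rejected with a pointer
#' to \code{\link{maxProject}}; RGB images are rejected.
#'
#' @param path TIFF file path.
#' @return numeric matrix of pixel intensities.
#' @export
readImageTiff <- function(path) {
    img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(img) > 1)
        stop("multi-page TIFF: read pages individually and combine with ",
             "maxProject()")
    img <- img[[1]]
    if (length(dim(img)) != 2)
        stop("expected a single-channel image; got an array with ",
             length(dim(img)), " dimensions (RGB TIFFs are not supported)")
    img
}

#' Write a matrix as a 16-bit single-channel TIFF
#'
#' Values are stored as 16-bit integers; values outside [0, 65535] are
#' clipped.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @export
writeImageTiff <- function(img, path) {
    img <- pmin(pmax(round(img), 0), 65535)
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    invisible(path)
}

#' Maximum-intensity projection of an image stack
#'
#' @param stack list of numeric matrices with identical dimensions.
#' @return per-pixel maximum across planes.
#' @export
maxProject <- function(stack) {
    if (!is.list(stack) || length(stack) < 1)
        stop("stack must be a non-empty list of matrices")
    d <- dim(stack[[1]])
    if (!all(vapply(stack, function(p) identical(dim(p), d), logical(1))))
        stop("ragged stack: all planes must share dimensions")
    Reduce(pmax, stack)
}
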