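## Shared fixtures: all built in code, no files.

## A channel of n puncta with fixed Feret diameter, uniform over the ROI.
uniformSet <- function(channel, n, roi, feret = 0.4, seed = 1) {
    set.seed(seed)
    punctaSet(channel, roi, data.frame(
        id = seq_len(n),
        x_um = runif(n, 0, roi@widthUm), y_um = runif(n, 0, roi@heightUm),
        area_um2 = pi * (feret / 2)^2, feret_um = feret,
        total_intensity = 100, mean_intensity = 10))
}

## A tiny set at explicit coordinates (one row per punctum).
pointSet <- function(channel, roi, x, y, feret = 0.4) {
    punctaSet(channel, roi, data.frame(
        id = seq_along(x), x_um = x, y_um = y,
        area_um2 = pi * (feret / 2)^2, feret_um = feret,
        total_intensity = 100, mean_intensity = 10))
}

## Closed-form chance that a reference punctum with radius rA colocalizes
## (centroid rule, factor f) with >= 1 of nB uniform target puncta of
## radius rB in an ROI of area S.
closedFormColoc <- function(f, rA, rB, nB, S) {
    1 - (1 - pi * (f * (rA + rB))^2 / S)^nB
}

## Greedy nearest-centroid matching of segmented puncta to ground truth.
matchDetections <- function(truthSet, segSet, maxDistUm = 0.3) {
    pt <- punctaTable(truthSet); ps <- punctaTable(segSet)
    if (nrow(ps) == 0 || nrow(pt) == 0)
        return(list(f1 = 0, matches = integer(0)))
    d <- outer(pt$x_um, ps$x_um, `-`)^2 + outer(pt$y_um, ps$y_um, `-`)^2
    d <- sqrt(d)
    j <- apply(d, 1, which.min)
    dm <- d[cbind(seq_len(nrow(pt)), j)]
    ok <- dm <= maxDistUm
    tp <- sum(ok)
    list(f1 = 2 * tp / (nrow(pt) + nrow(ps)),
         truthIdx = which(ok), segIdx = j[ok])
}

## Render one channel at a given signal-to-noise ratio (median per-pixel
## punctum amplitude over the noise sd) and return scene + images.
renderedSceneSNR <- function(n = 100, roiUm = 52, snr = 10, seed = 1) {
    roi <- roiSpec(roiUm, roiUm)
    sc <- generateScene(
        list(channelSpec("A", n, areaMeanlog = log(0.25), areaSdlog = 0.25)),
        roi, seed = seed, perTranscriptIntensity = 20000)
    p <- punctaTable(sc@channels$A)
    amp <- median(p$total_intensity /
                  pmax(1, round(p$area_um2 * roi@pixelScale^2)))
    r <- renderImages(sc, psfSigmaUm = 0.03, background = 100,
                      noiseSd = amp / snr, seed = seed + 1)
    list(scene = sc, roi = roi, images = r$images, negatives = r$negatives,
         amplitude = amp)
}
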