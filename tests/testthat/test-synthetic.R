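test_that("scene counts are Poisson around the specified abundances", {
    ## abundances of the most and least abundant channels in a 211 um ROI
    roi <- roiSpec(211, 211)
    sc <- generateScene(list(channelSpec("Camk2a", 12829, "small_broad"),
                             channelSpec("Ppfia3", 1162, "large")),
                        roi, seed = 42)
    expect_lt(abs(nPuncta(sc@channels$Camk2a) - 12829), 3 * sqrt(12829))
    expect_lt(abs(nPuncta(sc@channels$Ppfia3) - 1162), 3 * sqrt(1162))
    ## truth covers every punctum exactly once
    expect_equal(nrow(sc@truth),
                 nPuncta(sc@channels$Camk2a) + nPuncta(sc@channels$Ppfia3))
    ## zero expected count -> empty scene
    sc0 <- generateScene(list(channelSpec("A", 0)), roiSpec(52, 52), seed = 1)
    expect_equal(nPuncta(sc0@channels$A), 0L)
})

test_that("planted pairs satisfy both overlap criteria by construction", {
    roi <- roiSpec(52, 52)
    sc <- generateScene(list(channelSpec("A", 60, "small"),
                             channelSpec("B", 120, "small")),
                        roi, plans = list(granulePlan("A", "B", 1,
                                                      jitterUm = 0)),
                        seed = 3)
    for (crit in list(overlapCriterion("centroid", 0.5),
                      overlapCriterion("pixel"))) {
        expect_equal(percentOfReference(sc@channels$A, sc@channels$B, crit),
                     100)
    }
    ## default jitter still passes the stringent criterion
    sc2 <- generateScene(list(channelSpec("A", 60, "small"),
                              channelSpec("B", 120, "small")),
                         roi, plans = list(granulePlan("A", "B", 0.5)),
                         seed = 4)
    planted <- !is.na(subset(sc2@truth, channel == "A")$granule_id)
    ids <- colocalizedReferenceIds(sc2@channels$A, sc2@channels$B,
                                   overlapCriterion("centroid", 0.5))
    expect_true(all(punctaTable(sc2@channels$A)$id[planted] %in% ids))
    ## demanding more partners than the target channel has is an error
    expect_error(
        generateScene(list(channelSpec("A", 200, "small"),
                           channelSpec("B", 5, "small")),
                      roi, plans = list(granulePlan("A", "B", 1)), seed = 5),
        "partners")
})

test_that("scenes exclude nuclei and are reproducible under a seed", {
    roi <- roiSpec(52, 52)
    sc1 <- generateScene(list(channelSpec("A", 300, "small")), roi,
                         nucleiCount = 5, seed = 9)
    sc2 <- generateScene(list(channelSpec("A", 300, "small")), roi,
                         nucleiCount = 5, seed = 9)
    expect_identical(punctaTable(sc1@channels$A), punctaTable(sc2@channels$A))
    expect_identical(sc1@nuclei@grid, sc2@nuclei@grid)
    ## no centroid falls on a nuclear pixel
    p <- punctaTable(sc1@channels$A)
    s <- roi@pixelScale
    rr <- pmin(floor(p$y_um * s), nrow(sc1@nuclei@grid) - 1) + 1
    cc <- pmin(floor(p$x_um * s), ncol(sc1@nuclei@grid) - 1) + 1
    expect_false(any(sc1@nuclei@grid[cbind(rr, cc)]))
})

test_that("size-class area draws land in the expected histogram regions", {
    set.seed(21)
    p <- sizeClassParams("small")
    draws <- rlnorm(5000, p["meanlog"], p["sdlog"])
    h <- relativeHistogram(draws)
    ## small cluster: peak bin at 0.2 um2 (bins labeled by upper edge),
    ## carrying roughly a quarter of the mass
    peakBin <- which.max(h$percent)
    expect_equal(h$bin_hi[peakBin], 0.2)
    expect_gt(h$percent[peakBin], 20)
    expect_lt(h$percent[peakBin], 35)
    expect_lt(h$percent[h$bin_lo == 1], 6) # thin >1 um2 tail
    pb <- sizeClassParams("small_broad")
    tail_broad <- mean(rlnorm(5000, pb["meanlog"], pb["sdlog"]) > 1)
    expect_gt(tail_broad, 0.05)            # broad class has a heavy tail
})

test_that("rendered images honour footprints and negative controls", {
    roi <- roiSpec(10, 10)
    p <- data.frame(id = 1L, x_um = 5, y_um = 5, area_um2 = 0.5,
                    feret_um = 0.8, total_intensity = 5000,
                    mean_intensity = 100)
    sc <- new("SyntheticScene", roi = roi,
              channels = list(A = punctaSet("A", roi, p)),
              truth = data.frame(channel = "A", id = 1L, size_class = "x",
                                 copy_number = 1L, granule_id = NA_integer_),
              nuclei = binaryMask(matrix(FALSE, gridDim(roi)[1],
                                         gridDim(roi)[2]), roi),
              seed = 1)
    ## no noise, no blur: suprathreshold pixel count equals the footprint
    r <- renderImages(sc, psfSigmaUm = 0, background = 10, noiseSd = 0,
                      seed = 1)
    dia <- 2 * sqrt(0.5 / pi)
    expect_equal(sum(r$images$A > 10),
                 nrow(discPixels(c(5, 5), dia, roi)))
    expect_true(all(r$negatives$A == 10))
    ## an empty scene is statistically identical to its negative control
    sc0 <- generateScene(list(channelSpec("A", 0)), roi, seed = 1)
    r0 <- renderImages(sc0, psfSigmaUm = 0, background = 100, noiseSd = 10,
                       seed = 2)
    expect_gt(stats::ks.test(r0$images$A, r0$negatives$A)$p.value, 0.01)
})

test_that("dilution reproduces the two copy-number branches", {
    n <- 4000
    ## single-copy population: count halves, intensity invariant
    d1 <- simulateDilution(dilutionSpec(labeledFractions = c(1, 0.5),
                                        copyNumber = 1L), n, seed = 2)
    se <- sqrt(0.5 * 0.5 / n)
    expect_lt(abs(d1$detected_fraction[2] - 0.5), 3 * se)
    expect_equal(d1$mean_intensity[2], d1$mean_intensity[1])
    ## labeled fraction 1 is the undiluted identity for any population
    dI <- simulateDilution(dilutionSpec(labeledFractions = 1,
                                        copyNumber = c(1L, 4L, 8L)), n,
                           seed = 3)
    expect_equal(dI$detected_fraction, 1)
    ## eight-copy population: count invariant, intensity halves
    d8 <- simulateDilution(dilutionSpec(labeledFractions = c(1, 0.5),
                                        copyNumber = 8L), n, seed = 4)
    pDet <- 1 - 0.5^8
    expect_lt(abs(d8$detected_fraction[2] - pDet),
              3 * sqrt(pDet * (1 - pDet) / n))
    ratio <- d8$mean_intensity[2] / d8$mean_intensity[1]
    expect_lt(abs(ratio - 0.5), 3 * sqrt(8 * 0.25) * 100 /
                  (sqrt(n) * d8$mean_intensity[1]))
    ## apparent diameter shrinks monotonically with dilution
    dd <- simulateDilution(dilutionSpec(copyNumber = 8L), n, seed = 5)
    expect_true(all(diff(dd$mean_apparent_diameter_um) < 0))
})

test_that("detected count is linear in labeled fraction for single copies", {
    n <- 3000
    fr <- c(1, 0.5, 0.25, 0.125)
    d <- simulateDilution(dilutionSpec(labeledFractions = fr,
                                       copyNumber = 1L), n, seed = 6)
    fit <- lm(d$detected_fraction ~ fr)
    expect_gt(summary(fit)$r.squared, 0.99)
    expect_lt(abs(coef(fit)[2] - 1), 0.05)
})
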