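## A hand-built configuration covering every category: focal puncta on a
## line, partners placed to force known partner sets.
toyComposition <- function() {
    roi <- roiSpec(20, 20)
    f <- pointSet("F", roi, x = c(2, 6, 10, 14, 18), y = rep(10, 5))
    S <- pointSet("S", roi, x = c(2, 10), y = c(10, 10))     # special
    P1 <- pointSet("P1", roi, x = c(6, 10, 14), y = rep(10, 3))
    P2 <- pointSet("P2", roi, x = 14, y = 10)
    list(roi = roi, f = f, partners = list(S, P1, P2))
}

test_that("composition classification matches manual enumeration", {
    t <- toyComposition()
    crit <- overlapCriterion("centroid", 0.99)
    r <- classifyComposition(t$f, t$partners, "S", crit)
    expect_equal(r$perPunctum$category,
                 c("dimer_S", "dimer_P1", "multimer_with_special",
                   "multimer_without_special", "singleton"))
    fr <- compositionFractions(r$summary)
    expect_equal(sum(fr), 100)
    expect_equal(unname(fr[c("singleton", "dimer_S", "dimer_P1",
                             "multimer_with_special",
                             "multimer_without_special")]),
                 rep(20, 5))
    expect_equal(unname(fr["dimer_P2"]), 0)
    ## every focal punctum in exactly one category
    expect_equal(sum(r$summary@counts), nPuncta(t$f))
    ## empty focal set -> missing summary
    r0 <- classifyComposition(t$f[0], t$partners, "S", crit)
    expect_true(all(is.na(compositionFractions(r0$summary))))
    expect_error(classifyComposition(t$f, t$partners, "missing", crit),
                 "not in the panel")
})

test_that("no overlapping partner means 100% singleton", {
    roi <- roiSpec(20, 20)
    f <- pointSet("F", roi, x = c(5, 15), y = c(5, 15))
    far <- pointSet("P", roi, x = 10, y = 2)
    r <- classifyComposition(f, list(far), "P",
                             overlapCriterion("centroid", 0.99))
    expect_equal(unname(compositionFractions(r$summary)["singleton"]), 100)
})

test_that("shrinking the partner panel only moves puncta to fewer partners", {
    roi <- roiSpec(52, 52)
    sc <- generateScene(list(channelSpec("F", 150, "small"),
                             channelSpec("S", 300, "small"),
                             channelSpec("P", 300, "small")),
                        roi, plans = list(granulePlan("F", "S", 0.3),
                                          granulePlan("F", "P", 0.3)),
                        seed = 12)
    crit <- overlapCriterion("centroid", 0.99)
    full <- classifyComposition(sc@channels$F,
                                sc@channels[c("S", "P")], "S", crit)
    red <- classifyComposition(sc@channels$F,
                               sc@channels["S"], "S", crit)
    expect_gte(compositionFractions(red$summary)["singleton"],
               compositionFractions(full$summary)["singleton"])
    rank <- function(cat) ifelse(cat == "singleton", 0,
                          ifelse(startsWith(cat, "dimer"), 1, 2))
    expect_true(all(rank(red$perPunctum$category) <=
                    rank(full$perPunctum$category)))
})

test_that("rotation null composition matches the independence closed form", {
    roi <- roiSpec(180, 180)
    crit <- overlapCriterion("centroid", 0.99)
    nF <- 400
    singles <- vapply(1:10, function(i) {
        F <- uniformSet("F", nF, roi, seed = 3000 + i)
        S <- uniformSet("S", 2000, roi, seed = 4000 + i)
        P <- uniformSet("P", 1000, roi, seed = 5000 + i)
        null <- compositionNull(F, list(S, P), "S", crit, angle = 90)
        compositionFractions(null$summary)["singleton"]
    }, numeric(1))
    pS <- closedFormColoc(0.99, 0.2, 0.2, 2000, 180^2)
    pP <- closedFormColoc(0.99, 0.2, 0.2, 1000, 180^2)
    expected <- 100 * (1 - pS) * (1 - pP)
    se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / (nF * 10))
    expect_lt(abs(mean(singles) - expected), 3 * se)
    ## sparse uniform scene: near-total singleton in both views
    Fs <- uniformSet("F", 50, roi, seed = 1)
    Ps <- uniformSet("P", 50, roi, seed = 2)
    rexp <- classifyComposition(Fs, list(Ps), "P", crit)
    rnull <- compositionNull(Fs, list(Ps), "P", crit, 90)
    expect_gt(compositionFractions(rexp$summary)["singleton"], 95)
    expect_gt(compositionFractions(rnull$summary)["singleton"], 95)
})

test_that("marker gating restricts channels and preserves planted pairs", {
    roi <- roiSpec(52, 52)
    sc <- generateScene(list(channelSpec("A", 100, "small"),
                             channelSpec("B", 150, "small")),
                        roi, plans = list(granulePlan("A", "B", 0.5,
                                                      jitterUm = 0)),
                        seed = 14)
    d <- gridDim(roi)
    ## marker covering the whole ROI is the identity
    allMask <- binaryMask(matrix(TRUE, d[1], d[2]), roi)
    gated <- gateByMarker(sc@channels, allMask)
    expect_equal(nPuncta(gated[[1]]), nPuncta(sc@channels$A))
    ## empty marker empties every channel
    noMask <- binaryMask(matrix(FALSE, d[1], d[2]), roi)
    gated0 <- gateByMarker(sc@channels, noMask)
    expect_true(all(vapply(gated0, nPuncta, integer(1)) == 0L))
    ## marker covering exactly the planted granule sites: gated
    ## colocalization >= ungated for the planted pair
    planted <- subset(sc@truth, channel == "A" & !is.na(granule_id))
    pA <- punctaTable(sc@channels$A)
    g <- matrix(FALSE, d[1], d[2])
    for (i in which(pA$id %in% planted$id)) {
        px <- discPixels(c(pA$x_um[i], pA$y_um[i]), 1, roi)
        g[px[, c("row", "col")] + 1L] <- TRUE
    }
    gatedG <- gateByMarker(sc@channels, binaryMask(g, roi))
    crit <- overlapCriterion("centroid", 0.99)
    expect_gte(percentOfReference(gatedG[[1]], gatedG[[2]], crit),
               percentOfReference(sc@channels$A, sc@channels$B, crit))
})
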