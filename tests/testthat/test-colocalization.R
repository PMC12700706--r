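test_that("centroid criterion applies the strict summed-radii inequality", {
    roi <- roiSpec(10, 10)
    ## two puncta, Feret 0.4 each, centroid distance 0.39:
    ## colocalized at f = 0.99 (0.39 < 0.396), not at f = 0.50 (0.39 > 0.20)
    A <- pointSet("A", roi, x = 5, y = 5, feret = 0.4)
    B <- pointSet("B", roi, x = 5.39, y = 5, feret = 0.4)
    expect_equal(colocalizedReferenceIds(A, B,
                     overlapCriterion("centroid", 0.99)), 1L)
    expect_length(colocalizedReferenceIds(A, B,
                     overlapCriterion("centroid", 0.50)), 0)
    ## empty target -> empty result; identical sets -> everything
    expect_length(colocalizedReferenceIds(A, B[0],
                     overlapCriterion("centroid", 0.99)), 0)
    U <- uniformSet("U", 50, roi, seed = 2)
    expect_equal(colocalizedReferenceIds(U, U, overlapCriterion("centroid")),
                 1:50)
    expect_equal(colocalizedReferenceIds(U, U, overlapCriterion("pixel")),
                 1:50)
    ## missing Feret is reported by punctum
    NoF <- punctaSet("N", roi, data.frame(
        id = 1L, x_um = 1, y_um = 1, area_um2 = 0.1, feret_um = NA,
        total_intensity = 1, mean_intensity = 1))
    expect_error(colocalizedReferenceIds(NoF, U,
                     overlapCriterion("centroid")), "id 1")
})

test_that("percent normalizations match their defining formulas", {
    roi <- roiSpec(120, 120)
    ## geometry with exactly 85 of 107 reference puncta colocalized
    x <- seq(1, 107) + 0.0
    A <- pointSet("A", roi, x = x, y = rep(60, 107), feret = 0.4)
    B <- pointSet("B", roi, x = x[1:85], y = rep(60, 85), feret = 0.4)
    crit <- overlapCriterion("centroid", 0.99)
    expect_equal(round(percentOfReference(A, B, crit), 1), 79.4)
    B33 <- B[1:33]
    expect_equal(round(percentOfReference(A, B33, crit), 1), 30.8)
    B5 <- B[1:5]
    expect_equal(round(percentOfReference(A, B5, crit), 1), 4.7)
    ## zero colocalized -> 0; empty reference -> missing
    far <- pointSet("C", roi, x = 1, y = 1, feret = 0.4)
    expect_equal(percentOfReference(far, B, crit), 0)
    expect_true(is.na(percentOfReference(A[0], B, crit)))
    ## pair normalization: symmetric, 100 for identical, 0 for disjoint
    expect_equal(percentOfPair(A, A, crit), 100)
    expect_equal(percentOfPair(A, B, crit), percentOfPair(B, A, crit))
    expect_equal(percentOfPair(far, B, crit), 100 * 1 / (1 + 85) * 0)
    expect_true(is.na(percentOfPair(A[0], B[0], crit)))
})

test_that("uniform scenes match the analytic overlap probability", {
    roi <- roiSpec(180, 180)
    S <- 180^2
    crit <- overlapCriterion("centroid", 0.99)
    nA <- 200; nB <- 4000; feret <- 0.4
    p <- closedFormColoc(0.99, 0.2, 0.2, nB, S)
    est <- vapply(1:15, function(i) {
        A <- uniformSet("A", nA, roi, feret, seed = 100 + i)
        B <- uniformSet("B", nB, roi, feret, seed = 900 + i)
        percentOfReference(A, B, crit) / 100
    }, numeric(1))
    expect_lt(abs(mean(est) - p), 3 * sqrt(p * (1 - p) / (nA * 15)))
})

test_that("pixel and centroid criteria agree away from boundary geometry", {
    roi <- roiSpec(52, 52)
    sc <- generateScene(list(channelSpec("A", 50, "small"),
                             channelSpec("B", 80, "small")),
                        roi, plans = list(granulePlan("A", "B", 0.4,
                                                      jitterUm = 0)),
                        seed = 8)
    idsPix <- colocalizedReferenceIds(sc@channels$A, sc@channels$B,
                                      overlapCriterion("pixel"))
    idsCen <- colocalizedReferenceIds(sc@channels$A, sc@channels$B,
                                      overlapCriterion("centroid", 0.99))
    planted <- punctaTable(sc@channels$A)$id[
        !is.na(subset(sc@truth, channel == "A")$granule_id)]
    expect_true(all(planted %in% idsPix))
    expect_true(all(planted %in% idsCen))
})

test_that("pairwise matrices cover all pairs and compose from pair calls", {
    roi <- roiSpec(52, 52)
    sets <- lapply(1:12, function(i)
        uniformSet(paste0("ch", i), 60, roi, seed = i))
    m <- pairwiseMatrix(sets, overlapCriterion("centroid", 0.99))
    cnt <- colocCounts(m)
    expect_equal(dim(cnt), c(12, 12))
    expect_equal(sum(!is.na(cnt[upper.tri(cnt)])), 66) # 66 unordered pairs
    ## identical channels: 100% off-diagonal
    dup <- pairwiseMatrix(list(uniformSet("a", 40, roi, seed = 1),
                               uniformSet("b", 40, roi, seed = 1)),
                          overlapCriterion("centroid", 0.99))
    expect_equal(colocPercent(dup)["a", "b"], 100)
    ## cells equal the standalone operations
    sc <- generateScene(list(channelSpec("A", 80, "small"),
                             channelSpec("B", 150, "small"),
                             channelSpec("C", 40, "small")),
                        roi, plans = list(granulePlan("A", "B", 0.3)),
                        seed = 6)
    crit <- overlapCriterion("centroid", 0.99)
    m3 <- pairwiseMatrix(sc@channels, crit)
    pc <- colocPercent(m3)
    expect_equal(pc["A", "B"],
                 percentOfReference(sc@channels$A, sc@channels$B, crit))
    mp <- pairwiseMatrix(sc@channels, crit, "percent_of_pair")
    pp <- colocPercent(mp)
    expect_equal(pp["B", "C"],
                 percentOfPair(sc@channels$B, sc@channels$C, crit))
    expect_equal(pp, t(pp))
    expect_error(pairwiseMatrix(list(uniformSet("a", 5, roi),
                                     uniformSet("a", 5, roi))),
                 "duplicated")
})

test_that("any-of-many colocalization equals the union of pairwise calls", {
    roi <- roiSpec(52, 52)
    sc <- generateScene(list(channelSpec("A", 100, "small"),
                             channelSpec("B", 200, "small"),
                             channelSpec("C", 200, "small")),
                        roi, plans = list(granulePlan("A", "B", 0.2)),
                        seed = 10)
    crit <- overlapCriterion("centroid", 0.99)
    u <- colocalizedWithAny(sc@channels$A, sc@channels[c("B", "C")], crit)
    ref <- sort(unique(c(
        colocalizedReferenceIds(sc@channels$A, sc@channels$B, crit),
        colocalizedReferenceIds(sc@channels$A, sc@channels$C, crit))))
    expect_equal(u, ref)
    ## all-empty partners -> empty
    expect_length(colocalizedWithAny(sc@channels$A,
                                     list(sc@channels$B[0]), crit), 0)
})

test_that("percentages are stable under duplication of both channels", {
    roi <- roiSpec(120, 120)
    A <- uniformSet("A", 300, roi, seed = 30)
    B <- uniformSet("B", 600, roi, seed = 31)
    crit <- overlapCriterion("centroid", 0.99)
    ## duplicate every punctum with a slightly offset copy: the spatial
    ## pattern is unchanged, so percentages should be too
    double <- function(s) {
        p <- punctaTable(s)
        p2 <- p
        p2$id <- p2$id + nrow(p)
        p2$x_um <- pmin(p2$x_um + 0.05, roiOf(s)@widthUm)
        p2$y_um <- pmin(p2$y_um + 0.05, roiOf(s)@heightUm)
        punctaSet(channelName(s), roiOf(s), rbind(p, p2))
    }
    p1 <- percentOfReference(A, B, crit)
    p2 <- percentOfReference(double(A), double(B), crit)
    expect_lt(abs(p1 - p2), 1.5)
})
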