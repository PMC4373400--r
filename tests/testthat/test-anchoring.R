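make_map <- function(vectors, lg, pos) {
    tab <- data.frame(linkage_group = lg, position_cM = pos,
                      bin_id = rownames(vectors),
                      representative = rownames(vectors),
                      n_members = 1L, stringsAsFactors = FALSE)
    methods::new("GeneticMap", table = tab, vectors = vectors,
                 members = as.list(rownames(vectors)), params = list())
}

framework_fixture <- function() {
    v <- random_dh_calls(12, 40, len_cM = 60, seed = 7, even = TRUE)
    rownames(v) <- sprintf("bin%02d", 1:12)
    make_map(v, lg = rep(c("LG1", "LG2"), each = 6),
             pos = rep(seq(0, 50, by = 10), 2))
}

test_that("anchoring applies the published rejection rules in order", {
    map <- framework_fixture()
    fw <- mapVectors(map)
    # identical to one framework vector: anchored there at distance 0
    q <- fw["bin03", , drop = FALSE]
    rownames(q) <- "scA"
    a <- anchorScaffolds(q, map)
    expect_identical(a$status, "anchored")
    expect_identical(a$linkage_group, "LG1")
    expect_equal(a$position_cM, 20)
    expect_equal(a$hamming, 0)
    # minimal distance 4 is rejected ("Hamming distance > 3")
    q4 <- fw["bin03", , drop = FALSE]
    q4[1, 1:4] <- ifelse(q4[1, 1:4] == "A", "B", "A")
    # ensure no other bin is closer than 4
    rownames(q4) <- "scB"
    a4 <- anchorScaffolds(q4, map)
    if (a4$hamming == 4) expect_identical(a4$status, "rejected:distance")
    # a distance-3 vector passes the distance rule
    q3 <- fw["bin03", , drop = FALSE]
    q3[1, 1:3] <- ifelse(q3[1, 1:3] == "A", "B", "A")
    rownames(q3) <- "scC"
    a3 <- anchorScaffolds(q3, map)
    if (a3$hamming == 3) expect_identical(a3$status, "anchored")
    # more than 70% missing is rejected before anything else
    qm <- q
    qm[1, 1:30] <- "-"
    rownames(qm) <- "scD"
    expect_identical(anchorScaffolds(qm, map)$status, "rejected:missing")
})

test_that("ties across linkage groups fail the 90% agreement rule", {
    v <- rbind(b1 = rep(c("A", "B"), 10), b2 = rep(c("A", "B"), 10))
    colnames(v) <- sprintf("I%02d", 1:20)
    map <- make_map(v, lg = c("LG1", "LG2"), pos = c(0, 0))
    q <- v["b1", , drop = FALSE]
    rownames(q) <- "sc"
    a <- anchorScaffolds(q, map)
    expect_identical(a$status, "rejected:agreement")
    expect_equal(a$agreement, 0.5)
})

test_that("MAD of neighbour positions above 5 cM rejects", {
    v <- matrix(rep(rep(c("A", "B"), 10), 3), 3, 20, byrow = TRUE,
                dimnames = list(c("b1", "b2", "b3"), sprintf("I%02d", 1:20)))
    map <- make_map(v, lg = rep("LG1", 3), pos = c(0, 30, 60))
    q <- v["b1", , drop = FALSE]
    rownames(q) <- "sc"
    a <- anchorScaffolds(q, map)
    expect_identical(a$status, "rejected:mad")
    map2 <- make_map(v, lg = rep("LG1", 3), pos = c(0, 1, 2))
    a2 <- anchorScaffolds(q, map2)
    expect_identical(a2$status, "anchored")
    expect_equal(a2$position_cM, 1)
})

test_that("nearest-neighbour search equals an exhaustive scan", {
    map <- framework_fixture()
    fw <- mapVectors(map)
    set.seed(31)
    for (i in 1:10) {
        q <- matrix(sample(c("A", "B", "-"), 40, TRUE, c(.4, .4, .2)), 1, 40,
                    dimnames = list("q", colnames(fw)))
        a <- anchorScaffolds(q, map, max_hamming = Inf,
                             min_chrom_agreement = 0, max_mad_cM = Inf,
                             max_missing = 1)
        brute <- apply(fw, 1, function(v)
            hammingDistance(q[1, ], v)[["distance"]])
        expect_equal(a$hamming, min(brute))
        expect_equal(a$n_nearest, sum(brute == min(brute)))
    }
})

test_that("marker-majority anchoring flags conflicting scaffolds", {
    placements <- data.frame(
        marker_id = c("m1", "m2", "m3", "m4", "m5"),
        scaffold = c("s1", "s1", "s1", "s2", "s2"),
        offset = c(10L, 50L, 90L, 5L, 60L),
        strand = "+", allele = 1L, status = "placed",
        stringsAsFactors = FALSE)
    marker_map <- data.frame(
        marker_id = c("m1", "m2", "m3", "m4", "m5"),
        linkage_group = c("LG1", "LG1", "LG1", "LG1", "LG2"),
        position_cM = c(3, 4, 5, 10, 44), stringsAsFactors = FALSE)
    res <- anchorByMarkers(placements, marker_map)
    expect_identical(res$anchors$linkage_group[res$anchors$scaffold_id == "s1"],
                     "LG1")
    expect_equal(res$anchors$position_cM[res$anchors$scaffold_id == "s1"], 4)
    expect_identical(res$conflicts$scaffold_id, "s2")
    # unplaced markers contribute nothing
    none <- placements
    none$status <- "absent"
    expect_identical(nrow(anchorByMarkers(none, marker_map)$anchors), 0L)
})

test_that("mis-join screening flags linkage-group and distance discordance", {
    mapped <- data.frame(
        marker_id = paste0("m", 1:6),
        scaffold = c("clean", "clean", "chim", "chim", "far", "far"),
        offset = c(0L, 100L, 0L, 100L, 0L, 100L),
        linkage_group = c("LG1", "LG1", "LG1", "LG2", "LG1", "LG1"),
        position_cM = c(10, 11, 10, 40, 10, 16.5), stringsAsFactors = FALSE)
    rep <- detectMisjoins(mapped, intra_scaffold_max_cM = 5)
    expect_identical(rep$flagged[rep$scaffold_id == "clean"], FALSE)
    expect_identical(rep$reason[rep$scaffold_id == "chim"], "linkage-group")
    expect_identical(rep$reason[rep$scaffold_id == "far"], "distance")
    # exactly 5 cM apart is tolerated
    edge <- mapped[1:2, ]
    edge$position_cM <- c(10, 15)
    expect_false(detectMisjoins(edge, 5)$flagged)
    # single-marker scaffolds are not assessable
    one <- mapped[1, , drop = FALSE]
    expect_identical(nrow(detectMisjoins(one, 5)), 0L)
})

test_that("collinearity reports agreement and signed rank correlation", {
    a <- data.frame(id = sprintf("s%02d", 1:20),
                    linkage_group = rep(c("A1", "A2"), each = 10),
                    position_cM = rep(seq(0, 45, by = 5), 2))
    b <- a
    b$linkage_group <- rep(c("B1", "B2"), each = 10)
    cc <- collinearity(a, b)
    expect_equal(cc$agreement, 1)
    expect_equal(cc$overall_rho, 1)
    # reversing one group gives rho -1 there, reported with sign
    b2 <- b
    b2$position_cM[1:10] <- rev(b2$position_cM[1:10])
    cc2 <- collinearity(a, b2)
    expect_equal(sort(cc2$per_group$rho), c(-1, 1))
    # independent random positions decorrelate
    set.seed(77)
    b3 <- b
    b3$position_cM <- runif(20, 0, 50)
    cc3 <- collinearity(a, b3)
    expect_lt(abs(cc3$overall_rho), 0.55)
    expect_error(collinearity(a[1, ], b[21, ]), "shared")
})

test_that("segregation distortion flags extreme allele-frequency bins only", {
    v <- rbind(balanced = c(rep("A", 39), rep("B", 39)),
               distorted = c(rep("A", 70), rep("B", 8)),
               sparse = c(rep("A", 5), rep("B", 4), rep("-", 69)))
    colnames(v) <- sprintf("I%02d", 1:78)
    map <- make_map(v, lg = rep("LG1", 3), pos = c(0, 1, 2))
    sd <- segregationDistortion(map)
    expect_false(sd$flagged[sd$bin_id == "balanced"])
    expect_true(sd$flagged[sd$bin_id == "distorted"])
    expect_lt(sd$p_value[sd$bin_id == "distorted"], 1e-12)
    expect_true(is.na(sd$p_value[sd$bin_id == "sparse"]))
    expect_equal(sd$freq_A[sd$bin_id == "balanced"], 0.5)
})
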