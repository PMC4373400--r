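# Expected canonical counts below were computed with the independent
# Biostrings-based oracle in helper-fixtures.R and frozen.

test_that("canonical counting matches hand-checkable cases and the oracle", {
    tab <- countKmers("ACGTA", 3)
    # ACG and CGT are reverse complements (canonical ACG, count 2);
    # GTA precedes its reverse complement TAC, so stays GTA
    expect_identical(kmerCounts(tab), c(ACG = 2L, GTA = 1L))
    expect_identical(kmerCounts(tab), oracle_count_kmers("ACGTA", 3))
    set.seed(99)
    seqs <- vapply(1:20, function(i)
        paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                     prob = c(.24, .24, .24, .24, .04)), collapse = ""),
        character(1))
    for (k in c(5, 9, 21)) {
        got <- kmerCounts(countKmers(seqs, k))
        expect_identical(got, oracle_count_kmers(seqs, k))
    }
})

test_that("a sequence and its reverse complement count identically", {
    s <- "ACCGTTAGGCATTTACGGAT"
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(kmerCounts(countKmers(s, 7)),
                     kmerCounts(countKmers(rc, 7)))
})

test_that("min_count filters and validation errors behave as documented", {
    tab <- countKmers(c("AAAAA", "AAAAA", "CCCCC"), 5, min_count = 2)
    expect_identical(kmerCounts(tab), c(AAAAA = 2L))
    expect_error(countKmers("ACGT", 4), "odd")
    expect_identical(length(kmerCounts(countKmers(character(0), 5))), 0L)
    # N-containing k-mers are skipped
    expect_identical(length(kmerCounts(countKmers("AANAA", 3))), 0L)
})

# Build read sets for a toy SNP with unique flanks: parents differ at one
# base; pooled population carries both alleles about equally.
toy_marker_reads <- function(k = 11, depth_parent = 20, depth_each = 45) {
    set.seed(7)
    left <- random_dna(k - 1)
    right <- random_dna(k - 1)
    g1 <- paste0(left, "A", right)
    g2 <- paste0(left, "G", right)
    list(p1 = rep(g1, depth_parent), p2 = rep(g2, depth_parent),
         pool = c(rep(g1, depth_each), rep(g2, depth_each)),
         g1 = g1, g2 = g2)
}

test_that("a planted SNP with unique flanks yields exactly one attributed pair", {
    k <- 11
    toy <- toy_marker_reads(k)
    t1 <- countKmers(toy$p1, k)
    t2 <- countKmers(toy$p2, k)
    tp <- countKmers(toy$pool, k)
    panel <- discoverMarkerPairs(t1, t2, tp, pool_window = c(40, 50))
    m <- panelMarkers(panel)
    # the SNP is flanked by k-1 unique bases on both sides: both the
    # left-flank and right-flank oriented pairs qualify
    expect_identical(nrow(m), 2L)
    expect_true(all(m$allele1 != m$allele2))
    # parental attribution is correct for every discovered pair
    for (i in seq_len(nrow(m))) {
        own <- if (m$parent_of_allele1[i] == "P1") m$count_a1_p1[i]
               else m$count_a1_p2[i]
        expect_gte(own, 5)
    }
})

test_that("identical parents give an empty panel", {
    k <- 11
    reads <- rep(random_dna(50), 30)
    t1 <- countKmers(reads, k)
    panel <- discoverMarkerPairs(t1, t1, t1, pool_window = c(1, 1000))
    expect_identical(nrow(panelMarkers(panel)), 0L)
})

test_that("a prefix with three observed final bases is rejected", {
    k <- 5
    pre <- "ACGT"
    reads1 <- rep(paste0(pre, "A"), 20)
    reads2 <- rep(paste0(pre, "C"), 20)
    reads3 <- rep(paste0(pre, "G"), 20)
    t1 <- countKmers(reads1, k)
    t2 <- countKmers(reads2, k)
    tp <- countKmers(c(reads1, reads2, reads3), k)
    panel <- discoverMarkerPairs(t1, t2, tp, pool_window = c(1, 100))
    expect_identical(nrow(panelMarkers(panel)), 0L)
})

test_that("discovery equals the brute-force prefix-group oracle on random genomes", {
    k <- 9
    for (seed in 1:3) {
        set.seed(seed)
        g1 <- random_dna(3000)
        snp_pos <- sort(sample(100:2900, 8))
        chars <- strsplit(g1, "")[[1]]
        chars2 <- chars
        for (ps in snp_pos)
            chars2[ps] <- sample(setdiff(c("A", "C", "G", "T"), chars[ps]), 1)
        g2 <- paste(chars2, collapse = "")
        t1 <- countKmers(rep(g1, 10), k)
        t2 <- countKmers(rep(g2, 10), k)
        tp <- countKmers(c(rep(g1, 45), rep(g2, 45)), k)
        win <- c(40, 50)
        panel <- discoverMarkerPairs(t1, t2, tp, win)
        oracle <- oracle_discover(t1, t2, tp, win)
        m <- panelMarkers(panel)
        expect_setequal(m$prefix, oracle$prefix)
        expect_identical(
            paste(pmin(m$allele1, m$allele2), pmax(m$allele1, m$allele2),
                  sep = "/")[order(m$prefix)],
            oracle$alleles[order(oracle$prefix)])
    }
})

test_that("discovery is invariant to reverse-complementing all input reads", {
    k <- 9
    set.seed(11)
    g1 <- random_dna(2000)
    chars <- strsplit(g1, "")[[1]]
    chars[500] <- ifelse(chars[500] == "A", "C", "A")
    g2 <- paste(chars, collapse = "")
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x)))
    t1 <- countKmers(rep(g1, 10), k); t1r <- countKmers(rep(rc(g1), 10), k)
    t2 <- countKmers(rep(g2, 10), k); t2r <- countKmers(rep(rc(g2), 10), k)
    tp <- countKmers(c(rep(g1, 45), rep(g2, 45)), k)
    tpr <- countKmers(rc(c(rep(g1, 45), rep(g2, 45))), k)
    a <- panelMarkers(discoverMarkerPairs(t1, t2, tp, c(40, 50)))
    b <- panelMarkers(discoverMarkerPairs(t1r, t2r, tpr, c(40, 50)))
    expect_identical(a, b)
})

test_that("genotyping against the panel calls A, B, H and absence", {
    k <- 11
    toy <- toy_marker_reads(k)
    panel <- discoverMarkerPairs(countKmers(toy$p1, k),
                                 countKmers(toy$p2, k),
                                 countKmers(toy$pool, k), c(40, 50))
    expect_true(all(genotypeAgainstPanel(toy$g1, panel) == "A"))
    expect_true(all(genotypeAgainstPanel(toy$g2, panel) == "B"))
    expect_true(all(genotypeAgainstPanel(c(toy$g1, toy$g2), panel) == "H"))
    expect_true(all(genotypeAgainstPanel("TTTTTTTTTTTTTTTTTTTT", panel) == "-"))
    # a KmerTable works as the read source too
    expect_true(all(genotypeAgainstPanel(countKmers(toy$g1, k), panel) == "A"))
    # genotyping a parent recovers its own allele everywhere
    expect_identical(unname(genotypeAgainstPanel(toy$p1, panel)),
                     rep("A", 2))
})

test_that("heterozygosity screen drops contaminated individuals then H markers", {
    k <- 11
    toy <- toy_marker_reads(k)
    panel <- discoverMarkerPairs(countKmers(toy$p1, k),
                                 countKmers(toy$p2, k),
                                 countKmers(toy$pool, k), c(40, 50))
    clean <- matrix("A", nrow(panelMarkers(panel)), 10,
                    dimnames = list(panelMarkers(panel)$marker_id,
                                    sprintf("I%02d", 1:10)))
    clean[, 6:10] <- "B"
    res <- screenPanel(panel, clean)
    expect_identical(res$excluded_individuals, character(0))
    expect_identical(nrow(panelMarkers(res$panel)), nrow(panelMarkers(panel)))
    # one individual heterozygous everywhere is excluded; the markers it
    # touched survive because the remaining individuals carry no H
    dirty <- clean
    dirty[, "I03"] <- "H"
    res2 <- screenPanel(panel, dirty)
    expect_identical(res2$excluded_individuals, "I03")
    expect_identical(nrow(panelMarkers(res2$panel)), nrow(panelMarkers(panel)))
    # an H call in a retained individual removes that marker (every
    # individual carries one H here, so none is an outlier)
    one_h <- clean
    one_h[1, ] <- "H"
    res3 <- screenPanel(panel, one_h)
    expect_identical(res3$excluded_individuals, character(0))
    expect_identical(res3$removed_markers, rownames(one_h)[1])
    expect_error(screenPanel(panel, clean[, 1:2, drop = FALSE]), "3 individuals")
})

test_that("markers place uniquely on scaffolds with strand awareness", {
    k <- 11
    toy <- toy_marker_reads(k)
    panel <- discoverMarkerPairs(countKmers(toy$p1, k),
                                 countKmers(toy$p2, k),
                                 countKmers(toy$pool, k), c(40, 50))
    pad <- random_dna(30)
    scaff <- Biostrings::DNAStringSet(c(s1 = paste0(pad, toy$g1)))
    pl <- placeMarkersOnScaffolds(panel, scaff)
    expect_true(all(pl$status == "placed"))
    expect_true(all(pl$scaffold == "s1"))
    # offsets are 0-based positions of the allele-1 k-mers inside s1
    expect_setequal(pl$offset, c(30L, 30L + k - 1L))
    # reverse-complemented scaffold flips the reported strand
    scaff_rc <- Biostrings::reverseComplement(scaff)
    names(scaff_rc) <- "s1"
    pl_rc <- placeMarkersOnScaffolds(panel, scaff_rc)
    expect_true(all(pl_rc$status == "placed"))
    expect_setequal(paste(pl$strand, pl_rc$strand), c("+ -", "- +"))
    # duplicated placement is non-unique; absence is reported
    two <- Biostrings::DNAStringSet(c(s1 = paste0(pad, toy$g1),
                                      s2 = toy$g1))
    pl2 <- placeMarkersOnScaffolds(panel, two)
    expect_true(all(pl2$status == "non-unique"))
    none <- Biostrings::DNAStringSet(c(s1 = strrep("AT", 40)))
    pl3 <- placeMarkersOnScaffolds(panel, none)
    expect_true(all(pl3$status == "absent"))
})
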