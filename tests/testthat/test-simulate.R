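test_that("parent genomes differ exactly at the registered SNPs", {
    p <- simParams(n_chromosomes = 1, chrom_len = 100000, snp_rate = 0.0032,
                   n_individuals = 5, seed = 42)
    pg <- makeParentGenomes(p)
    snps <- truthSnps(pg$truth)
    # binomial expectation: 320 +- 3 SD
    expect_lt(abs(nrow(snps) - 320), 3 * sqrt(320 * (1 - 0.0032)) + 1)
    s1 <- as.character(pg$parents$P1[["chr1"]])
    s2 <- as.character(pg$parents$P2[["chr1"]])
    diffs <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]]) - 1L
    expect_identical(diffs, snps$pos)
    expect_true(all(snps$allele_p1 != snps$allele_p2))
})

test_that("snp_rate 0 gives identical genomes and an empty registry", {
    p <- simParams(n_chromosomes = 1, chrom_len = 5000, snp_rate = 0,
                   n_individuals = 3, seed = 1)
    pg <- makeParentGenomes(p)
    expect_identical(as.character(pg$parents$P1), as.character(pg$parents$P2))
    expect_identical(nrow(truthSnps(pg$truth)), 0L)
})

test_that("generation is deterministic given the seed", {
    p <- simParams(n_chromosomes = 2, chrom_len = 20000, n_individuals = 10,
                   seed = 9)
    a <- makeParentGenomes(p)
    b <- makeParentGenomes(p)
    expect_identical(as.character(a$parents$P1), as.character(b$parents$P1))
    expect_identical(truthSnps(a$truth), truthSnps(b$truth))
    ta <- makeDHPopulation(a$truth)
    tb <- makeDHPopulation(b$truth)
    expect_identical(truthHaplotypes(ta), truthHaplotypes(tb))
})

test_that("degenerate configurations are rejected", {
    expect_error(simParams(chrom_len = 0), "chrom_len")
    expect_error(simParams(snp_rate = 1.5), "snp_rate")
    expect_error(simParams(chrom_len = 100, read_len = 150), "read_len")
})

test_that("map_length 0 gives non-recombinant parental chromosomes", {
    p <- simParams(n_chromosomes = 1, chrom_len = 50000, map_length = 0,
                   n_individuals = 20, arm_loss_rate = 0, seed = 3)
    truth <- makeDHPopulation(makeParentGenomes(p)$truth)
    hap <- truthHaplotypes(truth)
    expect_true(all(apply(hap, 2, function(h) length(unique(h)) == 1)))
})

test_that("recombinant fraction at 10 cM matches the no-interference model", {
    p <- simParams(n_chromosomes = 1, chrom_len = 100000, snp_rate = 0,
                   map_length = 50, n_individuals = 1000,
                   arm_loss_rate = 0, het_rate = 0, seed = 17)
    pg <- makeParentGenomes(p)
    # plant two markers exactly 10 cM (= 20 kbp at 50 cM / 100 kbp) apart
    truth <- pg$truth
    snps <- data.frame(snp_id = c("S1", "S2"), chrom = "chr1",
                       pos = c(40000L, 60000L), allele_p1 = "A",
                       allele_p2 = "C", cM = c(20, 30))
    truth <- methods::initialize(truth, snps = snps)
    truth <- makeDHPopulation(truth)
    hap <- truthHaplotypes(truth)
    rf_hat <- mean(hap[1, ] != hap[2, ])
    rf_exp <- (1 - exp(-0.2)) / 2 # Haldane at 10 cM
    se <- sqrt(rf_exp * (1 - rf_exp) / 1000)
    expect_lt(abs(rf_hat - rf_exp), 3 * se)
})

test_that("forced arm loss is recorded for every individual", {
    p <- simParams(n_chromosomes = 1, chrom_len = 20000, arm_loss_rate = 1,
                   n_individuals = 15, seed = 2)
    truth <- makeDHPopulation(makeParentGenomes(p)$truth)
    expect_identical(sort(unique(truth@arm_loss$individual)),
                     sprintf("DH%03d", 1:15))
    # SNPs inside lost arms are absent
    hap <- truthHaplotypes(truth)
    expect_true(anyNA(hap))
})

test_that("shredded reads are exact substrings at error rate 0 and cover deeply", {
    p <- simParams(n_chromosomes = 1, chrom_len = 10000, seed = 4)
    pg <- makeParentGenomes(p)
    reads <- shredReads(pg$parents$P1, coverage = 30, read_len = 100,
                        error_rate = 0, seed = 8)
    expect_equal(sum(Biostrings::width(reads)), 30 * 10000, tolerance = 0.02)
    genome <- pg$parents$P1[["chr1"]]
    some <- as.character(reads[1:50])
    hits <- vapply(some, function(r) {
        Biostrings::countPattern(r, genome) +
            Biostrings::countPattern(as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(r))),
                genome) > 0
    }, logical(1))
    expect_true(all(hits))
    expect_identical(length(shredReads(pg$parents$P1, 0, 100, seed = 1)), 0L)
    expect_error(shredReads(pg$parents$P1, 1, 20000, seed = 1), "read_len")
})

test_that("k-mer spectrum of reads is invariant to reverse complementation", {
    p <- simParams(n_chromosomes = 1, chrom_len = 5000, seed = 6)
    pg <- makeParentGenomes(p)
    reads <- shredReads(pg$parents$P1, 5, 80, 0, seed = 10)
    tab_fwd <- countKmers(reads, 21)
    tab_rc <- countKmers(Biostrings::reverseComplement(reads), 21)
    expect_identical(kmerCounts(tab_fwd), kmerCounts(tab_rc))
})

test_that("genotype matrix equals truth when noise-free, and missingness is calibrated", {
    p <- simParams(n_chromosomes = 2, chrom_len = 30000, n_individuals = 40,
                   arm_loss_rate = 0, het_rate = 0, seed = 12)
    truth <- makeDHPopulation(makeParentGenomes(p)$truth)
    gm <- makeGenotypeMatrix(truth, call_rate = 1, genotype_error = 0,
                             seed = 13)
    calls <- genotypeCalls(gm)
    hap <- truthHaplotypes(truth)[rownames(calls), ]
    expect_identical(unname(calls == "A"), unname(hap == 0L))
    expect_false(any(calls == "H"))
    gm3 <- makeGenotypeMatrix(truth, call_rate = 0.3, seed = 13)
    miss <- mean(genotypeCalls(gm3) == "-")
    expect_lt(abs(miss - 0.7), 3 * sqrt(0.7 * 0.3 / length(genotypeCalls(gm3))))
})

test_that("contaminated individuals show excess heterozygous calls", {
    p <- simParams(n_chromosomes = 1, chrom_len = 50000, n_individuals = 30,
                   arm_loss_rate = 0, het_rate = 0, seed = 21)
    truth <- makeDHPopulation(makeParentGenomes(p)$truth)
    truth <- methods::initialize(truth, het_individuals = "DH005")
    gm <- makeGenotypeMatrix(truth, call_rate = 1, seed = 22)
    h <- colMeans(genotypeCalls(gm) == "H")
    expect_gt(h[["DH005"]], 10 * max(stats::median(h), 0.001))
})

test_that("fragmentation tiles the genome and plants the requested chimeras", {
    p <- simParams(n_chromosomes = 2, chrom_len = 100000, seed = 31)
    pg <- makeParentGenomes(p)
    fa <- fragmentAssembly(pg$parents$P1, pg$truth, mean_len = 5000,
                           misjoin_rate = 0, seed = 32)
    sc <- truthScaffolds(fa$truth)
    expect_false(any(sc$chimera))
    expect_equal(sum(sc$end - sc$start), 200000)
    # concatenating per-chromosome scaffolds reconstructs the parent
    for (chrom in c("chr1", "chr2")) {
        ord <- sc[sc$chrom == chrom, ]
        ord <- ord[order(ord$start), ]
        rebuilt <- paste(as.character(fa$scaffolds[ord$scaffold_id]),
                         collapse = "")
        expect_identical(rebuilt, as.character(pg$parents$P1[[chrom]]))
    }
    fa2 <- fragmentAssembly(pg$parents$P1, pg$truth, mean_len = 2000,
                            misjoin_rate = 0.10, seed = 33)
    n_chim <- nrow(truthMisjoins(fa2$truth))
    n_total <- 100 # ~100 scaffolds at 2 kbp over 200 kbp
    expect_gt(n_chim, 0)
    expect_lt(abs(n_chim - 0.10 * n_total), 3 * sqrt(0.10 * 0.9 * n_total) + 2)
    expect_true(all(truthMisjoins(fa2$truth)$chrom_a !=
                    truthMisjoins(fa2$truth)$chrom_b))
    expect_error(fragmentAssembly(pg$parents$P1[1], pg$truth,
                                  misjoin_rate = 0.1), "2 chromosomes")
})

test_that("DH purity holds without contamination or genotype error", {
    p <- simParams(n_chromosomes = 1, chrom_len = 20000, n_individuals = 25,
                   het_rate = 0, seed = 41)
    truth <- makeDHPopulation(makeParentGenomes(p)$truth)
    gm <- makeGenotypeMatrix(truth, call_rate = 0.6, genotype_error = 0,
                             seed = 42)
    expect_false(any(genotypeCalls(gm) == "H"))
})
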