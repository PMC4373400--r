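#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @useDynLib popanchor, .registration = TRUE
NULL

# Genotype call alphabet used throughout: A = parent-1 allele, B = parent-2
# allele, H = both observed (heterozygous/contaminated), "-" = missing.
CALL_ALPHABET <- c("A", "B", "H", "-")

#' Simulation parameters for the synthetic study design
#'
#' Holds the population and sequencing design of a doubled-haploid (DH)
#' mapping experiment: two fully homozygous parents differing at a given
#' SNP rate, a DH population derived from their F1, low-coverage shotgun
#' reads per individual, and deeper parental read sets. Defaults emulate
#' the wheat SynOpDH design: 90 DH lines at 1.4-fold coverage, a 0.32%
#' parental SNP rate, parental coverages of 30x and 19x, occasional loss
#' of a chromosome arm and occasional heterozygous contamination.
#'
#' @slot n_chromosomes number of chromosomes
#' @slot chrom_len chromosome length in bp
#' @slot snp_rate substitutions per bp between the parents
#' @slot n_individuals number of DH individuals
#' @slot map_length genetic length per chromosome in cM
#' @slot coverage_parent_a,coverage_parent_b,coverage_dh fold coverages
#' @slot read_len read length in bp
#' @slot error_rate per-base substitution error rate of simulated reads
#' @slot arm_loss_rate probability an individual loses one chromosome arm
#' @slot het_rate probability an individual is a heterozygous contaminant
#' @slot seed integer seed governing all randomness
#' @exportClass SimParams
setClass("SimParams", representation(
    n_chromosomes = "integer", chrom_len = "integer", snp_rate = "numeric",
    n_individuals = "integer", map_length = "numeric",
    coverage_parent_a = "numeric", coverage_parent_b = "numeric",
    coverage_dh = "numeric", read_len = "integer", error_rate = "numeric",
    arm_loss_rate = "numeric", het_rate = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    rates <- c(snp_rate = object@snp_rate, error_rate = object@error_rate,
               arm_loss_rate = object@arm_loss_rate, het_rate = object@het_rate)
    bad <- rates < 0 | rates > 1
    if (any(bad))
        msg <- c(msg, paste0(names(rates)[bad][1], " must lie in [0, 1]"))
    if (object@n_chromosomes < 1L) msg <- c(msg, "need at least one chromosome")
    if (object@chrom_len < 1L) msg <- c(msg, "chrom_len must be positive")
    if (object@chrom_len < object@read_len)
        msg <- c(msg, "chrom_len must be >= read_len")
    if (object@n_individuals < 1L) msg <- c(msg, "need at least one individual")
    if (object@map_length < 0) msg <- c(msg, "map_length must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated mapping experiment
#'
#' Accumulates everything the generator knows and analyses try to recover:
#' the SNP registry with true genetic positions, per-individual crossover
#' breakpoints and haplotypes, arm-loss events, contaminated individuals,
#' the scaffold origin table and the list of planted chimeric joins.
#' Haplotype codes: 0 = parent-1 allele, 1 = parent-2 allele, NA = absent
#' (lost chromosome arm).
#'
#' @slot params the generating [SimParams]
#' @slot snps data.frame: snp_id, chrom, pos (0-based), allele_p1,
#'   allele_p2, cM (true genetic position)
#' @slot haplotypes integer matrix, SNPs x individuals
#' @slot crossovers per-individual list of per-chromosome breakpoints (bp)
#' @slot arm_loss data.frame: individual, chrom, arm ("L"/"R"), from, to
#' @slot het_individuals ids of contaminated individuals
#' @slot scaffolds data.frame: scaffold_id, chrom, start, end (0-based,
#'   half-open), strand, part, chimera
#' @slot misjoins data.frame: scaffold_id, chrom_a, chrom_b
#' @exportClass SimTruth
setClass("SimTruth", representation(
    params = "SimParams", snps = "data.frame", haplotypes = "matrix",
    crossovers = "list", arm_loss = "data.frame",
    het_individuals = "character", scaffolds = "data.frame",
    misjoins = "data.frame"))

#' Canonical k-mer count table
#'
#' Exact multiplicities of canonical k-mers (the lexicographically smaller
#' of a k-mer and its reverse complement) in one read source. k must be
#' odd so that canonical form is unambiguous.
#'
#' @slot k k-mer length (odd)
#' @slot source free-text label of the read source
#' @slot kmers canonical k-mer strings, sorted
#' @slot counts multiplicities (after any minimum-count filter)
#' @exportClass KmerTable
setClass("KmerTable", representation(
    k = "integer", source = "character", kmers = "character",
    counts = "integer"))

setValidity("KmerTable", function(object) {
    if (object@k %% 2L == 0L) return("k must be odd")
    if (length(object@kmers) != length(object@counts))
        return("kmers and counts differ in length")
    if (length(object@counts) && any(object@counts < 1L))
        return("counts must be >= 1")
    TRUE
})

#' k-mer frequency spectrum
#'
#' Histogram of distinct-k-mer multiplicities: the low-depth uptick is
#' sequencing error, the main peak sits at the homozygous k-mer depth, and
#' the heavy tail is repetitive sequence.
#'
#' @slot k k-mer length
#' @slot freq occurrence frequencies (>= 1)
#' @slot count number of distinct k-mers at each frequency
#' @exportClass Spectrum
setClass("Spectrum", representation(
    k = "integer", freq = "integer", count = "numeric"))

#' Panel of k-mer pair markers
#'
#' Each marker is a pair of k-mers sharing a common (k-1)-mer prefix and
#' differing only in their final base, with one allele private to each
#' parent ("50+1-mer marker" at k = 51). The table stores the prefix, the
#' two final bases, which parent owns allele 1, and the observed counts of
#' each allele in parent 1, parent 2 and the pooled population reads.
#'
#' @slot k k-mer length
#' @slot markers data.frame: marker_id, prefix, allele1, allele2,
#'   parent_of_allele1, count_a1_p1, count_a1_p2, count_a1_pool,
#'   count_a2_p1, count_a2_p2, count_a2_pool
#' @slot params discovery parameters (pool window, parental thresholds)
#' @exportClass MarkerPanel
setClass("MarkerPanel", representation(
    k = "integer", markers = "data.frame", params = "list"))

setValidity("MarkerPanel", function(object) {
    m <- object@markers
    if (!nrow(m)) return(TRUE)
    if (anyDuplicated(m$marker_id)) return("marker ids must be unique")
    if (anyDuplicated(m$prefix)) return("two pairs share a prefix (bi-allelic condition violated)")
    if (any(m$allele1 == m$allele2)) return("alleles of a pair must differ")
    TRUE
})

#' SNP-by-individual genotype matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"calls"}
#' holds one character cell per SNP and individual. After polarization the
#' alphabet is A/B/H/- (A = parent-1 allele); before polarization raw
#' nucleotide calls such as "G" or "G/T" are accepted. Row metadata
#' carries snp_id, scaffold, pos (0-based), qual, allele_p1, allele_p2.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    need <- c("snp_id", "scaffold", "pos", "qual", "allele_p1", "allele_p2")
    miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
    if (length(miss))
        return(paste("missing row metadata columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' Consensus genotypes of marker groups or scaffolds
#'
#' One consensus call vector (A/B/-) per unit (typically per scaffold)
#' across individuals, with per-unit call statistics.
#'
#' @slot calls character matrix, units x individuals, alphabet A/B/-
#' @slot stats data.frame: unit_id, n_sites, n_A, n_B, n_missing
#' @exportClass ConsensusGenotypes
setClass("ConsensusGenotypes", representation(
    calls = "matrix", stats = "data.frame"))

#' Genetic linkage map of ordered recombination bins
#'
#' Linkage groups of ordered marker bins with cumulative Kosambi cM
#' positions, plus each bin representative's genotype vector (needed for
#' nearest-neighbour anchoring) and the bin memberships.
#'
#' @slot table data.frame: linkage_group, position_cM, bin_id,
#'   representative, n_members
#' @slot vectors character matrix of representative call vectors
#'   (rownames = bin_id), alphabet A/B/-
#' @slot members list mapping bin_id to member unit ids
#' @slot params parameters used during construction
#' @exportClass GeneticMap
setClass("GeneticMap", representation(
    table = "data.frame", vectors = "matrix", members = "list",
    params = "list"))

setValidity("GeneticMap", function(object) {
    tab <- object@table
    if (!nrow(tab)) return(TRUE)
    if (anyDuplicated(tab$bin_id)) return("bin ids must be unique")
    bad <- vapply(split(tab$position_cM, tab$linkage_group), function(p) {
        is.unsorted(p) || p[1] != 0
    }, logical(1))
    if (any(bad))
        return("positions within a linkage group must be non-decreasing from 0")
    TRUE
})
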