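#' @rdname KmerTable-class
#' @param object,x a \linkS4class{KmerTable}
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname KmerTable-class
#' @export
setMethod("kmerLength", "KmerTable", function(x) x@k)

#' @rdname MarkerPanel-class
#' @export
setMethod("kmerLength", "MarkerPanel", function(x) x@k)

#' @rdname Spectrum-class
#' @export
setMethod("kmerLength", "Spectrum", function(x) x@k)

#' Counts stored in a k-mer table
#'
#' @param x a \linkS4class{KmerTable}
#' @return named integer vector of canonical k-mer counts
#' @export
kmerCounts <- function(x) {
    stopifnot(is(x, "KmerTable"))
    stats::setNames(x@counts, x@kmers)
}

#' @rdname MarkerPanel-class
#' @param x a \linkS4class{MarkerPanel}
#' @export
panelMarkers <- function(x) {
    stopifnot(is(x, "MarkerPanel"))
    x@markers
}

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix (SNPs x individuals) of genotype calls
#' @param info data.frame of row metadata with columns snp_id, scaffold,
#'   pos (0-based), qual, allele_p1, allele_p2
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(calls, info) {
    stopifnot(is.matrix(calls), nrow(calls) == nrow(info))
    rownames(calls) <- info$snp_id
    if (is.null(colnames(calls)) && ncol(calls))
        colnames(calls) <- sprintf("I%03d", seq_len(ncol(calls)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls),
        rowData = S4Vectors::DataFrame(info, row.names = info$snp_id))
    methods::new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix
#' @param x a \linkS4class{GenotypeMatrix}
#' @export
genotypeCalls <- function(x) {
    stopifnot(is(x, "GenotypeMatrix"))
    SummarizedExperiment::assay(x, "calls")
}

#' @rdname GenotypeMatrix
#' @export
snpInfo <- function(x) {
    stopifnot(is(x, "GenotypeMatrix"))
    as.data.frame(SummarizedExperiment::rowData(x))
}

#' @rdname ConsensusGenotypes-class
#' @param x a \linkS4class{ConsensusGenotypes}
#' @export
consensusCalls <- function(x) {
    stopifnot(is(x, "ConsensusGenotypes"))
    x@calls
}

#' @rdname ConsensusGenotypes-class
#' @export
consensusStats <- function(x) {
    stopifnot(is(x, "ConsensusGenotypes"))
    x@stats
}

#' @rdname GeneticMap-class
#' @param x a \linkS4class{GeneticMap}
#' @export
mapTable <- function(x) {
    stopifnot(is(x, "GeneticMap"))
    x@table
}

#' @rdname GeneticMap-class
#' @export
mapVectors <- function(x) {
    stopifnot(is(x, "GeneticMap"))
    x@vectors
}

#' @rdname GeneticMap-class
#' @export
binMembers <- function(x) {
    stopifnot(is(x, "GeneticMap"))
    x@members
}

#' @rdname SimTruth-class
#' @param x a \linkS4class{SimTruth}
#' @export
truthSnps <- function(x) {
    stopifnot(is(x, "SimTruth"))
    x@snps
}

#' @rdname SimTruth-class
#' @export
truthHaplotypes <- function(x) {
    stopifnot(is(x, "SimTruth"))
    x@haplotypes
}

#' @rdname SimTruth-class
#' @export
truthScaffolds <- function(x) {
    stopifnot(is(x, "SimTruth"))
    x@scaffolds
}

#' @rdname SimTruth-class
#' @export
truthMisjoins <- function(x) {
    stopifnot(is(x, "SimTruth"))
    x@misjoins
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@n_chromosomes, "chromosome(s) x",
        object@chrom_len, "bp,", object@n_individuals, "DH individuals\n")
    cat("  snp_rate", object@snp_rate, "| map", object@map_length,
        "cM | coverage P1/P2/DH", object@coverage_parent_a, "/",
        object@coverage_parent_b, "/", object@coverage_dh, "\n")
    cat("  read_len", object@read_len, "| error", object@error_rate,
        "| arm loss", object@arm_loss_rate, "| het", object@het_rate,
        "| seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@snps), "SNPs,",
        ncol(object@haplotypes), "individuals,",
        nrow(object@scaffolds), "scaffold origin record(s),",
        nrow(object@misjoins), "planted misjoin(s)\n")
})

setMethod("show", "KmerTable", function(object) {
    cat("KmerTable (", object@source, "): ", length(object@kmers),
        " distinct canonical ", object@k, "-mers, total count ",
        sum(as.numeric(object@counts)), "\n", sep = "")
})

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum: k =", object@k, ",", length(object@freq),
        "frequency classes, mass", sum(object@freq * object@count), "\n")
})

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel:", nrow(object@markers), "k-mer pair markers (k =",
        object@k, ")\n")
})

setMethod("show", "ConsensusGenotypes", function(object) {
    cat("ConsensusGenotypes:", nrow(object@calls), "units x",
        ncol(object@calls), "individuals\n")
})

setMethod("show", "GeneticMap", function(object) {
    tab <- object@table
    cat("GeneticMap:", length(unique(tab$linkage_group)),
        "linkage group(s),", nrow(tab), "bins,",
        round(sum(vapply(split(tab$position_cM, tab$linkage_group), max,
                         numeric(1))), 1), "cM total\n")
})
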