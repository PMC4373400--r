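#' Define a synthetic DH mapping experiment
#'
#' Constructs the parameter object governing the whole generator. The
#' defaults emulate the published SynOpDH wheat design scaled to desk
#' size: two homozygous parents differing at a 0.32% SNP rate, 90
#' doubled-haploid (DH) progeny sequenced at 1.4-fold coverage, parental
#' coverages of 30x and 19x, about 135 cM of genetic length per
#' chromosome, and low rates of chromosome-arm loss and heterozygous
#' contamination among individuals (the published population contained 10
#' arm-loss and 2 contaminated lines out of 90).
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_len chromosome length (bp)
#' @param snp_rate substitution rate between the parents (per bp)
#' @param n_individuals number of DH progeny
#' @param map_length genetic length per chromosome (cM)
#' @param coverage_parent_a,coverage_parent_b,coverage_dh fold coverages
#'   of parent 1, parent 2 and each DH individual
#' @param read_len read length (bp)
#' @param error_rate per-base substitution error rate of simulated reads
#' @param arm_loss_rate probability an individual loses one chromosome arm
#' @param het_rate probability an individual is a heterozygous contaminant
#' @param seed integer seed
#' @return a \linkS4class{SimParams}
#' @export
simParams <- function(n_chromosomes = 3, chrom_len = 1e6, snp_rate = 0.0032,
                      n_individuals = 90, map_length = 135,
                      coverage_parent_a = 30, coverage_parent_b = 19,
                      coverage_dh = 1.4, read_len = 150, error_rate = 0.005,
                      arm_loss_rate = 10 / 90, het_rate = 2 / 90, seed = 1) {
    methods::new("SimParams",
        n_chromosomes = as.integer(n_chromosomes),
        chrom_len = as.integer(chrom_len), snp_rate = snp_rate,
        n_individuals = as.integer(n_individuals), map_length = map_length,
        coverage_parent_a = coverage_parent_a,
        coverage_parent_b = coverage_parent_b, coverage_dh = coverage_dh,
        read_len = as.integer(read_len), error_rate = error_rate,
        arm_loss_rate = arm_loss_rate, het_rate = het_rate,
        seed = as.integer(seed))
}

#' Generate the two homozygous parental genomes
#'
#' Draws a random genome for parent 1 and derives parent 2 by placing
#' biallelic substitutions at independently sampled positions (rate
#' \code{snp_rate}), so the SNP count is binomial around
#' \code{snp_rate * genome length}. Every SNP is registered with its true
#' genetic position, taken proportional to physical position
#' (\code{map_length * pos / chrom_len}).
#'
#' @param params a \linkS4class{SimParams}
#' @return list with elements \code{parents} (list of two named
#'   \code{DNAStringSet}s, \code{P1} and \code{P2}) and \code{truth}
#'   (a \linkS4class{SimTruth})
#' @export
makeParentGenomes <- function(params) {
    methods::validObject(params)
    set.seed(params@seed)
    chroms <- paste0("chr", seq_len(params@n_chromosomes))
    len <- params@chrom_len
    p1 <- p2 <- character(length(chroms))
    snp_list <- vector("list", length(chroms))
    bases <- c("A", "C", "G", "T")
    for (ci in seq_along(chroms)) {
        seq1 <- sample(bases, len, replace = TRUE)
        pos <- which(stats::runif(len) < params@snp_rate) # 1-based index
        seq2 <- seq1
        if (length(pos)) {
            alt <- vapply(seq1[pos], function(b) sample(setdiff(bases, b), 1),
                          character(1))
            seq2[pos] <- alt
            snp_list[[ci]] <- data.frame(
                chrom = chroms[ci], pos = pos - 1L,
                allele_p1 = seq1[pos], allele_p2 = alt,
                stringsAsFactors = FALSE)
        } else {
            snp_list[[ci]] <- data.frame(
                chrom = character(), pos = integer(),
                allele_p1 = character(), allele_p2 = character())
        }
        p1[ci] <- paste(seq1, collapse = "")
        p2[ci] <- paste(seq2, collapse = "")
    }
    snps <- do.call(rbind, snp_list)
    if (nrow(snps)) {
        snps$snp_id <- sprintf("S%06d", seq_len(nrow(snps)))
        snps$cM <- params@map_length * snps$pos / len
        snps <- snps[, c("snp_id", "chrom", "pos", "allele_p1", "allele_p2", "cM")]
    } else {
        snps <- data.frame(snp_id = character(), chrom = character(),
                           pos = integer(), allele_p1 = character(),
                           allele_p2 = character(), cM = numeric())
    }
    rownames(snps) <- NULL
    truth <- methods::new("SimTruth", params = params, snps = snps,
        haplotypes = matrix(integer(), nrow(snps), 0),
        crossovers = list(), arm_loss = empty_arm_loss(),
        het_individuals = character(), scaffolds = empty_scaffolds(),
        misjoins = empty_misjoins())
    parents <- list(
        P1 = Biostrings::DNAStringSet(stats::setNames(p1, chroms)),
        P2 = Biostrings::DNAStringSet(stats::setNames(p2, chroms)))
    list(parents = parents, truth = truth)
}

empty_arm_loss <- function() data.frame(
    individual = character(), chrom = character(), arm = character(),
    from = integer(), to = integer(), stringsAsFactors = FALSE)

empty_scaffolds <- function() data.frame(
    scaffold_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), part = integer(),
    chimera = logical(), stringsAsFactors = FALSE)

empty_misjoins <- function() data.frame(
    scaffold_id = character(), chrom_a = character(), chrom_b = character(),
    stringsAsFactors = FALSE)

#' Simulate the DH population
#'
#' Each individual is one recombinant gamete doubled: a mosaic of the two
#' parental haplotypes with crossovers drawn from a no-interference
#' (Poisson) model, \code{Poisson(map_length / 100)} crossovers per
#' chromosome placed uniformly. With probability \code{arm_loss_rate} an
#' individual loses one arm (left or right of the midpoint) of one random
#' chromosome; SNPs there become absent (NA). With probability
#' \code{het_rate} an individual is flagged as a heterozygous contaminant;
#' the flag is consumed downstream when genotype calls or reads are
#' produced.
#'
#' @param truth a \linkS4class{SimTruth} from [makeParentGenomes()]
#' @return the updated \linkS4class{SimTruth} with haplotypes, crossover
#'   breakpoints, arm-loss events and contaminated-individual flags
#' @export
makeDHPopulation <- function(truth) {
    params <- truth@params
    set.seed(params@seed + 1L)
    n <- params@n_individuals
    len <- params@chrom_len
    chroms <- paste0("chr", seq_len(params@n_chromosomes))
    inds <- sprintf("DH%03d", seq_len(n))
    snps <- truth@snps
    hap <- matrix(NA_integer_, nrow(snps), n,
                  dimnames = list(snps$snp_id, inds))
    xo <- vector("list", n)
    names(xo) <- inds
    arm_loss <- empty_arm_loss()
    for (i in seq_len(n)) {
        xo_i <- vector("list", length(chroms))
        names(xo_i) <- chroms
        for (ci in seq_along(chroms)) {
            n_xo <- stats::rpois(1, params@map_length / 100)
            bp <- sort(stats::runif(n_xo, 0, len))
            start_parent <- sample(0:1, 1)
            xo_i[[ci]] <- list(breakpoints = bp, start = start_parent)
            rows <- which(snps$chrom == chroms[ci])
            if (length(rows)) {
                segment <- findInterval(snps$pos[rows], bp)
                hap[rows, i] <- (start_parent + segment) %% 2L
            }
        }
        xo[[i]] <- xo_i
        if (stats::runif(1) < params@arm_loss_rate) {
            ci <- sample(seq_along(chroms), 1)
            arm <- sample(c("L", "R"), 1)
            from <- if (arm == "L") 0L else as.integer(len %/% 2L)
            to <- if (arm == "L") as.integer(len %/% 2L) else len
            arm_loss <- rbind(arm_loss, data.frame(
                individual = inds[i], chrom = chroms[ci], arm = arm,
                from = from, to = to, stringsAsFactors = FALSE))
            rows <- which(snps$chrom == chroms[ci] & snps$pos >= from &
                          snps$pos < to)
            hap[rows, i] <- NA_integer_
        }
    }
    het <- inds[stats::runif(n) < params@het_rate]
    methods::initialize(truth, haplotypes = hap, crossovers = xo,
                        arm_loss = arm_loss, het_individuals = het)
}

#' Reconstruct one DH individual's genome sequence
#'
#' Splices the two parental sequences at the individual's crossover
#' breakpoints; a lost chromosome arm is excised (absent from the
#' returned sequence).
#'
#' @param parents parental genomes from [makeParentGenomes()]
#' @param truth populated \linkS4class{SimTruth}
#' @param individual individual id, e.g. \code{"DH001"}
#' @return named \code{DNAStringSet}, one sequence per (retained part of
#'   a) chromosome
#' @export
individualGenome <- function(parents, truth, individual) {
    xo <- truth@crossovers[[individual]]
    if (is.null(xo)) stop("unknown individual: ", individual)
    len <- truth@params@chrom_len
    p1 <- as.character(parents$P1)
    p2 <- as.character(parents$P2)
    out <- character(length(xo))
    names(out) <- names(xo)
    for (chrom in names(xo)) {
        bp <- c(0, xo[[chrom]]$breakpoints, len)
        parent <- (xo[[chrom]]$start + seq_len(length(bp) - 1L) - 1L) %% 2L
        pieces <- character(length(bp) - 1L)
        for (s in seq_along(pieces)) {
            src <- if (parent[s] == 0L) p1[[chrom]] else p2[[chrom]]
            pieces[s] <- substring(src, floor(bp[s]) + 1L, floor(bp[s + 1L]))
        }
        out[chrom] <- paste(pieces, collapse = "")
    }
    loss <- truth@arm_loss[truth@arm_loss$individual == individual, ]
    if (nrow(loss)) {
        for (r in seq_len(nrow(loss))) {
            chrom <- loss$chrom[r]
            keep_from <- if (loss$arm[r] == "L") loss$to[r] + 1L else 1L
            keep_to <- if (loss$arm[r] == "L") len else loss$from[r]
            out[chrom] <- substring(out[chrom], keep_from, keep_to)
        }
    }
    Biostrings::DNAStringSet(out)
}

#' Shred a genome into error-bearing single-end shotgun reads
#'
#' Uniformly samples single-end reads of fixed length from both strands
#' to the requested fold coverage, then applies i.i.d. substitution
#' errors at \code{error_rate}. Deterministic given \code{seed}.
#'
#' @param genome a \code{DNAStringSet} (or named character vector)
#' @param coverage target fold coverage (0 gives an empty read set)
#' @param read_len read length (bp); must not exceed any sequence length
#' @param error_rate per-base substitution probability
#' @param seed integer seed
#' @param prefix read-name prefix
#' @return named \code{DNAStringSet} of reads
#' @export
shredReads <- function(genome, coverage, read_len, error_rate = 0,
                       seed = 1, prefix = "read") {
    seqs <- as.character(genome)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (coverage < 0) stop("coverage must be >= 0")
    if (coverage > 0 && any(lens < read_len))
        stop("read_len exceeds the length of sequence ",
             names(seqs)[which(lens < read_len)[1]])
    set.seed(seed)
    n_reads <- round(coverage * lens / read_len)
    all_reads <- character(0)
    for (si in seq_along(seqs)) {
        n <- n_reads[si]
        if (n == 0) next
        start <- sample.int(lens[si] - read_len + 1L, n, replace = TRUE)
        reads <- substring(seqs[si], start, start + read_len - 1L)
        rc <- stats::runif(n) < 0.5
        if (any(rc)) reads[rc] <- revcomp(reads[rc])
        all_reads <- c(all_reads, reads)
    }
    if (length(all_reads))
        all_reads <- cpp_inject_errors(all_reads, error_rate)
    names(all_reads) <- if (length(all_reads))
        paste0(prefix, "_", seq_along(all_reads)) else character(0)
    Biostrings::DNAStringSet(all_reads)
}

#' Write reads to FASTQ
#'
#' @param reads a \code{DNAStringSet} of reads
#' @param path output file path
#' @export
writeReadsFastq <- function(reads, path) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}

# Map every registered SNP onto its scaffold and scaffold-local position.
snp_scaffold_map <- function(truth) {
    snps <- truth@snps
    sc <- truth@scaffolds
    if (!nrow(sc)) {
        return(data.frame(snp_id = snps$snp_id, scaffold = snps$chrom,
                          pos = snps$pos, stringsAsFactors = FALSE))
    }
    # offset of each origin segment within its scaffold (chimera part 2
    # starts after part 1)
    sc$seg_len <- sc$end - sc$start
    sc$offset <- 0L
    two <- sc$part == 2L
    if (any(two)) {
        part1_len <- stats::setNames(sc$seg_len[sc$part == 1L],
                                     sc$scaffold_id[sc$part == 1L])
        sc$offset[two] <- part1_len[sc$scaffold_id[two]]
    }
    out <- data.frame(snp_id = snps$snp_id, scaffold = NA_character_,
                      pos = NA_integer_, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(sc))) {
        hit <- snps$chrom == sc$chrom[r] & snps$pos >= sc$start[r] &
               snps$pos < sc$end[r]
        out$scaffold[hit] <- sc$scaffold_id[r]
        out$pos[hit] <- snps$pos[hit] - sc$start[r] + sc$offset[r]
    }
    out
}

#' Emit a genotype matrix from the simulated truth
#'
#' An alignment-free stand-in for read-mapping/pileup genotyping: each
#' SNP row carries its (scaffold, position, quality, parental alleles)
#' metadata and per-individual calls equal to the true haplotype allele,
#' masked to missing with probability \code{1 - call_rate} and corrupted
#' with probability \code{genotype_error} (half flipped, half set to H).
#' SNPs falling in lost chromosome arms are missing. Contaminated
#' individuals (flagged in the truth) additionally have a fraction
#' \code{het_call_fraction} of their non-missing calls set to H.
#' Quality scores are drawn so that a fraction \code{low_qual_fraction}
#' falls below 40, exercising the downstream quality filter.
#'
#' @param truth populated \linkS4class{SimTruth}
#' @param call_rate probability a true call is observed
#' @param genotype_error probability an observed call is corrupted
#' @param seed integer seed
#' @param raw if TRUE, emit raw nucleotide calls (heterozygotes as
#'   \code{"X/Y"}) plus parental columns P1/P2, for [polarizeGenotypes()]
#' @param low_qual_fraction fraction of rows with quality below 40
#' @param het_call_fraction fraction of H calls for contaminated individuals
#' @return a \linkS4class{GenotypeMatrix}
#' @export
makeGenotypeMatrix <- function(truth, call_rate = 1, genotype_error = 0,
                               seed = 1, raw = FALSE,
                               low_qual_fraction = 0.05,
                               het_call_fraction = 0.15) {
    if (!ncol(truth@haplotypes)) stop("population not generated yet")
    set.seed(seed)
    snps <- truth@snps
    hap <- truth@haplotypes
    n_snp <- nrow(hap)
    n_ind <- ncol(hap)
    calls <- matrix("-", n_snp, n_ind, dimnames = dimnames(hap))
    calls[!is.na(hap) & hap == 0L] <- "A"
    calls[!is.na(hap) & hap == 1L] <- "B"
    observed <- calls != "-"
    drop <- observed & matrix(stats::runif(n_snp * n_ind) >= call_rate,
                              n_snp, n_ind)
    calls[drop] <- "-"
    observed <- calls != "-"
    if (genotype_error > 0) {
        err <- observed &
            matrix(stats::runif(n_snp * n_ind) < genotype_error, n_snp, n_ind)
        idx <- which(err)
        if (length(idx)) {
            flip <- stats::runif(length(idx)) < 0.5
            flipped <- calls[idx]
            flipped[flip] <- ifelse(flipped[flip] == "A", "B", "A")
            flipped[!flip] <- "H"
            calls[idx] <- flipped
        }
    }
    for (ind in intersect(truth@het_individuals, colnames(calls))) {
        obs <- which(calls[, ind] != "-")
        n_h <- round(het_call_fraction * length(obs))
        if (n_h > 0) calls[sample(obs, n_h), ind] <- "H"
    }
    qual <- ifelse(stats::runif(n_snp) < low_qual_fraction,
                   stats::runif(n_snp, 20, 39.9),
                   stats::runif(n_snp, 40, 255))
    placement <- snp_scaffold_map(truth)
    info <- data.frame(snp_id = snps$snp_id, scaffold = placement$scaffold,
                       pos = placement$pos, qual = round(qual, 2),
                       allele_p1 = snps$allele_p1,
                       allele_p2 = snps$allele_p2, stringsAsFactors = FALSE)
    ord <- order(info$scaffold, info$pos)
    info <- info[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    if (raw) {
        nuc <- calls
        nuc[calls == "A"] <- info$allele_p1[row(calls)[calls == "A"]]
        nuc[calls == "B"] <- info$allele_p2[row(calls)[calls == "B"]]
        het_pairs <- paste0(pmin(info$allele_p1, info$allele_p2), "/",
                            pmax(info$allele_p1, info$allele_p2))
        nuc[calls == "H"] <- het_pairs[row(calls)[calls == "H"]]
        nuc <- cbind(P1 = info$allele_p1, P2 = info$allele_p2, nuc)
        return(GenotypeMatrix(nuc, info))
    }
    GenotypeMatrix(calls, info)
}

#' Fragment a genome into scaffolds, optionally planting chimeric joins
#'
#' Cuts each chromosome into consecutive scaffolds with log-normally
#' distributed lengths (tiling the genome without overlap), then marks
#' each scaffold chimeric with probability \code{misjoin_rate}: a chimera
#' concatenates the marked scaffold with a randomly chosen scaffold from
#' a different chromosome (which is removed as a standalone scaffold).
#' Every origin segment and every planted misjoin is recorded in the
#' truth.
#'
#' @param genome parental genome (\code{DNAStringSet})
#' @param truth \linkS4class{SimTruth} to update
#' @param mean_len mean scaffold length (bp)
#' @param sd_log standard deviation of log length
#' @param min_len minimum scaffold length (bp)
#' @param misjoin_rate fraction of scaffolds converted to chimeras
#' @param seed integer seed
#' @return list with \code{scaffolds} (\code{DNAStringSet}) and the
#'   updated \code{truth}
#' @export
fragmentAssembly <- function(genome, truth, mean_len = 10000, sd_log = 0.35,
                             min_len = 500, misjoin_rate = 0, seed = 1) {
    if (misjoin_rate > 0 && length(genome) < 2)
        stop("misjoin_rate > 0 requires at least 2 chromosomes")
    set.seed(seed)
    seqs <- as.character(genome)
    origins <- list()
    for (chrom in names(seqs)) {
        len <- nchar(seqs[[chrom]])
        cuts <- integer(0)
        at <- 0L
        while (at < len) {
            piece <- max(min_len,
                         round(stats::rlnorm(1, log(mean_len), sd_log)))
            at <- min(len, at + piece)
            cuts <- c(cuts, at)
        }
        if (length(cuts) > 1 && cuts[length(cuts)] - cuts[length(cuts) - 1] < min_len)
            cuts <- cuts[-(length(cuts) - 1)] # merge a short trailing piece
        start <- c(0L, cuts[-length(cuts)])
        origins[[chrom]] <- data.frame(chrom = chrom, start = start,
                                       end = cuts, stringsAsFactors = FALSE)
    }
    origins <- do.call(rbind, origins)
    n <- nrow(origins)
    origins$scaffold_id <- sprintf("scaffold_%04d", seq_len(n))
    chim <- which(stats::runif(n) < misjoin_rate)
    partner_of <- integer(0)
    misjoins <- empty_misjoins()
    used <- rep(FALSE, n)
    for (i in chim) {
        if (used[i]) next
        candidates <- which(!used & origins$chrom != origins$chrom[i] &
                            seq_len(n) != i)
        candidates <- setdiff(candidates, chim)
        if (!length(candidates)) next
        j <- candidates[sample.int(length(candidates), 1)]
        used[i] <- used[j] <- TRUE
        partner_of[as.character(i)] <- j
        misjoins <- rbind(misjoins, data.frame(
            scaffold_id = origins$scaffold_id[i],
            chrom_a = origins$chrom[i], chrom_b = origins$chrom[j],
            stringsAsFactors = FALSE))
    }
    seq_of <- function(r) substring(seqs[[origins$chrom[r]]],
                                    origins$start[r] + 1L, origins$end[r])
    out_seq <- character(0)
    truth_rows <- list()
    consumed <- as.integer(partner_of)
    for (r in seq_len(n)) {
        if (r %in% consumed) next
        id <- origins$scaffold_id[r]
        j <- partner_of[as.character(r)]
        if (!is.na(j) && length(j)) {
            out_seq[id] <- paste0(seq_of(r), seq_of(j))
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                scaffold_id = id,
                chrom = c(origins$chrom[r], origins$chrom[j]),
                start = c(origins$start[r], origins$start[j]),
                end = c(origins$end[r], origins$end[j]),
                strand = "+", part = 1:2, chimera = TRUE,
                stringsAsFactors = FALSE)
        } else {
            out_seq[id] <- seq_of(r)
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                scaffold_id = id, chrom = origins$chrom[r],
                start = origins$start[r], end = origins$end[r],
                strand = "+", part = 1L, chimera = FALSE,
                stringsAsFactors = FALSE)
        }
    }
    scaffold_truth <- do.call(rbind, truth_rows)
    rownames(scaffold_truth) <- NULL
    truth <- methods::initialize(truth, scaffolds = scaffold_truth,
                                 misjoins = misjoins)
    list(scaffolds = Biostrings::DNAStringSet(out_seq), truth = truth)
}
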