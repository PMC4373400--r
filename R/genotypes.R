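#' Filter SNP rows of a genotype matrix
#'
#' Discards rows with quality below \code{min_quality} (strict), more
#' than \code{max_missing_fraction} missing data (strict), or a minor
#' allele frequency below \code{min_maf} (strict). MAF is computed over
#' non-missing, non-heterozygous calls. Thresholds default to the
#' published values: quality 40, missingness 90%, MAF 5%.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param min_quality minimum quality score retained
#' @param max_missing_fraction maximum tolerated missing fraction
#' @param min_maf minimum minor allele frequency
#' @return the filtered \linkS4class{GenotypeMatrix}; per-criterion
#'   removal counts are attached as \code{attr(, "removed")}
#' @export
filterVariants <- function(x, min_quality = 40, max_missing_fraction = 0.9,
                           min_maf = 0.05) {
    info <- snpInfo(x)
    calls <- genotypeCalls(x)
    progeny <- setdiff(colnames(calls), c("P1", "P2"))
    sub <- calls[, progeny, drop = FALSE]
    n_ind <- length(progeny)
    low_q <- info$qual < min_quality
    missing_frac <- rowMeans(sub == "-" | sub == "N")
    too_missing <- missing_frac > max_missing_fraction
    if (all(sub %in% CALL_ALPHABET)) { # polarized coding
        nA <- rowSums(sub == "A")
        nB <- rowSums(sub == "B")
    } else { # raw nucleotide coding: count the two parental alleles
        nA <- rowSums(sub == matrix(info$allele_p1, nrow(sub), ncol(sub)))
        nB <- rowSums(sub == matrix(info$allele_p2, nrow(sub), ncol(sub)))
    }
    maf <- ifelse(nA + nB > 0, pmin(nA, nB) / (nA + nB), NA_real_)
    low_maf <- !is.na(maf) & maf < min_maf
    drop <- low_q | too_missing | low_maf
    if (all(drop)) warning("all rows removed by filtering")
    out <- x[!drop, ]
    out <- methods::as(out, "GenotypeMatrix")
    attr(out, "removed") <- c(quality = sum(low_q),
                              missing = sum(too_missing),
                              maf = sum(low_maf), total = sum(drop))
    out
}

#' Polarize raw nucleotide genotypes against the parents
#'
#' Keeps only rows where both parents have successful homozygous calls
#' for opposite alleles; maps progeny calls onto A (= parent-1 allele)
#' and B (= parent-2 allele); progeny heterozygotes (\code{"X/Y"} calls)
#' become missing. Idempotent on already-polarized matrices.
#'
#' @param x a \linkS4class{GenotypeMatrix} with raw nucleotide cells
#' @param parent_p1,parent_p2 column names of the two parents
#' @return a polarized \linkS4class{GenotypeMatrix} (parent columns
#'   removed, row metadata alleles updated)
#' @export
polarizeGenotypes <- function(x, parent_p1 = "P1", parent_p2 = "P2") {
    calls <- genotypeCalls(x)
    info <- snpInfo(x)
    if (!all(c(parent_p1, parent_p2) %in% colnames(calls))) {
        if (all(calls %in% CALL_ALPHABET)) return(x) # already polarized
        stop("parent columns not found: ", parent_p1, ", ", parent_p2)
    }
    p1 <- calls[, parent_p1]
    p2 <- calls[, parent_p2]
    ok_parent <- function(p) p %in% c("A", "C", "G", "T")
    keep <- ok_parent(p1) & ok_parent(p2) & p1 != p2
    progeny <- setdiff(colnames(calls), c(parent_p1, parent_p2))
    sub <- calls[keep, progeny, drop = FALSE]
    p1 <- p1[keep]; p2 <- p2[keep]
    out <- matrix("-", nrow(sub), ncol(sub), dimnames = dimnames(sub))
    out[sub == matrix(p1, nrow(sub), ncol(sub))] <- "A"
    out[sub == matrix(p2, nrow(sub), ncol(sub))] <- "B"
    # polarized input passes through unchanged
    out[sub == "A" & p1 == "A"] <- "A" # (no-op, kept for clarity)
    info <- info[keep, , drop = FALSE]
    info$allele_p1 <- p1
    info$allele_p2 <- p2
    GenotypeMatrix(out, info)
}

#' Scaffold consensus genotypes
#'
#' For every scaffold and individual, the majority allele over the
#' individual's non-missing calls on the scaffold, assigned only when the
#' individual has at least \code{min_calls} successful calls and the
#' majority fraction is at least \code{min_concordance} (inclusive);
#' otherwise missing. H calls never contribute.
#'
#' @param x a polarized \linkS4class{GenotypeMatrix}
#' @param min_calls minimum successful calls per individual per scaffold
#' @param min_concordance minimum majority fraction (inclusive)
#' @return a \linkS4class{ConsensusGenotypes} (one unit per scaffold)
#' @export
scaffoldConsensus <- function(x, min_calls = 3, min_concordance = 0.95) {
    calls <- genotypeCalls(x)
    info <- snpInfo(x)
    scaffolds <- sort(unique(info$scaffold))
    n_ind <- ncol(calls)
    cons <- matrix("-", length(scaffolds), n_ind,
                   dimnames = list(scaffolds, colnames(calls)))
    stats_list <- vector("list", length(scaffolds))
    for (si in seq_along(scaffolds)) {
        rows <- info$scaffold == scaffolds[si]
        sub <- calls[rows, , drop = FALSE]
        nA <- colSums(sub == "A")
        nB <- colSums(sub == "B")
        n <- nA + nB
        major <- ifelse(nA >= nB, "A", "B")
        frac <- ifelse(n > 0, pmax(nA, nB) / n, 0)
        assign_ok <- n >= min_calls & frac >= min_concordance
        cons[si, assign_ok] <- major[assign_ok]
        stats_list[[si]] <- data.frame(
            unit_id = scaffolds[si], n_sites = sum(rows),
            n_A = sum(cons[si, ] == "A"), n_B = sum(cons[si, ] == "B"),
            n_missing = sum(cons[si, ] == "-"), stringsAsFactors = FALSE)
    }
    methods::new("ConsensusGenotypes", calls = cons,
                 stats = do.call(rbind, stats_list))
}

#' Select candidate framework units
#'
#' Retains consensus units with at least \code{min_calls_per_allele}
#' calls of each parental allele and at most \code{max_missing_calls}
#' missing calls (the published rule: at least 10 calls per allele and
#' fewer than four missing).
#'
#' @param cons a \linkS4class{ConsensusGenotypes}
#' @param min_calls_per_allele minimum A calls and minimum B calls
#' @param max_missing_calls maximum missing calls (inclusive)
#' @return a \linkS4class{ConsensusGenotypes} restricted to candidates
#' @export
selectFramework <- function(cons, min_calls_per_allele = 10,
                            max_missing_calls = 3) {
    st <- cons@stats
    keep <- st$n_A >= min_calls_per_allele & st$n_B >= min_calls_per_allele &
            st$n_missing <= max_missing_calls
    methods::new("ConsensusGenotypes",
                 calls = cons@calls[keep, , drop = FALSE],
                 stats = st[keep, , drop = FALSE])
}

#' Hamming distance between genotype vectors under the missing-skip policy
#'
#' Counts positions where both calls are non-missing (and not H) and
#' differ; also reports the number of mutually observed positions.
#'
#' @param v1,v2 equal-length call vectors over A/B/H/-
#' @return named numeric: \code{distance}, \code{n_compared}
#' @export
hammingDistance <- function(v1, v2) {
    if (length(v1) != length(v2)) stop("vectors differ in length")
    obs <- v1 %in% c("A", "B") & v2 %in% c("A", "B")
    c(distance = sum(v1[obs] != v2[obs]), n_compared = sum(obs))
}

#' Bin markers with identical segregation
#'
#' Groups units at pairwise Hamming distance 0 (missing-skip policy) into
#' recombination bins. Because ignore-missing distance 0 is not
#' transitive, units are processed greedily in a fixed order (descending
#' number of non-missing calls, ties by unit id) and a unit joins the
#' first bin to whose every member it has distance 0; this keeps all bins
#' internally pairwise-consistent and the result deterministic. The bin
#' representative is the member with the fewest missing calls, ties by
#' lexicographic unit id.
#'
#' @param units character call matrix, units x individuals (rownames =
#'   unit ids), or a \linkS4class{ConsensusGenotypes}
#' @return data.frame: bin_id, representative, unit_id (one row per
#'   member), plus \code{attr(, "representative_calls")} matrix
#' @export
binMarkers <- function(units) {
    if (methods::is(units, "ConsensusGenotypes")) units <- units@calls
    n <- nrow(units)
    if (!n) stop("no units to bin")
    n_obs <- rowSums(units == "A" | units == "B")
    ord <- order(-n_obs, rownames(units))
    m <- units[ord, , drop = FALSE]
    pc <- pair_counts(m)
    bins <- list() # member row indices into m
    for (i in seq_len(n)) {
        placed <- FALSE
        for (b in seq_along(bins)) {
            if (all(pc$D[i, bins[[b]]] == 0)) {
                bins[[b]] <- c(bins[[b]], i)
                placed <- TRUE
                break
            }
        }
        if (!placed) bins[[length(bins) + 1L]] <- i
    }
    n_missing <- rowSums(!(m == "A" | m == "B"))
    res <- lapply(seq_along(bins), function(b) {
        ids <- rownames(m)[bins[[b]]]
        rep_id <- ids[order(n_missing[bins[[b]]], ids)][1]
        data.frame(bin_id = sprintf("bin_%04d", b), representative = rep_id,
                   unit_id = ids, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    reps <- unique(out[, c("bin_id", "representative")])
    rep_calls <- m[reps$representative, , drop = FALSE]
    rownames(rep_calls) <- reps$bin_id
    attr(out, "representative_calls") <- rep_calls
    out
}

#' Screen individuals with outlying missingness (chromosome-arm loss)
#'
#' Individuals that lost a chromosome arm (or carry pervasive
#' heterozygosity, which polarization turns into missing data) show an
#' outlying fraction of missing consensus calls. The published map
#' construction excluded such individuals (12 of 90) before building the
#' final framework. An individual is flagged when its missing fraction
#' exceeds \code{median + n_mad * MAD} across individuals and the
#' absolute floor \code{min_fraction}.
#'
#' @param cons a \linkS4class{ConsensusGenotypes}
#' @param n_mad outlier multiplier
#' @param min_fraction absolute floor, guards against a degenerate MAD
#' @return character vector of excluded individual ids
#' @export
screenIndividuals <- function(cons, n_mad = 3, min_fraction = 0.05) {
    calls <- if (methods::is(cons, "ConsensusGenotypes")) cons@calls else cons
    miss <- colMeans(calls == "-")
    cutoff <- max(stats::median(miss) + n_mad * stats::mad(miss),
                  min_fraction)
    colnames(calls)[miss > cutoff]
}

# Majority-vote consensus call vector per bin ("super-marker"): combining
# the sparse calls of co-segregating members yields a near-complete
# haplotype vector. Ties and H calls give missing.
bin_consensus_calls <- function(bins, calls) {
    bin_ids <- unique(bins$bin_id)
    out <- matrix("-", length(bin_ids), ncol(calls),
                  dimnames = list(bin_ids, colnames(calls)))
    for (b in seq_along(bin_ids)) {
        sub <- calls[bins$unit_id[bins$bin_id == bin_ids[b]], , drop = FALSE]
        nA <- colSums(sub == "A")
        nB <- colSums(sub == "B")
        out[b, nA > nB] <- "A"
        out[b, nB > nA] <- "B"
    }
    out
}
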