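#' Anchor scaffold consensus genotypes onto a framework map
#'
#' Nearest-neighbour genotype search: for each scaffold consensus vector,
#' all framework bin representatives at minimal Hamming distance
#' (missing-skip policy) form the neighbour set. Rejection rules are
#' applied in the published order: more than \code{max_missing} missing
#' calls (fraction) rejects; fewer than \code{min_calls} successful calls
#' rejects; nearest distance above \code{max_hamming} rejects; less than
#' \code{min_chrom_agreement} of the neighbours on one linkage group
#' rejects; a median absolute deviation of neighbour positions above
#' \code{max_mad_cM} rejects. Anchored position is the median cM of the
#' neighbours on the winning linkage group.
#'
#' @param cons \linkS4class{ConsensusGenotypes} of the scaffolds (built
#'   with \code{min_calls = 1} per the published anchoring variant)
#' @param map a \linkS4class{GeneticMap}
#' @param max_hamming maximum nearest-neighbour Hamming distance
#' @param min_chrom_agreement minimum fraction of neighbours on one group
#' @param max_mad_cM maximum MAD of neighbour positions (cM)
#' @param max_missing maximum fraction of missing calls
#' @param min_calls minimum successful calls
#' @return data.frame: scaffold_id, linkage_group, position_cM,
#'   n_nearest, hamming, agreement, mad_cM, status
#' @export
anchorScaffolds <- function(cons, map, max_hamming = 3,
                            min_chrom_agreement = 0.9, max_mad_cM = 5,
                            max_missing = 0.7, min_calls = 1) {
    fw <- mapVectors(map)
    if (!nrow(fw)) stop("empty framework map")
    tab <- mapTable(map)
    calls <- if (methods::is(cons, "ConsensusGenotypes")) cons@calls else cons
    stopifnot(ncol(calls) == ncol(fw))
    pc <- pair_counts(calls, fw)
    n_ind <- ncol(calls)
    n_called <- rowSums(calls == "A" | calls == "B")
    out <- data.frame(scaffold_id = rownames(calls),
                      linkage_group = NA_character_, position_cM = NA_real_,
                      n_nearest = NA_integer_, hamming = NA_real_,
                      agreement = NA_real_, mad_cM = NA_real_,
                      status = "anchored", stringsAsFactors = FALSE)
    bin_lg <- stats::setNames(tab$linkage_group, tab$bin_id)
    bin_pos <- stats::setNames(tab$position_cM, tab$bin_id)
    for (i in seq_len(nrow(calls))) {
        if (1 - n_called[i] / n_ind > max_missing) {
            out$status[i] <- "rejected:missing"
            next
        }
        if (n_called[i] < min_calls) {
            out$status[i] <- "rejected:no-calls"
            next
        }
        d <- pc$D[i, ]
        dmin <- min(d)
        out$hamming[i] <- dmin
        if (dmin > max_hamming) {
            out$status[i] <- "rejected:distance"
            next
        }
        nn <- colnames(pc$D)[d == dmin] %||% rownames(fw)[d == dmin]
        out$n_nearest[i] <- length(nn)
        lgs <- bin_lg[nn]
        lg_tab <- sort(table(lgs), decreasing = TRUE)
        agreement <- lg_tab[1] / length(nn)
        out$agreement[i] <- agreement
        if (agreement < min_chrom_agreement) {
            out$status[i] <- "rejected:agreement"
            next
        }
        win <- names(lg_tab)[1]
        pos <- bin_pos[nn[lgs == win]]
        mad_pos <- stats::median(abs(pos - stats::median(pos)))
        out$mad_cM[i] <- mad_pos
        if (mad_pos > max_mad_cM) {
            out$status[i] <- "rejected:mad"
            next
        }
        out$linkage_group[i] <- win
        out$position_cM[i] <- stats::median(pos)
    }
    out
}

#' Anchor scaffolds via uniquely placed k-mer markers
#'
#' Assigns each scaffold to the linkage group holding the majority of
#' its placed, mapped markers, at the median cM of those markers.
#' Scaffolds whose markers span two or more linkage groups are emitted
#' as conflicts (candidate chimeras).
#'
#' @param placements output of [placeMarkersOnScaffolds()]
#' @param marker_map data.frame: marker_id, linkage_group, position_cM
#'   (genetic positions of the markers, e.g. their bin positions)
#' @return list: \code{anchors} (scaffold_id, linkage_group, position_cM,
#'   n_markers, n_groups), \code{conflicts} (subset spanning >= 2 groups)
#' @export
anchorByMarkers <- function(placements, marker_map) {
    placed <- placements[placements$status == "placed", , drop = FALSE]
    merged <- merge(placed, marker_map, by = "marker_id")
    if (!nrow(merged))
        return(list(anchors = data.frame(), conflicts = data.frame()))
    split_sc <- split(merged, merged$scaffold)
    rows <- lapply(split_sc, function(d) {
        lg_tab <- sort(table(d$linkage_group), decreasing = TRUE)
        win <- names(lg_tab)[1]
        data.frame(scaffold_id = d$scaffold[1], linkage_group = win,
                   position_cM = stats::median(
                       d$position_cM[d$linkage_group == win]),
                   n_markers = nrow(d), n_groups = length(lg_tab),
                   stringsAsFactors = FALSE)
    })
    anchors <- do.call(rbind, rows)
    rownames(anchors) <- NULL
    list(anchors = anchors,
         conflicts = anchors[anchors$n_groups >= 2, , drop = FALSE])
}

#' Map individual SNP rows of a genotype matrix onto a framework map
#'
#' Anchors every SNP's own call vector to its nearest framework
#' neighbour(s), yielding a per-scaffold table of mapped markers with
#' scaffold offsets, as input for [detectMisjoins()].
#'
#' @param x a polarized \linkS4class{GenotypeMatrix}
#' @param map a \linkS4class{GeneticMap}
#' @param max_hamming maximum nearest-neighbour distance for a SNP to map
#' @return data.frame: marker_id, scaffold, offset, linkage_group,
#'   position_cM
#' @export
mappedMarkersFromMatrix <- function(x, map, max_hamming = 3) {
    calls <- genotypeCalls(x)
    info <- snpInfo(x)
    anch <- anchorScaffolds(calls, map, max_hamming = max_hamming,
                            min_chrom_agreement = 0, max_mad_cM = Inf,
                            max_missing = 1, min_calls = 1)
    ok <- anch$status == "anchored"
    data.frame(marker_id = info$snp_id[ok], scaffold = info$scaffold[ok],
               offset = info$pos[ok], linkage_group = anch$linkage_group[ok],
               position_cM = anch$position_cM[ok], stringsAsFactors = FALSE)
}

#' Detect candidate mis-joins (chimeric scaffolds)
#'
#' Flags scaffolds whose terminal mapped markers (smallest and largest
#' scaffold offset) lie on different linkage groups, or farther apart
#' than \code{intra_scaffold_max_cM} on the same group. Only scaffolds
#' with at least two mapped markers are assessable.
#'
#' @param mapped per-scaffold mapped markers: scaffold, offset,
#'   linkage_group, position_cM (e.g. from [mappedMarkersFromMatrix()] or
#'   a merge of marker placements with map positions)
#' @param intra_scaffold_max_cM maximum tolerated terminal separation
#' @param scaffold_lengths optional named lengths (bp) for the per-Mbp rate
#' @return data.frame of assessable scaffolds with columns scaffold_id,
#'   lg_start, lg_end, span_cM, flagged, reason; rates are attached as
#'   \code{attr(, "rates")}
#' @export
detectMisjoins <- function(mapped, intra_scaffold_max_cM = 5,
                           scaffold_lengths = NULL) {
    split_sc <- split(mapped, mapped$scaffold)
    split_sc <- split_sc[vapply(split_sc, nrow, integer(1)) >= 2]
    rows <- lapply(split_sc, function(d) {
        d <- d[order(d$offset), , drop = FALSE]
        first <- d[1, ]
        last <- d[nrow(d), ]
        diff_lg <- first$linkage_group != last$linkage_group
        span <- if (diff_lg) NA_real_
                else abs(last$position_cM - first$position_cM)
        flagged <- diff_lg || (!is.na(span) && span > intra_scaffold_max_cM)
        data.frame(scaffold_id = d$scaffold[1],
                   lg_start = first$linkage_group, lg_end = last$linkage_group,
                   span_cM = span, flagged = flagged,
                   reason = if (diff_lg) "linkage-group" else
                            if (flagged) "distance" else "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(
        scaffold_id = character(), lg_start = character(),
        lg_end = character(), span_cM = numeric(), flagged = logical(),
        reason = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    rates <- c(per_scaffold = if (nrow(out)) mean(out$flagged) else NA)
    if (!is.null(scaffold_lengths)) {
        mbp <- sum(scaffold_lengths[out$scaffold_id], na.rm = TRUE) / 1e6
        rates <- c(rates, per_mbp = sum(out$flagged) / mbp)
    }
    attr(out, "rates") <- rates
    out
}

#' Collinearity between two maps of shared items
#'
#' Matches linkage groups between the maps by modal co-occurrence, then
#' reports the chromosome-assignment agreement fraction and the signed
#' Spearman rank correlation of positions within each matched group (a
#' negative correlation denotes a reversed group, not an error).
#'
#' @param a,b data.frames with columns id, linkage_group, position_cM
#' @return list: \code{agreement}, \code{per_group} (data.frame with
#'   group pair, n and rho), \code{overall_rho} (median |rho| weighted
#'   by size is left to the caller; this is the n-weighted mean of |rho|)
#' @export
collinearity <- function(a, b) {
    shared <- merge(a, b, by = "id", suffixes = c("_a", "_b"))
    if (nrow(shared) < 2) stop("fewer than 2 shared items")
    match_tab <- table(shared$linkage_group_a, shared$linkage_group_b)
    modal <- colnames(match_tab)[apply(match_tab, 1, which.max)]
    names(modal) <- rownames(match_tab)
    agree <- shared$linkage_group_b == modal[shared$linkage_group_a]
    per_group <- lapply(split(shared[agree, , drop = FALSE],
                              shared$linkage_group_a[agree]), function(d) {
        if (nrow(d) < 2) return(NULL)
        rho <- suppressWarnings(stats::cor(d$position_cM_a, d$position_cM_b,
                                           method = "spearman"))
        data.frame(group_a = d$linkage_group_a[1],
                   group_b = d$linkage_group_b[1], n = nrow(d), rho = rho,
                   stringsAsFactors = FALSE)
    })
    per_group <- do.call(rbind, per_group)
    rownames(per_group) <- NULL
    overall <- if (!is.null(per_group) && nrow(per_group))
        sum(abs(per_group$rho) * per_group$n, na.rm = TRUE) /
            sum(per_group$n[!is.na(per_group$rho)]) else NA_real_
    list(agreement = mean(agree), per_group = per_group,
         overall_rho = overall)
}

#' Segregation-distortion scan over map bins
#'
#' Per bin, the parent-1 allele frequency among non-missing calls of the
#' representative vector, with a two-sided exact binomial test against
#' the 1:1 DH expectation and a Bonferroni-adjusted flag. Bins with
#' fewer than \code{min_informative} calls are excluded from testing.
#'
#' @param map a \linkS4class{GeneticMap}
#' @param alpha family-wise significance level (Bonferroni)
#' @param min_informative minimum informative calls per tested bin
#' @return data.frame: bin_id, linkage_group, position_cM, n, freq_A,
#'   p_value, flagged
#' @export
segregationDistortion <- function(map, alpha = 0.05, min_informative = 10) {
    tab <- mapTable(map)
    vec <- mapVectors(map)
    nA <- rowSums(vec == "A")
    nB <- rowSums(vec == "B")
    n <- nA + nB
    keep <- n >= min_informative
    p <- rep(NA_real_, nrow(tab))
    p[keep] <- vapply(which(keep), function(i)
        stats::binom.test(nA[i], n[i], 0.5)$p.value, numeric(1))
    n_tests <- sum(keep)
    data.frame(bin_id = tab$bin_id, linkage_group = tab$linkage_group,
               position_cM = tab$position_cM, n = n,
               freq_A = ifelse(n > 0, nA / n, NA),
               p_value = p,
               flagged = !is.na(p) & p < alpha / max(n_tests, 1),
               stringsAsFactors = FALSE)
}
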