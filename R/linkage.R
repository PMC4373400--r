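#' Two-point linkage statistics for a DH marker pair
#'
#' Over the mutually observed individuals, recombinants are
#' \code{min(d, n - d)} where d counts discordant (A vs B) calls: a
#' repulsion-phase pair co-segregates with alleles swapped, so phase is
#' resolved toward the smaller count. The LOD score is the log10
#' likelihood ratio of linkage at the estimated recombination fraction
#' rf = r/n versus independence (rf = 0.5):
#' \deqn{LOD = r \log_{10} rf + (n-r) \log_{10}(1-rf) + n \log_{10} 2}
#' with the 0*log(0) = 0 convention, so perfect co-segregation gives
#' exactly n*log10(2).
#'
#' @param v1,v2 equal-length call vectors (A/B/H/-)
#' @return named numeric: r, n, rf, lod (all NA when n = 0)
#' @export
twoPoint <- function(v1, v2) {
    if (length(v1) != length(v2)) stop("vectors differ in length")
    obs <- v1 %in% c("A", "B") & v2 %in% c("A", "B")
    n <- sum(obs)
    if (n == 0) return(c(r = NA, n = 0, rf = NA, lod = NA))
    d <- sum(v1[obs] != v2[obs])
    r <- min(d, n - d)
    rf <- r / n
    lod <- lod_score(r, n)
    c(r = r, n = n, rf = rf, lod = lod)
}

lod_score <- function(r, n) {
    rf <- r / n
    t1 <- ifelse(r > 0, r * log10(rf), 0)
    t2 <- ifelse(n - r > 0, (n - r) * log10(1 - rf), 0)
    t1 + t2 + n * log10(2)
}

#' All-pairs two-point statistics between rows of call matrices
#'
#' Vectorized counterpart of [twoPoint()]: returns recombinant counts,
#' informative counts, recombination fractions and LOD scores for every
#' row pair.
#'
#' @param a call matrix (units x individuals)
#' @param b optional second matrix (defaults to \code{a})
#' @return list of matrices r, n, rf, lod
#' @export
pairwiseLinkage <- function(a, b = a) {
    pc <- pair_counts(a, b)
    N <- pc$N
    R <- pmin(pc$D, N - pc$D)
    RF <- ifelse(N > 0, R / N, NA)
    T1 <- ifelse(!is.na(RF) & R > 0, R * log10(RF), 0)
    T2 <- ifelse(!is.na(RF) & N - R > 0, (N - R) * log10(1 - RF), 0)
    LOD <- ifelse(N > 0, T1 + T2 + N * log10(2), NA)
    list(r = R, n = N, rf = RF, lod = LOD)
}

#' Cluster markers into linkage groups by LOD threshold
#'
#' Units with at least \code{min_informative} non-missing calls are
#' clustered by single linkage: connected components of the graph with an
#' edge wherever the pairwise LOD is at least \code{lod_threshold}
#' (published threshold: 9). Components are returned in decreasing size;
#' singletons are reported separately.
#'
#' @param units call matrix (units x individuals) or
#'   \linkS4class{ConsensusGenotypes}
#' @param lod_threshold minimum LOD for an edge
#' @param min_informative minimum non-missing calls per unit; default
#'   half the individuals (the published screen kept markers with calls
#'   in at least 46 of 88 individuals)
#' @return list: \code{clusters} (list of unit-id vectors, decreasing
#'   size), \code{singletons}, \code{dropped} (failed min_informative)
#' @export
clusterMarkers <- function(units, lod_threshold = 9, min_informative = NULL) {
    if (methods::is(units, "ConsensusGenotypes")) units <- units@calls
    if (is.null(min_informative)) min_informative <- ceiling(ncol(units) / 2)
    n_obs <- rowSums(units == "A" | units == "B")
    dropped <- rownames(units)[n_obs < min_informative]
    m <- units[n_obs >= min_informative, , drop = FALSE]
    if (!nrow(m)) return(list(clusters = list(), singletons = character(),
                              dropped = dropped))
    pl <- pairwiseLinkage(m)
    adj <- !is.na(pl$lod) & pl$lod >= lod_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    groups <- split(rownames(m), comp$membership)
    sizes <- lengths(groups)
    groups <- groups[order(-sizes, vapply(groups, min, character(1)))]
    singletons <- unlist(groups[lengths(groups) == 1], use.names = FALSE)
    list(clusters = unname(groups[lengths(groups) > 1]),
         singletons = singletons %||% character(0), dropped = dropped)
}

#' Kosambi map function
#'
#' Maps a recombination fraction to genetic distance,
#' d = 25 ln((1 + 2rf) / (1 - 2rf)) cM, accounting for moderate crossover
#' interference.
#'
#' @param rf recombination fraction(s) in [0, 0.5)
#' @return distance in cM
#' @export
kosambi <- function(rf) {
    if (any(rf < 0 | rf >= 0.5)) stop("rf must lie in [0, 0.5)")
    25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' Haldane map function (no interference)
#'
#' @param rf recombination fraction(s) in [0, 0.5)
#' @return distance in cM
#' @export
haldane <- function(rf) {
    if (any(rf < 0 | rf >= 0.5)) stop("rf must lie in [0, 0.5)")
    -50 * log(1 - 2 * rf)
}

# Ordering objective: total adjacent recombinant counts; non-informative
# adjacencies are penalized so they are never chosen over informative ones.
order_objective <- function(ord, R, N) {
    if (length(ord) < 2) return(0)
    i <- ord[-length(ord)]
    j <- ord[-1]
    cost <- R[cbind(i, j)]
    pen <- max(N, 1)
    sum(ifelse(N[cbind(i, j)] > 0, cost, pen))
}

#' Order the bins of one linkage group
#'
#' Re-implements the function of MST-based map ordering: build the
#' maximum-LOD spanning tree of the bins, extract its longest path as a
#' backbone, insert off-path bins at the adjacent position minimizing the
#' objective (total adjacent recombinant count), then refine with
#' deterministic 2-opt segment reversals until no improving move remains.
#' The final orientation places the lexicographically smaller terminal
#' bin first.
#'
#' @param vectors call matrix of bin representatives (rownames = bin ids)
#' @return character vector of bin ids in map order
#' @export
orderBins <- function(vectors) {
    ids <- rownames(vectors)
    n <- length(ids)
    if (n == 1) return(ids)
    pl <- pairwiseLinkage(vectors)
    R <- pl$r; N <- pl$n; LOD <- pl$lod
    if (any(is.na(LOD[upper.tri(LOD)])) &&
        all(is.na(LOD[upper.tri(LOD)])))
        stop("bins share no informative individuals")
    W <- -LOD
    W[is.na(W)] <- max(W, na.rm = TRUE) + 1
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if (igraph::components(g)$no > 1) stop("disconnected cluster")
    tree <- igraph::mst(g)
    path <- as.integer(igraph::get_diameter(tree, weights = NA))
    remaining <- setdiff(seq_len(n), path)
    # deterministic insertion order: strongest linkage to the backbone first
    if (length(remaining)) {
        strength <- vapply(remaining, function(i)
            max(LOD[i, path], na.rm = TRUE), numeric(1))
        remaining <- remaining[order(-strength, ids[remaining])]
        for (i in remaining) {
            best <- NULL
            best_obj <- Inf
            for (slot in seq_len(length(path) + 1L)) {
                cand <- append(path, i, after = slot - 1L)
                obj <- order_objective(cand, R, N)
                if (obj < best_obj) { best_obj <- obj; best <- cand }
            }
            path <- best
        }
    }
    # 2-opt refinement
    improved <- TRUE
    sweeps <- 0L
    while (improved && sweeps < 200L) {
        improved <- FALSE
        sweeps <- sweeps + 1L
        cur <- order_objective(path, R, N)
        for (i in seq_len(length(path) - 1L)) {
            for (j in seq(i + 1L, length(path))) {
                cand <- path
                cand[i:j] <- rev(cand[i:j])
                obj <- order_objective(cand, R, N)
                if (obj < cur - 1e-9) {
                    path <- cand
                    cur <- obj
                    improved <- TRUE
                }
            }
        }
    }
    out <- ids[path]
    if (out[length(out)] < out[1]) out <- rev(out)
    out
}

#' Cumulative Kosambi positions for ordered bins
#'
#' Adjacent-bin recombination fractions converted by [kosambi()] and
#' accumulated from 0. Adjacent rf values of 0.5 or above (possible only
#' for uninformative adjacencies) are clamped to 0.499.
#'
#' @param vectors call matrix of bin representatives
#' @param order bin ids in map order (default [orderBins()])
#' @return data.frame: bin_id, position_cM
#' @export
mapPositions <- function(vectors, order = orderBins(vectors)) {
    m <- vectors[order, , drop = FALSE]
    if (nrow(m) == 1)
        return(data.frame(bin_id = order, position_cM = 0))
    rf <- numeric(nrow(m) - 1L)
    for (i in seq_along(rf)) {
        tp <- twoPoint(m[i, ], m[i + 1L, ])
        rf[i] <- if (is.na(tp["rf"])) 0.499 else min(tp[["rf"]], 0.499)
    }
    data.frame(bin_id = order, position_cM = c(0, cumsum(kosambi(rf))))
}

#' Build a framework genetic map from consensus genotypes
#'
#' Composition of the full published procedure: framework candidate
#' selection (calls per allele, missingness), Hamming-0 binning, LOD
#' clustering of bin representatives into linkage groups, MST-path
#' ordering and cumulative Kosambi positions. Linkage groups are named
#' LG1, LG2, ... in decreasing bin count.
#'
#' @param cons a \linkS4class{ConsensusGenotypes}
#' @param lod_threshold LOD threshold for linkage-group clustering
#' @param min_calls_per_allele,max_missing_calls framework selection
#'   thresholds (see [selectFramework()])
#' @param min_informative minimum informative calls for clustering
#' @return a \linkS4class{GeneticMap}
#' @export
buildFrameworkMap <- function(cons, lod_threshold = 9,
                              min_calls_per_allele = 10,
                              max_missing_calls = 3,
                              min_informative = NULL) {
    fw <- selectFramework(cons, min_calls_per_allele, max_missing_calls)
    if (!nrow(fw@calls)) stop("no framework candidates survive selection")
    bins <- binMarkers(fw)
    rep_calls <- attr(bins, "representative_calls")
    cl <- clusterMarkers(rep_calls, lod_threshold = lod_threshold,
                         min_informative = min_informative)
    groups <- c(cl$clusters, as.list(cl$singletons))
    if (!length(groups)) stop("no linkage groups formed")
    tab_list <- vector("list", length(groups))
    members <- split(bins$unit_id, bins$bin_id)
    bin_rep <- stats::setNames(bins$representative, bins$bin_id)
    for (gi in seq_along(groups)) {
        bin_ids <- groups[[gi]]
        sub <- rep_calls[bin_ids, , drop = FALSE]
        pos <- mapPositions(sub)
        tab_list[[gi]] <- data.frame(
            linkage_group = paste0("LG", gi), position_cM = pos$position_cM,
            bin_id = pos$bin_id,
            representative = unname(bin_rep[pos$bin_id]),
            n_members = lengths(members)[pos$bin_id],
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, tab_list)
    rownames(tab) <- NULL
    methods::new("GeneticMap", table = tab,
                 vectors = rep_calls[tab$bin_id, , drop = FALSE],
                 members = members[unique(tab$bin_id)],
                 params = list(lod_threshold = lod_threshold,
                               min_calls_per_allele = min_calls_per_allele,
                               max_missing_calls = max_missing_calls))
}
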