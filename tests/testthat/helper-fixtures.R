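# Shared fixtures: all built in code, seeded.

# A small call matrix with known segregation patterns.
toy_call_matrix <- function() {
    m <- rbind(
        u1 = c("A", "A", "B", "B", "A", "B"),
        u2 = c("A", "A", "B", "B", "A", "B"),
        u3 = c("A", "A", "B", "B", "-", "B"),
        u4 = c("B", "A", "B", "A", "A", "B"))
    colnames(m) <- paste0("I", 1:6)
    m
}

# Random DH call matrices for property-style loops: n_mark markers on one
# chromosome of len cM, n individuals, optional missing fraction.
random_dh_calls <- function(n_mark, n_ind, len_cM = 100, missing = 0,
                            seed = 1, even = FALSE) {
    set.seed(seed)
    pos <- if (even) seq(0, len_cM, length.out = n_mark)
           else sort(runif(n_mark, 0, len_cM))
    calls <- matrix("-", n_mark, n_ind,
                    dimnames = list(sprintf("m%03d", seq_len(n_mark)),
                                    sprintf("I%03d", seq_len(n_ind))))
    for (i in seq_len(n_ind)) {
        n_xo <- rpois(1, len_cM / 100)
        bp <- sort(runif(n_xo, 0, len_cM))
        parent <- (sample(0:1, 1) + findInterval(pos, bp)) %% 2
        calls[, i] <- ifelse(parent == 0, "A", "B")
    }
    if (missing > 0) {
        drop <- matrix(runif(n_mark * n_ind) < missing, n_mark, n_ind)
        calls[drop] <- "-"
    }
    attr(calls, "true_pos") <- pos
    calls
}

# Independent canonical k-mer counting oracle built on Biostrings.
oracle_count_kmers <- function(seqs, k, min_count = 1) {
    all_kmers <- unlist(lapply(as.character(seqs), function(s) {
        if (nchar(s) < k) return(character(0))
        substring(s, seq_len(nchar(s) - k + 1), k:nchar(s))
    }))
    all_kmers <- all_kmers[!grepl("[^ACGT]", all_kmers)]
    if (!length(all_kmers)) return(integer(0))
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(all_kmers)))
    canon <- pmin(all_kmers, rc)
    tab <- table(canon)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[out >= min_count]
}

# Brute-force marker-pair discovery oracle: enumerate every oriented
# (k-1)-mer prefix group over the union of the three tables.
oracle_discover <- function(t1, t2, t3, window, pmin_own = 5, pmax_other = 0) {
    k <- kmerLength(t1)
    u <- sort(unique(c(names(kmerCounts(t1)), names(kmerCounts(t2)),
                       names(kmerCounts(t3)))))
    cnt <- function(tab, km) {
        x <- kmerCounts(tab)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(km)))
        canon <- pmin(km, rc)
        out <- unname(x[canon])
        out[is.na(out)] <- 0L
        out
    }
    rows <- data.frame(oriented = c(u, as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))),
        canonical = c(u, u), stringsAsFactors = FALSE)
    rows$prefix <- substr(rows$oriented, 1, k - 1)
    rows$last <- substr(rows$oriented, k, k)
    rows$c1 <- cnt(t1, rows$oriented)
    rows$c2 <- cnt(t2, rows$oriented)
    rows$cp <- cnt(t3, rows$oriented)
    found <- list()
    for (pref in unique(rows$prefix)) {
        g <- rows[rows$prefix == pref, ]
        if (nrow(g) != 2) next
        if (g$last[1] == g$last[2] || g$canonical[1] == g$canonical[2]) next
        own <- function(i) {
            p1 <- g$c1[i] >= pmin_own && g$c2[i] <= pmax_other
            p2 <- g$c2[i] >= pmin_own && g$c1[i] <= pmax_other
            if (p1 && !p2) "P1" else if (p2 && !p1) "P2" else NA
        }
        o1 <- own(1); o2 <- own(2)
        if (is.na(o1) || is.na(o2) || o1 == o2) next
        if (any(g$cp < window[1] | g$cp > window[2])) next
        found[[length(found) + 1]] <- data.frame(
            prefix = pref, alleles = paste(sort(g$last), collapse = "/"),
            stringsAsFactors = FALSE)
    }
    if (!length(found)) return(data.frame(prefix = character(),
                                          alleles = character()))
    do.call(rbind, found)
}

# Brute-force greedy Hamming-0 binning with the same fixed order policy,
# written independently of the package internals.
oracle_bin <- function(calls) {
    ham <- function(a, b) {
        obs <- a %in% c("A", "B") & b %in% c("A", "B")
        sum(a[obs] != b[obs])
    }
    n_obs <- apply(calls, 1, function(v) sum(v %in% c("A", "B")))
    ord <- order(-n_obs, rownames(calls))
    ids <- rownames(calls)[ord]
    bins <- list()
    for (id in ids) {
        placed <- FALSE
        for (b in seq_along(bins)) {
            if (all(vapply(bins[[b]], function(o)
                ham(calls[id, ], calls[o, ]) == 0, logical(1)))) {
                bins[[b]] <- c(bins[[b]], id)
                placed <- TRUE
                break
            }
        }
        if (!placed) bins[[length(bins) + 1]] <- id
    }
    bins
}

# Brute-force single-linkage clustering at a LOD threshold (union-find).
oracle_single_linkage <- function(calls, lod_threshold) {
    n <- nrow(calls)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1) {
        for (i in seq_len(n - 1)) {
            for (j in seq(i + 1, n)) {
                tp <- twoPoint(calls[i, ], calls[j, ])
                if (!is.na(tp["lod"]) && tp[["lod"]] >= lod_threshold) {
                    ri <- find(i); rj <- find(j)
                    if (ri != rj) parent[ri] <- rj
                }
            }
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    unname(lapply(split(rownames(calls), roots), sort))
}
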