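#' Count canonical k-mers in a read set
#'
#' Exact multiplicities of canonical k-mers (lexicographic minimum of a
#' k-mer and its reverse complement). k-mers containing non-ACGT
#' characters are skipped; k must be odd (even k makes canonical form
#' ambiguous for palindromes) and at most 63.
#'
#' @param reads a \code{DNAStringSet}, character vector, or list of such
#' @param k odd k-mer length, 1..63
#' @param min_count discard k-mers seen fewer than this many times
#' @param source label stored on the table
#' @return a \linkS4class{KmerTable}
#' @export
countKmers <- function(reads, k, min_count = 1, source = "reads") {
    k <- as.integer(k)
    if (k < 1L || k > 63L) stop("k must be between 1 and 63")
    if (k %% 2L == 0L) stop("k must be odd (canonicalization ambiguity)")
    if (!is.list(reads)) reads <- list(reads)
    reads <- unlist(lapply(reads, as.character), use.names = FALSE)
    res <- cpp_count_kmers(reads %||% character(0), k, as.integer(min_count))
    methods::new("KmerTable", k = k, source = source,
                 kmers = as.character(res$kmer),
                 counts = as.integer(res$count))
}

canonical_kmers <- function(x) {
    rc <- revcomp(x)
    pmin(x, rc)
}

# Look up counts of arbitrary k-mers (any orientation) in a KmerTable.
lookup_counts <- function(table, kmers) {
    idx <- match(canonical_kmers(kmers), table@kmers)
    counts <- table@counts[idx]
    counts[is.na(counts)] <- 0L
    counts
}

#' Pool-frequency window from expected homozygous k-mer depth
#'
#' The published discovery screen kept alleles seen 40 to 50 times in
#' pooled population reads of roughly 90-fold homozygous k-mer depth,
#' i.e. a window of about 0.44 to 0.56 of the homozygous pool depth
#' (each allele segregates 1:1, so is expected near half). This helper
#' scales that fractional window to any pooled depth so toy-scale runs
#' use the same screen.
#'
#' @param pool_depth expected homozygous k-mer depth of the pooled reads
#' @param fraction lower/upper window as fractions of \code{pool_depth}
#' @return numeric length-2 window of absolute counts
#' @export
poolWindow <- function(pool_depth, fraction = c(0.44, 0.56)) {
    pool_depth * fraction
}

#' Discover k-mer pair markers from parental and pooled k-mer tables
#'
#' Finds all pairs of k-mers that (1) share a common (k-1)-mer prefix and
#' differ only in their final base; (2) are the only k-mers with that
#' prefix across all three tables (bi-allelic condition); (3) are found
#' differentially in the two parental read sets (one allele with count >=
#' \code{parental_min} in its parent and <= \code{parental_max_other} in
#' the other, and vice versa); (4) each fall inside
#' \code{pool_window} in the pooled population table (segregation
#' condition). Both orientations of every stored canonical k-mer are
#' considered when grouping by prefix, which makes discovery
#' strand-invariant; each SNP with unique flanks can yield up to two
#' pairs (one per flank).
#'
#' @param table_p1,table_p2,table_pool \linkS4class{KmerTable}s of parent
#'   1, parent 2 and the pooled population reads (same k)
#' @param pool_window numeric (lo, hi) absolute count window in the pool
#' @param parental_min minimum count in the owning parent
#' @param parental_max_other maximum count in the other parent
#' @return a \linkS4class{MarkerPanel}
#' @export
discoverMarkerPairs <- function(table_p1, table_p2, table_pool, pool_window,
                                parental_min = 5, parental_max_other = 0) {
    k <- table_p1@k
    if (table_p2@k != k || table_pool@k != k)
        stop("all three tables must share the same k")
    if (length(pool_window) != 2 || pool_window[1] > pool_window[2])
        stop("pool_window must be (lo, hi)")
    dt1 <- data.table::data.table(kmer = table_p1@kmers, c1 = table_p1@counts)
    dt2 <- data.table::data.table(kmer = table_p2@kmers, c2 = table_p2@counts)
    dtp <- data.table::data.table(kmer = table_pool@kmers, cp = table_pool@counts)
    dt <- merge(merge(dt1, dt2, by = "kmer", all = TRUE),
                dtp, by = "kmer", all = TRUE)
    for (col in c("c1", "c2", "cp"))
        data.table::set(dt, which(is.na(dt[[col]])), col, 0L)
    if (!nrow(dt)) return(empty_panel(k, pool_window, parental_min,
                                      parental_max_other))
    fwd <- dt$kmer
    rev <- revcomp(fwd)
    ori <- data.table::data.table(
        oriented = c(fwd, rev),
        canonical = c(fwd, fwd),
        c1 = c(dt$c1, dt$c1), c2 = c(dt$c2, dt$c2), cp = c(dt$cp, dt$cp))
    ori[, `:=`(prefix = substr(oriented, 1L, k - 1L),
               last = substr(oriented, k, k))]
    grp <- ori[, .N, by = prefix][N == 2L, prefix]
    cand <- ori[prefix %in% grp]
    if (!nrow(cand)) return(empty_panel(k, pool_window, parental_min,
                                        parental_max_other))
    data.table::setorder(cand, prefix, last)
    odd <- seq(1L, nrow(cand), by = 2L)
    a <- cand[odd]
    b <- cand[odd + 1L]
    ok <- a$last != b$last & a$canonical != b$canonical
    a <- a[ok]; b <- b[ok]
    a_p1 <- a$c1 >= parental_min & a$c2 <= parental_max_other
    a_p2 <- a$c2 >= parental_min & a$c1 <= parental_max_other
    b_p1 <- b$c1 >= parental_min & b$c2 <= parental_max_other
    b_p2 <- b$c2 >= parental_min & b$c1 <= parental_max_other
    differential <- (a_p1 & b_p2 & !a_p2 & !b_p1) |
                    (a_p2 & b_p1 & !a_p1 & !b_p2)
    in_window <- a$cp >= pool_window[1] & a$cp <= pool_window[2] &
                 b$cp >= pool_window[1] & b$cp <= pool_window[2]
    keep <- differential & in_window
    a <- a[keep]; b <- b[keep]
    markers <- data.frame(
        marker_id = sprintf("M%06d", seq_len(nrow(a))),
        prefix = a$prefix, allele1 = a$last, allele2 = b$last,
        parent_of_allele1 = ifelse(a$c1 >= parental_min, "P1", "P2"),
        count_a1_p1 = a$c1, count_a1_p2 = a$c2, count_a1_pool = a$cp,
        count_a2_p1 = b$c1, count_a2_p2 = b$c2, count_a2_pool = b$cp,
        stringsAsFactors = FALSE)
    methods::new("MarkerPanel", k = k, markers = markers,
                 params = list(pool_window = pool_window,
                               parental_min = parental_min,
                               parental_max_other = parental_max_other))
}

empty_panel <- function(k, pool_window, parental_min, parental_max_other) {
    methods::new("MarkerPanel", k = k,
        markers = data.frame(marker_id = character(), prefix = character(),
            allele1 = character(), allele2 = character(),
            parent_of_allele1 = character(), count_a1_p1 = integer(),
            count_a1_p2 = integer(), count_a1_pool = integer(),
            count_a2_p1 = integer(), count_a2_p2 = integer(),
            count_a2_pool = integer(), stringsAsFactors = FALSE),
        params = list(pool_window = pool_window, parental_min = parental_min,
                      parental_max_other = parental_max_other))
}

# The two allele k-mers of each marker, oriented so the allele base is last.
panel_allele_kmers <- function(panel) {
    m <- panel@markers
    list(a1 = paste0(m$prefix, m$allele1), a2 = paste0(m$prefix, m$allele2))
}

#' Genotype one individual's reads against a marker panel
#'
#' Per marker: A if only the parent-1 allele k-mer is observed, B if only
#' the parent-2 allele, H if both, "-" if neither (absence is a call).
#'
#' @param reads the individual's reads (\code{DNAStringSet} or character),
#'   or a \linkS4class{KmerTable} built from them
#' @param panel a \linkS4class{MarkerPanel}
#' @return named character vector of calls (names = marker ids)
#' @export
genotypeAgainstPanel <- function(reads, panel) {
    m <- panel@markers
    if (!nrow(m)) return(stats::setNames(character(0), character(0)))
    q <- panel_allele_kmers(panel)
    if (methods::is(reads, "KmerTable")) {
        if (reads@k != panel@k) stop("k of table and panel differ")
        n1 <- lookup_counts(reads, q$a1)
        n2 <- lookup_counts(reads, q$a2)
    } else {
        reads <- as.character(reads)
        n1 <- cpp_match_kmers(reads, panel@k, q$a1)
        n2 <- cpp_match_kmers(reads, panel@k, q$a2)
    }
    has1 <- n1 >= 1L
    has2 <- n2 >= 1L
    p1_first <- m$parent_of_allele1 == "P1"
    call <- rep("-", nrow(m))
    call[has1 & !has2] <- ifelse(p1_first[has1 & !has2], "A", "B")
    call[!has1 & has2] <- ifelse(p1_first[!has1 & has2], "B", "A")
    call[has1 & has2] <- "H"
    stats::setNames(call, m$marker_id)
}

#' Genotype a whole population against a marker panel
#'
#' @param read_sets named list of per-individual read sets
#' @param panel a \linkS4class{MarkerPanel}
#' @return character matrix, markers x individuals
#' @export
genotypePopulation <- function(read_sets, panel) {
    calls <- vapply(read_sets, genotypeAgainstPanel, panel = panel,
                    character(nrow(panel@markers)))
    matrix(calls, nrow = nrow(panel@markers),
           dimnames = list(panel@markers$marker_id, names(read_sets)))
}

#' Screen a genotyped marker panel for heterozygosity
#'
#' First excludes individuals whose fraction of H calls is an outlier
#' (above \code{median + 3 * MAD} across individuals), then removes every
#' marker with at least one H call among the retained individuals. This
#' mirrors the published two-step screen: drop contaminated individuals,
#' then drop k-mer pairs observed in both allelic states in any DH.
#'
#' @param panel a \linkS4class{MarkerPanel}
#' @param calls character matrix of calls, markers x individuals
#' @param n_mad outlier multiplier on the MAD of per-individual H fractions
#' @param min_h_fraction absolute floor below which an individual is never
#'   an outlier; guards against a degenerate (near-zero) MAD when most
#'   individuals carry no H calls at all
#' @return list: \code{panel} (filtered), \code{calls} (filtered matrix),
#'   \code{excluded_individuals}, \code{removed_markers}
#' @export
screenPanel <- function(panel, calls, n_mad = 3, min_h_fraction = 0.02) {
    stopifnot(nrow(calls) == nrow(panel@markers))
    h_frac <- colMeans(calls == "H")
    cutoff <- max(stats::median(h_frac) + n_mad * stats::mad(h_frac),
                  min_h_fraction)
    excluded <- colnames(calls)[h_frac > cutoff]
    kept <- setdiff(colnames(calls), excluded)
    if (length(kept) < 3)
        stop("fewer than 3 individuals remain after heterozygosity screen")
    sub <- calls[, kept, drop = FALSE]
    bad <- rowSums(sub == "H") > 0
    removed <- panel@markers$marker_id[bad]
    panel@markers <- panel@markers[!bad, , drop = FALSE]
    list(panel = panel, calls = sub[!bad, , drop = FALSE],
         excluded_individuals = excluded, removed_markers = removed)
}

#' Place panel markers uniquely on assembly scaffolds
#'
#' A marker is placed iff exactly one of its two allele k-mers occurs in
#' the scaffold set, at exactly one location counting both strands.
#' Markers hitting multiple locations, hitting with both alleles, or
#' absent entirely are reported unplaced with a reason.
#'
#' @param panel a \linkS4class{MarkerPanel}
#' @param scaffolds a \code{DNAStringSet}
#' @return data.frame: marker_id, scaffold, offset (0-based), strand,
#'   allele (1 or 2), status ("placed", "absent", "non-unique",
#'   "both-alleles")
#' @export
placeMarkersOnScaffolds <- function(panel, scaffolds) {
    m <- panel@markers
    out <- data.frame(marker_id = m$marker_id, scaffold = NA_character_,
                      offset = NA_integer_, strand = NA_character_,
                      allele = NA_integer_, status = "absent",
                      stringsAsFactors = FALSE)
    if (!nrow(m)) return(out)
    q <- panel_allele_kmers(panel)
    queries <- c(q$a1, q$a2, revcomp(q$a1), revcomp(q$a2))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
    cnt <- Biostrings::vcountPDict(pd, scaffolds)
    n <- nrow(m)
    per_query <- rowSums(cnt)
    tot1 <- per_query[1:n] + per_query[2 * n + 1:n]
    tot2 <- per_query[n + 1:n] + per_query[3 * n + 1:n]
    out$status[tot1 > 0 & tot2 > 0] <- "both-alleles"
    one <- (tot1 + tot2 > 1) & !(tot1 > 0 & tot2 > 0)
    out$status[one] <- "non-unique"
    placed <- (tot1 == 1 & tot2 == 0) | (tot1 == 0 & tot2 == 1)
    scaffold_names <- names(scaffolds) %||% as.character(seq_along(scaffolds))
    for (i in which(placed)) {
        allele <- if (tot1[i] == 1) 1L else 2L
        base_idx <- if (allele == 1L) i else n + i
        fwd_hit <- per_query[base_idx] == 1
        qi <- if (fwd_hit) base_idx else 2L * n + base_idx
        sc <- which(cnt[qi, ] > 0)
        hit <- Biostrings::matchPattern(queries[qi], scaffolds[[sc]])
        out$scaffold[i] <- scaffold_names[sc]
        out$offset[i] <- BiocGenerics::start(hit)[1] - 1L
        out$strand[i] <- if (fwd_hit) "+" else "-"
        out$allele[i] <- allele
        out$status[i] <- "placed"
    }
    out
}
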