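#' Simulate a full study data set
#'
#' Convenience wrapper: parents, fragmented (optionally chimeric)
#' assembly, DH population and genotype matrix, all from one
#' \linkS4class{SimParams}.
#'
#' @param params a \linkS4class{SimParams}
#' @param call_rate,genotype_error genotype-matrix noise (see
#'   [makeGenotypeMatrix()])
#' @param misjoin_rate fraction of chimeric scaffolds
#' @param mean_scaffold_len mean scaffold length (bp)
#' @param raw emit raw nucleotide calls plus parent columns
#' @return list: parents, scaffolds, truth, genotypes
#' @export
simulateStudy <- function(params, call_rate = 0.3, genotype_error = 0,
                          misjoin_rate = 0, mean_scaffold_len = 10000,
                          raw = TRUE) {
    seeds <- derive_seeds(params@seed, 3)
    pg <- makeParentGenomes(params)
    fa <- fragmentAssembly(pg$parents$P1, pg$truth,
                           mean_len = mean_scaffold_len,
                           misjoin_rate = misjoin_rate, seed = seeds[1])
    truth <- makeDHPopulation(fa$truth)
    gm <- makeGenotypeMatrix(truth, call_rate = call_rate,
                             genotype_error = genotype_error,
                             seed = seeds[2], raw = raw)
    list(parents = pg$parents, scaffolds = fa$scaffolds, truth = truth,
         genotypes = gm)
}

# Majority true chromosome of each scaffold (part 1 for chimeras).
scaffold_true_chrom <- function(truth) {
    sc <- truth@scaffolds[truth@scaffolds$part == 1L, ]
    stats::setNames(sc$chrom, sc$scaffold_id)
}

#' Compare scaffold anchors against simulation truth
#'
#' Matches linkage groups to true chromosomes by majority vote over
#' anchored non-chimeric scaffolds, then reports the fraction anchored to
#' the correct chromosome.
#'
#' @param anchors data.frame with scaffold_id, linkage_group (anchored
#'   rows are used)
#' @param truth a \linkS4class{SimTruth}
#' @return list: accuracy, n_assessed, lg_to_chrom
#' @export
anchorAccuracy <- function(anchors, truth) {
    true_chrom <- scaffold_true_chrom(truth)
    chimeric <- unique(truth@scaffolds$scaffold_id[truth@scaffolds$chimera])
    ok <- !is.na(anchors$linkage_group) &
          anchors$scaffold_id %in% names(true_chrom) &
          !(anchors$scaffold_id %in% chimeric)
    a <- anchors[ok, , drop = FALSE]
    if (!nrow(a)) return(list(accuracy = NA, n_assessed = 0L,
                              lg_to_chrom = character(0)))
    tc <- true_chrom[a$scaffold_id]
    lg_map <- vapply(split(tc, a$linkage_group),
                     function(x) names(sort(table(x), decreasing = TRUE))[1],
                     character(1))
    list(accuracy = mean(lg_map[a$linkage_group] == tc),
         n_assessed = nrow(a), lg_to_chrom = lg_map)
}

#' Alignment-based (genotype matrix) mapping and anchoring pipeline
#'
#' The full published matrix path: variant filtering (quality,
#' missingness, minor allele frequency), polarization against the
#' parents, scaffold consensus genotypes, framework selection, Hamming-0
#' binning, LOD clustering, bin ordering and Kosambi positions, then
#' nearest-neighbour anchoring of all scaffold consensus genotypes,
#' per-SNP mis-join screening and a segregation-distortion scan.
#' Per-stage record counts are collected in \code{stage_log}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (raw or polarized)
#' @param min_quality,max_missing_fraction,min_maf variant filters
#' @param consensus_min_calls,consensus_concordance scaffold-consensus rules
#' @param lod_threshold linkage-group LOD threshold
#' @param min_calls_per_allele,max_missing_calls framework selection
#' @param max_hamming,min_chrom_agreement,max_mad_cM,max_missing anchoring
#'   thresholds
#' @param intra_scaffold_max_cM mis-join flagging window
#' @return list: map, consensus, anchors, mapped_markers, misjoins,
#'   distortion, stage_log
#' @export
runMatrixPipeline <- function(genotypes, min_quality = 40,
                              max_missing_fraction = 0.9, min_maf = 0.05,
                              consensus_min_calls = 3,
                              consensus_concordance = 0.95,
                              lod_threshold = 9, min_calls_per_allele = 10,
                              max_missing_calls = 3, max_hamming = 3,
                              min_chrom_agreement = 0.9, max_mad_cM = 5,
                              max_missing = 0.7,
                              intra_scaffold_max_cM = 5) {
    log <- list(input_snps = nrow(genotypes))
    if (!nrow(genotypes)) stop("filter stage: empty genotype matrix")
    filt <- filterVariants(genotypes, min_quality, max_missing_fraction,
                           min_maf)
    log$filtered_snps <- nrow(filt)
    if (!nrow(filt)) stop("filter stage: no SNPs survive filtering")
    pol <- polarizeGenotypes(filt)
    log$polarized_snps <- nrow(pol)
    cons <- scaffoldConsensus(pol, consensus_min_calls,
                              consensus_concordance)
    # exclude individuals with outlying missingness (arm loss, pervasive
    # heterozygosity) before the final map, as in the published procedure
    excluded <- screenIndividuals(cons)
    log$excluded_individuals <- length(excluded)
    if (length(excluded)) {
        pol <- pol[, setdiff(colnames(pol), excluded)]
        cons <- scaffoldConsensus(pol, consensus_min_calls,
                                  consensus_concordance)
    }
    log$consensus_units <- nrow(cons@calls)
    map <- buildFrameworkMap(cons, lod_threshold = lod_threshold,
                             min_calls_per_allele = min_calls_per_allele,
                             max_missing_calls = max_missing_calls)
    log$framework_bins <- nrow(mapTable(map))
    log$linkage_groups <- length(unique(mapTable(map)$linkage_group))
    cons_anchor <- scaffoldConsensus(pol, min_calls = 1,
                                     min_concordance = consensus_concordance)
    anchors <- anchorScaffolds(cons_anchor, map, max_hamming = max_hamming,
                               min_chrom_agreement = min_chrom_agreement,
                               max_mad_cM = max_mad_cM,
                               max_missing = max_missing)
    log$anchored <- sum(anchors$status == "anchored")
    mapped <- mappedMarkersFromMatrix(pol, map)
    misjoins <- detectMisjoins(mapped, intra_scaffold_max_cM)
    log$misjoin_flagged <- sum(misjoins$flagged)
    distortion <- segregationDistortion(map)
    list(map = map, consensus = cons, anchors = anchors,
         mapped_markers = mapped, misjoins = misjoins,
         distortion = distortion, stage_log = log)
}

#' Assembly-free (k-mer) mapping and anchoring pipeline
#'
#' The full published k-mer path, produced directly from shotgun reads
#' without an assembly: canonical k-mer counting of both parents and the
#' pooled population, k-mer pair marker discovery, per-individual
#' genotyping against the panel, heterozygosity screening, LOD
#' clustering, Hamming-0 binning and ordering per linkage group, then
#' (optionally) unique placement of markers on scaffolds and
#' marker-majority anchoring with conflict detection.
#'
#' @param parent_reads_1,parent_reads_2 parental read sets
#' @param dh_reads named list of per-individual read sets
#' @param k k-mer length (published value 51)
#' @param min_count minimum parental/pool k-mer frequency
#' @param pool_window absolute (lo, hi) pool-count window; default scales
#'   the published 40-50x window (at ~90x pool depth) via [poolWindow()]
#'   from \code{pool_depth}
#' @param pool_depth expected homozygous k-mer depth of the pool
#' @param parental_min,parental_max_other differential-presence thresholds
#' @param lod_threshold LOD threshold for clustering
#' @param min_informative minimum non-missing calls per marker
#' @param scaffolds optional \code{DNAStringSet} for marker placement
#' @return list: panel, calls, screen, map, marker_map, placements,
#'   anchors, conflicts, stage_log
#' @export
runKmerPipeline <- function(parent_reads_1, parent_reads_2, dh_reads,
                            k = 51, min_count = 3, pool_window = NULL,
                            pool_depth = NULL, parental_min = 5,
                            parental_max_other = 0, lod_threshold = 9,
                            min_informative = NULL, scaffolds = NULL) {
    t1 <- countKmers(parent_reads_1, k, min_count, source = "P1")
    t2 <- countKmers(parent_reads_2, k, min_count, source = "P2")
    tp <- countKmers(dh_reads, k, min_count, source = "pool")
    log <- list(kmers_p1 = length(t1@kmers), kmers_p2 = length(t2@kmers),
                kmers_pool = length(tp@kmers))
    if (is.null(pool_window)) {
        if (is.null(pool_depth))
            stop("either pool_window or pool_depth is required")
        pool_window <- poolWindow(pool_depth)
    }
    panel <- discoverMarkerPairs(t1, t2, tp, pool_window,
                                 parental_min, parental_max_other)
    log$discovered_markers <- nrow(panel@markers)
    if (!nrow(panel@markers)) {
        return(list(panel = panel, calls = NULL, screen = NULL, map = NULL,
                    marker_map = NULL, placements = NULL, anchors = NULL,
                    conflicts = NULL,
                    stage_log = c(log, status = "no markers discovered")))
    }
    calls <- genotypePopulation(dh_reads, panel)
    screen <- screenPanel(panel, calls)
    log$screened_markers <- nrow(screen$panel@markers)
    log$excluded_individuals <- length(screen$excluded_individuals)
    # At ~1.4x per individual each single marker is called in only ~60%
    # of the population, too sparse for LOD-threshold clustering. Markers
    # are therefore first collapsed into Hamming-0 recombination bins and
    # each bin's members are combined into a haplotype "super-marker"
    # whose consensus call vector has little missing data; clustering and
    # ordering then operate on the super-markers.
    bins <- binMarkers(screen$calls)
    super <- bin_consensus_calls(bins, screen$calls)
    log$super_markers <- nrow(super)
    cl <- clusterMarkers(super, lod_threshold = lod_threshold,
                         min_informative = min_informative)
    log$clusters <- length(cl$clusters)
    tab_list <- list()
    marker_map_list <- list()
    vec_list <- list()
    members <- split(bins$unit_id, bins$bin_id)
    bin_rep <- stats::setNames(bins$representative, bins$bin_id)
    for (gi in seq_along(cl$clusters)) {
        ids <- cl$clusters[[gi]]
        lg <- paste0("LG", gi)
        sub <- super[ids, , drop = FALSE]
        pos <- mapPositions(sub)
        tab_list[[gi]] <- data.frame(
            linkage_group = lg, position_cM = pos$position_cM,
            bin_id = pos$bin_id,
            representative = unname(bin_rep[pos$bin_id]),
            n_members = lengths(members)[pos$bin_id],
            stringsAsFactors = FALSE)
        bin_pos <- stats::setNames(pos$position_cM, pos$bin_id)
        in_lg <- bins$bin_id %in% ids
        marker_map_list[[gi]] <- data.frame(
            marker_id = bins$unit_id[in_lg], linkage_group = lg,
            position_cM = unname(bin_pos[bins$bin_id[in_lg]]),
            stringsAsFactors = FALSE)
        vec_list[[gi]] <- sub[pos$bin_id, , drop = FALSE]
    }
    if (!length(tab_list)) stop("no linkage groups formed from markers")
    tab <- do.call(rbind, tab_list)
    rownames(tab) <- NULL
    map <- methods::new("GeneticMap", table = tab,
                        vectors = do.call(rbind, vec_list),
                        members = members[tab$bin_id],
                        params = list(lod_threshold = lod_threshold, k = k))
    marker_map <- do.call(rbind, marker_map_list)
    log$mapped_markers <- nrow(marker_map)
    placements <- NULL
    anchors <- NULL
    conflicts <- NULL
    if (!is.null(scaffolds)) {
        placements <- placeMarkersOnScaffolds(screen$panel, scaffolds)
        log$placed_markers <- sum(placements$status == "placed")
        ab <- anchorByMarkers(placements, marker_map)
        anchors <- ab$anchors
        conflicts <- ab$conflicts
        log$anchored <- if (!is.null(anchors)) nrow(anchors) else 0L
        log$conflicts <- if (!is.null(conflicts)) nrow(conflicts) else 0L
    }
    list(panel = screen$panel, calls = screen$calls, screen = screen,
         map = map, marker_map = marker_map, placements = placements,
         anchors = anchors, conflicts = conflicts, stage_log = log)
}
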