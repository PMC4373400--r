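# TSV serialization with provenance headers. Every writer emits
# "# popanchor <version>" plus echoed parameters; readers skip "#" lines.
# Round trips are value-stable and reruns with the same seed are
# byte-identical.

io_header <- function(kind, params = list()) {
    ver <- as.character(utils::packageVersion("popanchor"))
    echo <- if (length(params))
        paste0("# ", names(params), "=",
               vapply(params, function(p) paste(format(p), collapse = ","),
                      character(1)))
    else character(0)
    c(paste0("# popanchor ", ver, " ", kind), echo)
}

write_tsv_with_header <- function(df, path, kind, params = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(io_header(kind, params), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

read_tsv_skip_header <- function(path, kind, ...) {
    first <- readLines(path, n = 1)
    if (!startsWith(first, paste0("# popanchor")))
        stop("not a popanchor ", kind, " file: ", path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      ...)
}

#' Write / read a genetic map as TSV
#'
#' Columns: linkage_group, position_cM, bin_id, representative,
#' n_members, then one call column per individual holding the bin
#' representative's genotype vector.
#'
#' @param map a \linkS4class{GeneticMap}
#' @param path file path
#' @param params optional named parameters echoed into the header
#' @return \code{readGeneticMap}: a \linkS4class{GeneticMap} (bin
#'   memberships reduce to the representatives)
#' @export
writeGeneticMap <- function(map, path, params = list()) {
    df <- cbind(mapTable(map),
                as.data.frame(mapVectors(map)[mapTable(map)$bin_id, ,
                                              drop = FALSE]))
    write_tsv_with_header(df, path, "genetic_map",
                          c(params, map@params))
}

#' @rdname writeGeneticMap
#' @export
readGeneticMap <- function(path) {
    df <- read_tsv_skip_header(path, "genetic_map", check.names = FALSE)
    meta <- c("linkage_group", "position_cM", "bin_id", "representative",
              "n_members")
    vec <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
    rownames(vec) <- df$bin_id
    methods::new("GeneticMap", table = df[, meta],
                 vectors = vec,
                 members = stats::setNames(as.list(df$representative),
                                           df$bin_id),
                 params = list())
}

#' Write / read a marker panel as TSV
#'
#' @param panel a \linkS4class{MarkerPanel}
#' @param path file path
#' @param params optional named parameters echoed into the header
#' @export
writeMarkerPanel <- function(panel, path, params = list()) {
    write_tsv_with_header(panel@markers, path, "marker_panel",
                          c(list(k = panel@k), params, panel@params))
}

#' @rdname writeMarkerPanel
#' @export
readMarkerPanel <- function(path) {
    first2 <- readLines(path, n = 2)
    k_line <- grep("^# k=", first2, value = TRUE)
    df <- read_tsv_skip_header(path, "marker_panel")
    k <- if (length(k_line)) as.integer(sub("^# k=", "", k_line))
         else nchar(df$prefix[1]) + 1L
    methods::new("MarkerPanel", k = k, markers = df, params = list())
}

#' Write / read a genotype matrix as TSV
#'
#' Dialect: header comment lines, then a header row with the fixed
#' leading columns snp_id, scaffold, pos (1-based in the file; 0-based in
#' memory, stated in the header), qual, allele_p1, allele_p2 followed by
#' individual ids; cells are A/B/H/- (or raw nucleotide calls before
#' polarization).
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param path file path
#' @param params optional named parameters echoed into the header
#' @export
writeGenotypeMatrix <- function(x, path, params = list()) {
    df <- cbind(snpInfo(x), as.data.frame(genotypeCalls(x)))
    df$pos <- df$pos + 1L # 1-based on disk
    write_tsv_with_header(df, path, "genotype_matrix pos=1-based",
                          params)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
    df <- read_tsv_skip_header(path, "genotype_matrix", check.names = FALSE)
    meta <- c("snp_id", "scaffold", "pos", "qual", "allele_p1", "allele_p2")
    info <- df[, meta]
    info$pos <- info$pos - 1L
    calls <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
    GenotypeMatrix(calls, info)
}

#' Import a genotype matrix from VCF
#'
#' Maps the GT field of a biallelic-SNP VCF onto the package's genotype
#' dialect, preserving sample order: homozygous calls become the allele
#' nucleotide, heterozygotes \code{"X/Y"}, missing \code{"-"}. The
#' result is a raw (unpolarized) matrix; run [polarizeGenotypes()] with
#' the parent sample names afterwards.
#'
#' @param path VCF path (plain or gzipped)
#' @return a \linkS4class{GenotypeMatrix} with raw nucleotide cells
#' @export
readGenotypeMatrixVcf <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("the vcfR package is required for VCF import")
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    keep <- nchar(ref) == 1 & nchar(alt) == 1 & !is.na(alt)
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    ref <- ref[keep]; alt <- alt[keep]
    decode <- function(g, i) {
        if (is.na(g)) return("-")
        x <- strsplit(gsub("|", "/", g, fixed = TRUE), "/")[[1]]
        if (length(x) < 2 || any(x == ".")) return("-")
        al <- ifelse(x == "0", ref[i], alt[i])
        if (al[1] == al[2]) al[1] else paste(sort(al[1:2]), collapse = "/")
    }
    calls <- gt
    for (j in seq_len(ncol(gt)))
        calls[, j] <- vapply(seq_len(nrow(gt)), function(i)
            decode(gt[i, j], i), character(1))
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    qual[is.na(qual)] <- 0
    info <- data.frame(
        snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                        fix[, "ID"]),
        scaffold = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]) - 1L, # VCF is 1-based
        qual = qual, allele_p1 = NA_character_,
        allele_p2 = NA_character_, stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    GenotypeMatrix(calls, info)
}

#' Write a k-mer table or spectrum as two-column TSV
#'
#' @param x a \linkS4class{KmerTable} or \linkS4class{Spectrum}
#' @param path file path
#' @export
writeSpectrum <- function(x, path) {
    if (methods::is(x, "KmerTable")) x <- buildSpectrum(x)
    write_tsv_with_header(data.frame(freq = x@freq, count = x@count),
                          path, "spectrum", list(k = x@k))
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
    k_line <- grep("^# k=", readLines(path, n = 2), value = TRUE)
    df <- read_tsv_skip_header(path, "spectrum")
    methods::new("Spectrum", k = as.integer(sub("^# k=", "", k_line)),
                 freq = as.integer(df$freq), count = as.numeric(df$count))
}
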