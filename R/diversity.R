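#' Pairwise SNP rate over mutually covered positions
#'
#' Rate = 1000 x (polymorphic positions with depth >= 1 in both
#' accessions) / (positions with depth >= 1 in both), optionally
#' restricted to a mask (e.g. coding regions). With zero mutually
#' covered positions the rate is undefined and NA is returned with
#' \code{attr(, "status") = "undefined"}.
#'
#' @param variant_pos 0-based positions polymorphic between the two
#'   accessions (on the same reference)
#' @param depth_x,depth_y equal-length per-position depth tracks
#' @param mask optional logical vector (TRUE = use the position)
#' @return SNPs per kbp (numeric), with attributes \code{n_covered} and
#'   \code{n_polymorphic}
#' @export
snpRate <- function(variant_pos, depth_x, depth_y, mask = NULL) {
    if (length(depth_x) != length(depth_y))
        stop("depth tracks differ in length")
    covered <- depth_x >= 1 & depth_y >= 1
    if (!is.null(mask)) covered <- covered & mask
    n_cov <- sum(covered)
    if (n_cov == 0)
        return(structure(NA_real_, status = "undefined",
                         n_covered = 0L, n_polymorphic = 0L))
    is_var <- logical(length(depth_x))
    is_var[variant_pos + 1L] <- TRUE
    n_poly <- sum(is_var & covered)
    structure(1000 * n_poly / n_cov, n_covered = n_cov,
              n_polymorphic = n_poly)
}

#' Presence-absence (deletion) intervals from depth tracks
#'
#' Maximal runs where the target accession has zero coverage while the
#' control has at least \code{min_control_depth}, reported when at least
#' \code{min_len} bp long (published screen: intervals >= 50 bp).
#' Coordinates are 0-based, half-open.
#'
#' @param depth_target,depth_control equal-length depth tracks
#' @param min_len minimum reported interval length (bp)
#' @param min_control_depth minimum control coverage inside the run
#' @return data.frame: start, end, length
#' @export
deletionIntervals <- function(depth_target, depth_control, min_len = 50,
                              min_control_depth = 1) {
    if (length(depth_target) != length(depth_control))
        stop("depth tracks differ in length")
    pred <- depth_target == 0 & depth_control >= min_control_depth
    r <- rle(pred)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len
    data.frame(start = starts[keep], end = ends[keep],
               length = r$lengths[keep])
}

#' Write deletion intervals as BED
#'
#' @param intervals output of [deletionIntervals()]
#' @param scaffold_id reference name for the BED records
#' @param path output path
#' @export
writeDeletionsBed <- function(intervals, scaffold_id, path) {
    bed <- data.frame(chrom = scaffold_id, start = intervals$start,
                      end = intervals$end)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a per-position depth track from TSV
#'
#' Expects columns scaffold, pos (1-based), depth; returns a named list
#' of dense integer tracks (positions absent from the file have depth 0).
#'
#' @param path TSV path
#' @param lengths optional named scaffold lengths; defaults to the
#'   maximum position seen
#' @return named list of integer vectors
#' @export
readDepthTrack <- function(path, lengths = NULL) {
    d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("scaffold", "pos", "depth"))
    out <- lapply(split(d, d$scaffold), function(s) {
        len <- if (!is.null(lengths)) lengths[[s$scaffold[1]]] else max(s$pos)
        v <- integer(len)
        v[s$pos] <- as.integer(s$depth)
        v
    })
    out
}
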