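#' Build a k-mer frequency spectrum from a count table
#'
#' The spectrum h(f) counts distinct canonical k-mers seen exactly f
#' times. Its total mass (sum of f * h(f)) equals the total k-mer count
#' of the table.
#'
#' @param table a non-empty \linkS4class{KmerTable}
#' @return a \linkS4class{Spectrum}
#' @export
buildSpectrum <- function(table) {
    if (!length(table@counts)) stop("empty k-mer table")
    tab <- table(table@counts)
    methods::new("Spectrum", k = table@k,
                 freq = as.integer(names(tab)), count = as.numeric(tab))
}

# Dense histogram over 1..max(freq), smoothed with a centred width-3
# moving average (ends use the available window).
smoothed_histogram <- function(spec) {
    h <- numeric(max(spec@freq))
    h[spec@freq] <- spec@count
    n <- length(h)
    if (n < 3) return(h)
    sm <- h
    sm[2:(n - 1)] <- (h[1:(n - 2)] + h[2:(n - 1)] + h[3:n]) / 3
    sm[1] <- (h[1] + h[2]) / 2
    sm[n] <- (h[n - 1] + h[n]) / 2
    sm
}

#' Error threshold of a spectrum
#'
#' Frequency of the first local minimum of the (width-3 smoothed)
#' spectrum, separating the low-depth sequencing-error component from the
#' genomic peak. For a spectrum with no interior minimum (e.g. pure
#' Poisson coverage with no error mass) the threshold is undefined and NA
#' is returned with \code{attr(, "status") = "undefined"}.
#'
#' @param spec a \linkS4class{Spectrum}
#' @return integer frequency, or NA with a status attribute
#' @export
errorThreshold <- function(spec) {
    sm <- smoothed_histogram(spec)
    n <- length(sm)
    if (n >= 3) {
        for (f in 2:(n - 1)) {
            if (sm[f] <= sm[f - 1] && sm[f] < sm[f + 1])
                return(as.integer(f))
        }
    }
    structure(NA_integer_, status = "undefined")
}

#' Peak (homozygous) k-mer depth of a spectrum
#'
#' Modal frequency of the smoothed spectrum above the error threshold,
#' ties broken toward the lower frequency. This is the typical number of
#' k-mers covering a non-repetitive nucleotide.
#'
#' @param spec a \linkS4class{Spectrum}
#' @param threshold error threshold; computed via [errorThreshold()] if
#'   missing (an undefined threshold falls back to 0, i.e. the whole
#'   spectrum)
#' @return integer modal frequency
#' @export
peakDepth <- function(spec, threshold = errorThreshold(spec)) {
    if (is.na(threshold)) threshold <- 0L
    sm <- smoothed_histogram(spec)
    above <- which(seq_along(sm) > threshold)
    if (!length(above) || all(sm[above] == 0))
        stop("no spectrum mass above the error threshold")
    as.integer(above[which.max(sm[above])])
}

#' Genomic copy-number CDF of a spectrum
#'
#' Cumulative genome fraction (in bp equivalents, i.e. weighted by
#' f * h(f)) as a function of estimated genomic copy count f / peak,
#' excluding error mass at or below the threshold.
#'
#' @param spec a \linkS4class{Spectrum}
#' @param peak homozygous peak depth ([peakDepth()])
#' @param threshold error threshold; mass at f <= threshold is excluded
#' @return data.frame: copy (f / peak), mass, cumulative (ends at 1)
#' @export
copyNumberCDF <- function(spec, peak = peakDepth(spec),
                          threshold = errorThreshold(spec)) {
    if (peak < 1) stop("peak must be >= 1")
    if (is.na(threshold)) threshold <- 0L
    keep <- spec@freq > threshold
    f <- spec@freq[keep]
    mass <- f * spec@count[keep]
    if (!length(f)) stop("no mass above the error threshold")
    data.frame(copy = f / peak, mass = mass / sum(mass),
               cumulative = cumsum(mass) / sum(mass))
}

#' Fraction of the genome at low copy number
#'
#' @param cdf output of [copyNumberCDF()]
#' @param copy_cutoff copy-count cutoff (> 0); published values of
#'   interest are 1.5 and 2.0
#' @return cumulative genome fraction at estimated copy <= cutoff
#' @export
uniqueFraction <- function(cdf, copy_cutoff = 2.0) {
    if (copy_cutoff <= 0) stop("copy_cutoff must be positive")
    sum(cdf$mass[cdf$copy <= copy_cutoff])
}

#' Expected k-mer depth from base coverage
#'
#' A read of length R is tiled by R - k + 1 k-mers, and each sequencing
#' error corrupts about k k-mers, of which about half fall within the
#' read (most errors sit near read ends), so the k-mer depth is
#' \code{C * (R - k + 1) / R * (1 - k * e / 2)}.
#'
#' @param base_coverage fold coverage C
#' @param read_len read length R (bp)
#' @param k k-mer length (<= R)
#' @param error_rate per-base error rate e
#' @return expected homozygous k-mer depth
#' @export
expectedKmerDepth <- function(base_coverage, read_len, k, error_rate = 0) {
    if (k > read_len) stop("k must not exceed the read length")
    base_coverage * (read_len - k + 1) / read_len * (1 - k * error_rate / 2)
}

#' Advisory genome-size estimate from a spectrum
#'
#' Total non-error k-mer mass divided by the homozygous peak depth.
#'
#' @inheritParams copyNumberCDF
#' @return estimated genome size in bp equivalents
#' @export
genomeSizeEstimate <- function(spec, peak = peakDepth(spec),
                               threshold = errorThreshold(spec)) {
    if (is.na(threshold)) threshold <- 0L
    keep <- spec@freq > threshold
    sum(spec@freq[keep] * spec@count[keep]) / peak
}
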