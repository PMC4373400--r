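# Internal helpers shared across modules.

# Encode A/B calls as +1/-1 with 0 for anything else (H, "-", NA).
encode_calls <- function(m) {
    x <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    x[m == "A"] <- 1
    x[m == "B"] <- -1
    x
}

# Pairwise mismatch (D) and mutually-observed (N) counts between the rows
# of two call matrices under the missing-skip policy. H counts as missing.
pair_counts <- function(a, b = a) {
    ea <- encode_calls(a)
    eb <- encode_calls(b)
    N <- abs(ea) %*% t(abs(eb))
    S <- ea %*% t(eb)
    list(D = (N - S) / 2, N = N)
}

# Derive a stream of reproducible sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
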