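#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Canonical k-mer machinery on a 2-bit alphabet (A=0, C=1, G=2, T=3),
// packed into a 128-bit word so k up to 63 fits. Canonical form is the
// numerically (= lexicographically) smaller of a k-mer and its reverse
// complement; k is kept odd so the two can never be equal.

typedef unsigned __int128 u128;

struct U128Hash {
    size_t operator()(const u128& x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL);
        h ^= h >> 33;
        return (size_t)h;
    }
};

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Stream all canonical k-mers of one sequence into a callback.
template <typename F>
static void stream_canonical(const char* s, size_t len, int k, F emit) {
    if ((int)len < k) return;
    u128 mask = (((u128)1) << (2 * k)) - 1;
    u128 fwd = 0, rev = 0;
    int valid = 0;
    int shift_rc = 2 * (k - 1);
    for (size_t i = 0; i < len; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (u128)c) & mask;
        rev = (rev >> 2) | (((u128)(3 - c)) << shift_rc);
        if (++valid >= k) emit(fwd < rev ? fwd : rev);
    }
}

static std::string decode_kmer(u128 x, int k) {
    std::string out(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        out[i] = BASES[(int)(x & 3)];
        x >>= 2;
    }
    return out;
}

static u128 encode_kmer(const char* s, int k) {
    u128 x = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) stop("query k-mer contains a non-ACGT character");
        x = (x << 2) | (u128)c;
    }
    return x;
}

static u128 revcomp_kmer(u128 x, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (u128)(3 - (int)(x & 3));
        x >>= 2;
    }
    return r;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, int min_count) {
    if (k < 1 || k > 63) stop("k must be between 1 and 63");
    std::unordered_map<u128, int, U128Hash> tab;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        const char* s = CHAR(seqs[i]);
        stream_canonical(s, LENGTH(seqs[i]), k, [&](u128 km) { tab[km]++; });
    }
    std::vector<std::pair<u128, int> > keep;
    keep.reserve(tab.size());
    for (const auto& kv : tab)
        if (kv.second >= min_count) keep.push_back(kv);
    std::sort(keep.begin(), keep.end(),
              [](const std::pair<u128, int>& a, const std::pair<u128, int>& b) {
                  return a.first < b.first;
              });
    R_xlen_t n = (R_xlen_t)keep.size();
    CharacterVector kmers(n);
    IntegerVector counts(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        kmers[i] = decode_kmer(keep[i].first, k);
        counts[i] = keep[i].second;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Count occurrences of each query k-mer (canonical match) in a read set.
// [[Rcpp::export]]
IntegerVector cpp_match_kmers(CharacterVector seqs, int k, CharacterVector queries) {
    if (k < 1 || k > 63) stop("k must be between 1 and 63");
    std::unordered_map<u128, int, U128Hash> want;
    R_xlen_t nq = queries.size();
    std::vector<u128> canon(nq);
    for (R_xlen_t i = 0; i < nq; ++i) {
        if (LENGTH(queries[i]) != k) stop("query length must equal k");
        u128 f = encode_kmer(CHAR(queries[i]), k);
        u128 r = revcomp_kmer(f, k);
        canon[i] = f < r ? f : r;
        want[canon[i]] = 0;
    }
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        stream_canonical(CHAR(seqs[i]), LENGTH(seqs[i]), k, [&](u128 km) {
            auto it = want.find(km);
            if (it != want.end()) it->second++;
        });
    }
    IntegerVector out(nq);
    for (R_xlen_t i = 0; i < nq; ++i) out[i] = want[canon[i]];
    return out;
}

// Substitution errors at a uniform per-base rate, using R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector reads, double error_rate) {
    if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]");
    R_xlen_t n = reads.size();
    CharacterVector out(n);
    RNGScope scope;
    std::string buf;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (reads[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        const char* s = CHAR(reads[i]);
        int len = LENGTH(reads[i]);
        buf.assign(s, len);
        if (error_rate > 0) {
            for (int j = 0; j < len; ++j) {
                if (unif_rand() < error_rate) {
                    int c = base_code(buf[j]);
                    if (c < 0) continue;
                    int alt = (int)(unif_rand() * 3.0);
                    if (alt > 2) alt = 2;
                    buf[j] = BASES[(c + 1 + alt) & 3];
                }
            }
        }
        out[i] = buf;
    }
    return out;
}
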