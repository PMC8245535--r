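#include <Rcpp.h>
#include <set>
#include <cstdint>

using namespace Rcpp;

namespace {

// Fixed sketching seed: sketches must be reproducible across sessions and
// comparable across genomes, so this is a package constant, not a parameter.
const uint64_t SKETCH_SEED = 0x4c414b4559434cULL;

inline uint64_t splitmix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // ambiguity codes break the k-mer run
    }
}

}  // namespace

//' MinHash sketch over canonical k-mers (ACGT only; ambiguity codes skipped).
//' Returns the `sketch_size` smallest distinct 53-bit hash values, ascending.
//' @noRd
// [[Rcpp::export(name = "cpp_minhash_sketch")]]
NumericVector cpp_minhash_sketch(CharacterVector seqs, int k, int sketch_size) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    if (sketch_size < 1) stop("sketch_size must be positive");

    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rc = 2 * (k - 1);
    std::set<uint64_t> sketch;  // smallest distinct hashes, bounded size

    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* seq = CHAR(STRING_ELT(seqs, s));
        uint64_t fwd = 0, rc = 0;
        int run = 0;  // length of current valid ACGT run
        for (const char* p = seq; *p; ++p) {
            int c = base_code(*p);
            if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
            rc = (rc >> 2) |
                 (static_cast<uint64_t>(3 - c) << shift_rc);
            if (++run < k) continue;
            uint64_t canonical = fwd < rc ? fwd : rc;
            uint64_t h = splitmix64(canonical ^ SKETCH_SEED) >> 11;  // 53 bits
            if (static_cast<int>(sketch.size()) < sketch_size) {
                sketch.insert(h);
            } else if (h < *sketch.rbegin()) {
                if (sketch.insert(h).second)
                    sketch.erase(std::prev(sketch.end()));
            }
        }
    }

    NumericVector out(sketch.size());
    R_xlen_t i = 0;
    for (std::set<uint64_t>::const_iterator it = sketch.begin();
         it != sketch.end(); ++it)
        out[i++] = static_cast<double>(*it);
    return out;
}

//' Count distinct canonical k-mers (used for the "genome too short" guard).
//' @noRd
// [[Rcpp::export(name = "cpp_count_canonical_kmers")]]
double cpp_count_canonical_kmers(CharacterVector seqs, int k) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rc = 2 * (k - 1);
    std::set<uint64_t> seen;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* seq = CHAR(STRING_ELT(seqs, s));
        uint64_t fwd = 0, rc = 0;
        int run = 0;
        for (const char* p = seq; *p; ++p) {
            int c = base_code(*p);
            if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
            rc = (rc >> 2) | (static_cast<uint64_t>(3 - c) << shift_rc);
            if (++run < k) continue;
            seen.insert(fwd < rc ? fwd : rc);
        }
    }
    return static_cast<double>(seen.size());
}
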