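#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit base codes; anything non-ACGT maps to A but is flagged so the
// affected windows take a slow character-comparison path.
static inline int code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

static const uint64_t PAIRMASK = 0x5555555555555555ULL;

// pack 20 bases starting at s[p] into 40 bits (2 bits per base)
static inline uint64_t packWindow(const char *s, long p) {
    uint64_t w = 0;
    for (int b = 0; b < 20; ++b) {
        int c = code(s[p + b]);
        w |= ((uint64_t)(c < 0 ? 0 : c)) << (2 * b);
    }
    return w;
}

static inline int mmCount(uint64_t a, uint64_t b) {
    uint64_t x = a ^ b;
    return __builtin_popcountll((x | (x >> 1)) & PAIRMASK);
}

static inline int mmChars(const char *w, const char *p) {
    int mm = 0;
    for (int b = 0; b < 20; ++b)
        if (w[b] != p[b]) ++mm;
    return mm;
}

// Exhaustive scan for NGG-adjacent genomic sites within maxMismatch of each
// 20-nt protospacer, on both strands of every chromosome. Counts include the
// guide's own on-target site. Candidate positions are prefiltered to those
// with a GG (plus strand) or CC (minus strand) PAM dinucleotide; windows
// are compared as packed 2-bit codes via XOR/popcount.
// [[Rcpp::export]]
IntegerVector cppCountNearMatches(CharacterVector chromSeqs,
                                  CharacterVector protospacers,
                                  int maxMismatch = 3) {
    const int P = 20;
    int n = protospacers.size();
    std::vector<std::string> ps(n), psrc(n);
    std::vector<uint64_t> pc(n), prc(n);
    for (int j = 0; j < n; ++j) {
        ps[j] = as<std::string>(protospacers[j]);
        if ((int)ps[j].size() != P)
            stop("protospacers must be 20 nt");
        psrc[j] = revcomp(ps[j]);
        pc[j] = packWindow(ps[j].c_str(), 0);
        prc[j] = packWindow(psrc[j].c_str(), 0);
    }
    IntegerVector counts(n, 0);

    for (int c = 0; c < chromSeqs.size(); ++c) {
        std::string s = as<std::string>(chromSeqs[c]);
        long L = (long)s.size();
        const char *sc = s.c_str();
        std::vector<long> nPrefix(L + 1, 0);
        for (long i = 0; i < L; ++i)
            nPrefix[i + 1] = nPrefix[i] + (code(sc[i]) < 0 ? 1 : 0);

        // plus strand: protospacer [i, i+19], PAM N at i+20, GG at i+21
        // minus strand: CC at q,q+1, N at q+2, revcomp(protospacer) [q+3,q+22]
        std::vector<long> plusStarts, minusStarts;
        for (long q = 0; q + 1 < L; ++q) {
            if (sc[q] == 'G' && sc[q + 1] == 'G' && q >= P + 1)
                plusStarts.push_back(q - P - 1);
            if (sc[q] == 'C' && sc[q + 1] == 'C' && q + 2 + P < L)
                minusStarts.push_back(q + 3);
        }
        size_t nPlus = plusStarts.size(), nMinus = minusStarts.size();
        std::vector<uint64_t> plusCodes(nPlus), minusCodes(nMinus);
        std::vector<char> plusN(nPlus), minusN(nMinus);
        for (size_t k = 0; k < nPlus; ++k) {
            plusCodes[k] = packWindow(sc, plusStarts[k]);
            plusN[k] = nPrefix[plusStarts[k] + P] - nPrefix[plusStarts[k]] > 0;
        }
        for (size_t k = 0; k < nMinus; ++k) {
            minusCodes[k] = packWindow(sc, minusStarts[k]);
            minusN[k] = nPrefix[minusStarts[k] + P] - nPrefix[minusStarts[k]] > 0;
        }

        for (int j = 0; j < n; ++j) {
            int hits = 0;
            const uint64_t cj = pc[j], cjr = prc[j];
            for (size_t k = 0; k < nPlus; ++k) {
                if (mmCount(plusCodes[k], cj) <= maxMismatch) {
                    if (!plusN[k] ||
                        mmChars(sc + plusStarts[k], ps[j].c_str()) <= maxMismatch)
                        ++hits;
                }
            }
            for (size_t k = 0; k < nMinus; ++k) {
                if (mmCount(minusCodes[k], cjr) <= maxMismatch) {
                    if (!minusN[k] ||
                        mmChars(sc + minusStarts[k], psrc[j].c_str()) <= maxMismatch)
                        ++hits;
                }
            }
            counts[j] += hits;
        }
    }
    return counts;
}
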