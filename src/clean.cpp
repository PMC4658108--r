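#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Leftmost 3' adapter occurrence: full internal match, or a terminal
// overlap of at least min_overlap nt with the adapter prefix, allowing
// up to max_mm substitutions over the compared stretch. Returns the
// 1-based match start per read, 0 when no acceptable occurrence exists.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_find_adapter3(CharacterVector reads, std::string adapter,
                                int min_overlap = 6, int max_mm = 1) {
    int nr = reads.size();
    int alen = (int) adapter.size();
    IntegerVector out(nr);
    for (int i = 0; i < nr; ++i) {
        std::string r = as<std::string>(reads[i]);
        int L = (int) r.size();
        int found = 0;
        for (int p = 0; p < L; ++p) {
            int ov = std::min(alen, L - p);
            if (ov < min_overlap) break;
            int mm = 0;
            bool ok = true;
            for (int q = 0; q < ov; ++q) {
                if (r[p + q] != adapter[q] && ++mm > max_mm) { ok = false; break; }
            }
            if (ok) { found = p + 1; break; }
        }
        out[i] = found;
    }
    return out;
}

// 5' adapter contamination: the adapter matches at the read start over
// the available overlap with at most max_mm substitutions.
//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_match_prefix(CharacterVector reads, std::string adapter,
                               int min_overlap = 6, int max_mm = 1) {
    int nr = reads.size();
    int alen = (int) adapter.size();
    LogicalVector out(nr);
    for (int i = 0; i < nr; ++i) {
        std::string r = as<std::string>(reads[i]);
        int ov = std::min(alen, (int) r.size());
        if (ov < min_overlap) { out[i] = false; continue; }
        int mm = 0;
        bool ok = true;
        for (int q = 0; q < ov; ++q) {
            if (r[q] != adapter[q] && ++mm > max_mm) { ok = false; break; }
        }
        out[i] = ok;
    }
    return out;
}

// Fraction of bases whose Phred score (ASCII - offset) is strictly below
// the floor.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_low_quality_frac(CharacterVector quals, int offset = 33,
                                   int floor = 5) {
    int nr = quals.size();
    NumericVector out(nr);
    for (int i = 0; i < nr; ++i) {
        std::string q = as<std::string>(quals[i]);
        int L = (int) q.size();
        if (L == 0) { out[i] = 0.0; continue; }
        int low = 0;
        for (int p = 0; p < L; ++p)
            if ((int) q[p] - offset < floor) ++low;
        out[i] = (double) low / (double) L;
    }
    return out;
}
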