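#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted canonical pair: GC=3, AU=2, GU=1 by default (DNA alphabet, T==U).
static inline int pair_weight(char a, char b, int wGC, int wAU, int wGU) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return wAU;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wGU;
    return 0;
}

static void fill_dp(const std::string &s, int min_loop,
                    int wGC, int wAU, int wGU,
                    std::vector<std::vector<int> > &M) {
    int n = (int) s.size();
    M.assign(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = M[i + 1][j];
            for (int k = i + min_loop + 1; k <= j; ++k) {
                int w = pair_weight(s[i], s[k], wGC, wAU, wGU);
                if (!w) continue;
                int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
                int right = (k + 1 <= j) ? M[k + 1][j] : 0;
                int sc = w + inner + right;
                if (sc > best) best = sc;
            }
            M[i][j] = best;
        }
    }
}

//' @noRd
// [[Rcpp::export]]
int cpp_nussinov_score(std::string seq, int min_loop = 3,
                       int wGC = 3, int wAU = 2, int wGU = 1) {
    int n = (int) seq.size();
    if (n < 2) return 0;
    std::vector<std::vector<int> > M;
    fill_dp(seq, min_loop, wGC, wAU, wGU, M);
    return M[0][n - 1];
}

// Maximum-weight non-crossing pairing with traceback. Ties resolved
// deterministically: the 5'-most free base prefers to pair, and among
// equal-scoring partners the outermost (largest k) is taken.
//' @noRd
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop = 3,
                  int wGC = 3, int wAU = 2, int wGU = 1) {
    int n = (int) seq.size();
    std::string db(n, '.');
    if (n < 2)
        return List::create(_["structure"] = db, _["score"] = 0);
    std::vector<std::vector<int> > M;
    fill_dp(seq, min_loop, wGC, wAU, wGU, M);

    std::vector<std::pair<int, int> > st;
    st.push_back(std::make_pair(0, n - 1));
    while (!st.empty()) {
        int i = st.back().first, j = st.back().second;
        st.pop_back();
        if (j - i <= min_loop) continue;
        int target = M[i][j];
        if (target == 0) continue;
        bool paired = false;
        for (int k = j; k >= i + min_loop + 1; --k) {
            int w = pair_weight(seq[i], seq[k], wGC, wAU, wGU);
            if (!w) continue;
            int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
            int right = (k + 1 <= j) ? M[k + 1][j] : 0;
            if (w + inner + right == target) {
                db[i] = '(';
                db[k] = ')';
                if (k - 1 > i + 1) st.push_back(std::make_pair(i + 1, k - 1));
                if (k + 1 < j) st.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) st.push_back(std::make_pair(i + 1, j));
    }
    return List::create(_["structure"] = db, _["score"] = M[0][n - 1]);
}
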