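#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Stacking-weighted nested-structure folding.
//
// Maximises sum of base-pair weights (GC=3, AU=2, GU=1) plus 1 per stacked
// pair (a pair (i,j) whose inner neighbour (i+1,j-1) is also paired).
// Hairpin loops are forced to hold at least `min_loop` unpaired bases.
// Deterministic tie-breaking: in M, an unpaired right end is preferred,
// then the smallest pairing partner; in P, stacking is preferred.

static const int NEG = -1000000000;

static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return NEG;
}

struct FoldDP {
    int n, min_loop;
    const std::string &s;
    std::vector<std::vector<int> > M, P;
    std::string db;

    FoldDP(const std::string &seq, int ml) : n(seq.size()), min_loop(ml), s(seq) {
        M.assign(n, std::vector<int>(n, 0));
        P.assign(n, std::vector<int>(n, NEG));
        db.assign(n, '.');
    }

    inline int getM(int i, int j) const {
        if (i < 0 || j < 0 || j < i || i >= n) return 0;
        return M[i][j];
    }

    // best over region [i..j] with (i,j) NOT paired to each other
    // (mirrors the M recurrence minus its k == i term)
    int inner_excl(int i, int j) const {
        if (j <= i) return 0;
        int best = getM(i, j - 1);                 // j unpaired
        for (int k = i + 1; k <= j - min_loop - 1; ++k) {
            if (P[k][j] == NEG) continue;
            int v = getM(i, k - 1) + P[k][j];
            if (v > best) best = v;
        }
        return best;
    }

    void fill() {
        for (int span = 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                // P(i,j)
                int w = pair_weight(s[i], s[j]);
                if (w != NEG && j - i - 1 >= min_loop) {
                    int opt = inner_excl(i + 1, j - 1);     // (i+1,j-1) not paired together
                    if (i + 1 < n && j - 1 >= 0 && j - 1 > i + 1 && P[i + 1][j - 1] != NEG) {
                        int st = P[i + 1][j - 1] + 1;       // stack bonus
                        if (st > opt) opt = st;
                    }
                    P[i][j] = w + opt;
                }
                // M(i,j)
                int best = getM(i, j - 1);
                for (int k = i; k <= j - min_loop - 1; ++k) {
                    if (P[k][j] == NEG) continue;
                    int v = (k > i ? getM(i, k - 1) : 0) + P[k][j];
                    if (v > best) best = v;
                }
                M[i][j] = best;
            }
        }
    }

    void traceM(int i, int j) {
        if (j <= i) return;
        if (M[i][j] == getM(i, j - 1)) { traceM(i, j - 1); return; }
        for (int k = i; k <= j - min_loop - 1; ++k) {
            if (P[k][j] == NEG) continue;
            int v = (k > i ? getM(i, k - 1) : 0) + P[k][j];
            if (v == M[i][j]) {
                traceP(k, j);
                if (k > i) traceM(i, k - 1);
                return;
            }
        }
    }

    void traceP(int i, int j) {
        db[i] = '(';
        db[j] = ')';
        int w = pair_weight(s[i], s[j]);
        int rest = P[i][j] - w;
        if (j - 1 > i + 1 && P[i + 1][j - 1] != NEG && rest == P[i + 1][j - 1] + 1) {
            traceP(i + 1, j - 1);
            return;
        }
        // inner region with (i+1,j-1) not paired together
        int a = i + 1, b = j - 1;
        if (b <= a) return;
        if (rest == getM(a, b - 1)) { traceM(a, b - 1); return; }
        for (int k = a + 1; k <= b - min_loop - 1; ++k) {
            if (P[k][b] == NEG) continue;
            int v = getM(a, k - 1) + P[k][b];
            if (v == rest) {
                traceP(k, b);
                traceM(a, k - 1);
                return;
            }
        }
    }
};

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq, int min_loop = 3) {
    int n = seq.size();
    if (n == 0) stop("empty sequence");
    FoldDP dp(seq, min_loop);
    if (n > 1) {
        dp.fill();
        if (dp.M[0][n - 1] > 0) dp.traceM(0, n - 1);
    }
    int score = (n > 1) ? dp.M[0][n - 1] : 0;
    return List::create(_["structure"] = dp.db, _["score"] = score);
}
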