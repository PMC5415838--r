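#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Minimum-energy nested secondary structure under a fixed, simple energy
// model: a base pair contributes its pair energy (GC -3.0, AU -2.0,
// GU -1.0 kcal/mol) only when stacked directly on the next pair inward
// (helix of k pairs = k-1 stacking contributions); a pair closing a hairpin
// loop adds +4.0, closing a bulge/internal loop adds +3.0, closing a
// multibranch loop adds +4.0; unpaired bases are free.  Isolated pairs are
// therefore never stabilizing, which is what separates genuine hairpins
// from the promiscuous pairing of random sequence.  Hairpin loops hold
// >= 3 unpaired bases; bulge/internal loops are capped at 30 unpaired bases
// total (standard practice, keeps the recursion O(n^2 * L^2)).  The model
// is deliberately small and fully documented so that tests can enumerate
// structures exhaustively and agree with the DP bit for bit.

static const double E_INF = 1e9;
static const double E_HAIRPIN = 4.0;
static const double E_BULGE = 3.0;
static const double E_MULTI = 4.0;
static const int MIN_HAIRPIN = 3;
static const int MAX_INTLOOP = 30;

static inline double pair_energy(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
    return E_INF;
}

struct FoldDP {
    int n;
    const char *s;
    std::vector<double> V, WM;
    std::vector<char> db;

    double v(int i, int j) const { return V[i * n + j]; }
    double wm(int i, int j) const { return WM[i * n + j]; }
    double &vref(int i, int j) { return V[i * n + j]; }
    double &wmref(int i, int j) { return WM[i * n + j]; }

    void fill() {
        V.assign((size_t)n * n, E_INF);
        WM.assign((size_t)n * n, E_INF);
        for (int len = 2; len <= n; ++len) {
            for (int i = 0; i + len - 1 < n; ++i) {
                int j = i + len - 1;
                double pe = pair_energy(s[i], s[j]);
                double best = E_INF;
                if (pe < E_INF && j - i - 1 >= MIN_HAIRPIN) {
                    best = E_HAIRPIN;                          // hairpin
                    if (v(i + 1, j - 1) < E_INF)               // stack
                        best = std::min(best, pe + v(i + 1, j - 1));
                    // bulge / internal loop (not both sides zero); the
                    // closing pair is unstacked, so no pair energy
                    for (int k = i + 1; k <= j - 2 && k - i - 1 <= MAX_INTLOOP; ++k) {
                        int lmin = k + 1;
                        int room = MAX_INTLOOP - (k - i - 1);
                        if (j - 1 - room > lmin) lmin = j - 1 - room;
                        for (int l = j - 1; l >= lmin && l > k; --l) {
                            if (k == i + 1 && l == j - 1) continue;
                            double in = v(k, l);
                            if (in < E_INF)
                                best = std::min(best, E_BULGE + in);
                        }
                    }
                    // multibranch: >= 2 inner helices
                    for (int m = i + 2; m <= j - 2; ++m) {
                        double a = wm(i + 1, m), b = wm(m + 1, j - 1);
                        if (a < E_INF && b < E_INF)
                            best = std::min(best, E_MULTI + a + b);
                    }
                }
                vref(i, j) = best;
                double w = best;
                w = std::min(w, wm(i + 1, j));
                w = std::min(w, wm(i, j - 1));
                for (int m = i; m < j; ++m) {
                    double a = wm(i, m), b = wm(m + 1, j);
                    if (a < E_INF && b < E_INF) w = std::min(w, a + b);
                }
                wmref(i, j) = w;
            }
        }
    }

    void trace_v(int i, int j) {
        db[i] = '(';
        db[j] = ')';
        double val = v(i, j);
        double pe = pair_energy(s[i], s[j]);
        if (val == E_HAIRPIN) return;
        if (v(i + 1, j - 1) < E_INF && val == pe + v(i + 1, j - 1)) {
            trace_v(i + 1, j - 1);
            return;
        }
        for (int k = i + 1; k <= j - 2 && k - i - 1 <= MAX_INTLOOP; ++k) {
            int lmin = k + 1;
            int room = MAX_INTLOOP - (k - i - 1);
            if (j - 1 - room > lmin) lmin = j - 1 - room;
            for (int l = j - 1; l >= lmin && l > k; --l) {
                if (k == i + 1 && l == j - 1) continue;
                if (v(k, l) < E_INF && val == E_BULGE + v(k, l)) {
                    trace_v(k, l);
                    return;
                }
            }
        }
        for (int m = i + 2; m <= j - 2; ++m) {
            double a = wm(i + 1, m), b = wm(m + 1, j - 1);
            if (a < E_INF && b < E_INF && val == E_MULTI + a + b) {
                trace_wm(i + 1, m);
                trace_wm(m + 1, j - 1);
                return;
            }
        }
        Rcpp::stop("fold traceback failed (V)");
    }

    void trace_wm(int i, int j) {
        double val = wm(i, j);
        if (val >= E_INF) Rcpp::stop("fold traceback failed (WM)");
        if (val == v(i, j)) { trace_v(i, j); return; }
        if (i + 1 <= j && val == wm(i + 1, j)) { trace_wm(i + 1, j); return; }
        if (val == wm(i, j - 1)) { trace_wm(i, j - 1); return; }
        for (int m = i; m < j; ++m) {
            double a = wm(i, m), b = wm(m + 1, j);
            if (a < E_INF && b < E_INF && val == a + b) {
                trace_wm(i, m);
                trace_wm(m + 1, j);
                return;
            }
        }
        Rcpp::stop("fold traceback failed (WM split)");
    }
};

//' @noRd
// [[Rcpp::export]]
List fold_engine_cpp(std::string seq) {
    int n = (int)seq.size();
    for (int i = 0; i < n; ++i) {
        char c = seq[i];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
            Rcpp::stop("fold: invalid character '%c' (RNA alphabet ACGU required)", c);
    }
    FoldDP dp;
    dp.n = n;
    dp.s = seq.c_str();
    dp.db.assign(n, '.');
    double mfe = 0.0;
    if (n >= 2) {
        dp.fill();
        double w = dp.wm(0, n - 1);
        if (w < 0) {
            mfe = w;
            dp.trace_wm(0, n - 1);
        }
    }
    return List::create(
        _["structure"] = std::string(dp.db.begin(), dp.db.end()),
        _["mfe"] = mfe);
}

// Log-mass of the exact two-library count statistic,
//   p(y|x) = r^y (x+y)! / ( x! y! (1+r)^(x+y+1) ),   r = N2/N1,
// evaluated in extended (long double) precision so the result agrees with
// exact rational arithmetic to ~1e-15 relative across the full count range.
//' @noRd
// [[Rcpp::export]]
NumericVector ac_mass_cpp(double x, NumericVector y, double r, bool give_log) {
    int n = y.size();
    NumericVector out(n);
    long double lr = logl((long double)r);
    long double l1r = log1pl((long double)r);
    long double lgx = lgammal((long double)x + 1.0L);
    for (int i = 0; i < n; ++i) {
        long double yi = (long double)y[i];
        long double lp = yi * lr
            + lgammal((long double)x + yi + 1.0L)
            - lgx
            - lgammal(yi + 1.0L)
            - ((long double)x + yi + 1.0L) * l1r;
        out[i] = give_log ? (double)lp : (double)expl(lp);
    }
    return out;
}

// Best 5'-anchored Hamming match of each tag against a panel of reference
// sequences.  Sequences whose lengths differ by more than max_len_diff are
// not compared; otherwise the comparison runs over the common 5' prefix.
// Returns, per tag: the best distance, the (1-based) index of the first
// reference achieving it, how many references tie at that distance, and the
// (1-based) position of the first mismatch against the best reference.
//' @noRd
// [[Rcpp::export]]
List hamming_best_cpp(CharacterVector tags, CharacterVector refs, int max_len_diff) {
    int nt = tags.size(), nr = refs.size();
    IntegerVector dist(nt), idx(nt), nbest(nt), pos(nt);
    std::vector<std::string> rs(nr);
    for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
    for (int i = 0; i < nt; ++i) {
        std::string t = as<std::string>(tags[i]);
        int bd = NA_INTEGER, bi = NA_INTEGER, nb = 0, bp = NA_INTEGER;
        for (int j = 0; j < nr; ++j) {
            int lt = (int)t.size(), lr = (int)rs[j].size();
            if (std::abs(lt - lr) > max_len_diff) continue;
            int L = std::min(lt, lr);
            int d = 0, first = -1;
            for (int k = 0; k < L; ++k) {
                if (t[k] != rs[j][k]) {
                    ++d;
                    if (first < 0) first = k;
                }
            }
            if (bd == NA_INTEGER || d < bd) {
                bd = d; bi = j + 1; nb = 1; bp = (first >= 0) ? first + 1 : NA_INTEGER;
            } else if (d == bd) {
                ++nb;
            }
        }
        dist[i] = bd; idx[i] = bi; nbest[i] = nb; pos[i] = bp;
    }
    return List::create(_["dist"] = dist, _["idx"] = idx,
                        _["nbest"] = nbest, _["pos"] = pos);
}
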