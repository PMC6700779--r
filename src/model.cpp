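#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Greedy left-to-right accessible-CpG count over sorted 1-based C positions
// in [lo, hi]: the first CpG is bound, a later CpG at c is bound iff
// (c_last + 1) + minSep < c.  This equals the maximum-cardinality subset
// under the pairwise separation constraint.
static inline int greedy_count(const int* pos, int i0, int i1, int minSep) {
    if (i0 > i1) return 0;
    int n = 1, last = pos[i0];
    for (int i = i0 + 1; i <= i1; ++i) {
        if ((last + 1) + minSep < pos[i]) {
            ++n;
            last = pos[i];
        }
    }
    return n;
}

// first index with pos[i] >= x, in [0, n)
static inline int lower_idx(const int* pos, int n, int x) {
    return (int)(std::lower_bound(pos, pos + n, x) - pos);
}

// [[Rcpp::export]]
int cpp_accessible_count(IntegerVector pos, int minSep) {
    if (pos.size() == 0) return 0;
    return greedy_count(&pos[0], 0, pos.size() - 1, minSep);
}

// Accessible-CpG count per fragment [start, end] (1-based inclusive),
// counting CpGs with C in [start, end-1] (both C and G on the fragment).
// Returns the uncapped count.
// [[Rcpp::export]]
IntegerVector cpp_fragment_ncpg(IntegerVector starts, IntegerVector ends,
                                IntegerVector cpg, int minSep) {
    int nf = starts.size(), nc = cpg.size();
    IntegerVector out(nf);
    const int* p = nc ? &cpg[0] : NULL;
    for (int k = 0; k < nf; ++k) {
        if (nc == 0 || ends[k] <= starts[k]) { out[k] = 0; continue; }
        int i0 = lower_idx(p, nc, starts[k]);
        int i1 = lower_idx(p, nc, ends[k]) - 1; // pos <= end - 1
        out[k] = greedy_count(p, i0, i1, minSep);
    }
    return out;
}

// Expected pulldown Lambda at every position of one chromosome, split by
// strand term.  cpg: sorted 1-based C positions; pmf: P(l) for
// l = lmin..lmax; cn: C_0..C_cap; clipEdges: fragments running past a
// chromosome end contribute with n computed on the clipped intersection
// (FALSE drops those lengths entirely).
// Returns a len x 2 matrix (columns: forward term, reverse term), without
// the prefactor.
// [[Rcpp::export]]
NumericMatrix cpp_lambda_track(IntegerVector cpg, int chromLen, int lmin,
                               int lmax, NumericVector pmf, NumericVector cn,
                               int minSep, bool clipEdges) {
    int nc = cpg.size(), cap = cn.size() - 1;
    int nl = lmax - lmin + 1;
    if (pmf.size() != nl) stop("pmf length must be lmax - lmin + 1");
    // cumulative pmf: F[k] = sum of pmf over lmin..(lmin + k)
    std::vector<double> F(nl);
    double acc = 0.0;
    for (int k = 0; k < nl; ++k) { acc += pmf[k]; F[k] = acc; }
    // F(l) for integer l, 0 below lmin, total above lmax
    auto cum = [&](int l) -> double {
        if (l < lmin) return 0.0;
        if (l >= lmax) return F[nl - 1];
        return F[l - lmin];
    };
    // next/prev accessible-chain pointers
    std::vector<int> nxt(nc), prv(nc);
    const int* p = nc ? &cpg[0] : NULL;
    {
        int j = 0;
        for (int i = 0; i < nc; ++i) {
            if (j < i + 1) j = i + 1;
            while (j < nc && !((p[i] + 1) + minSep < p[j])) ++j;
            nxt[i] = j; // nc means none
        }
        j = nc - 1;
        for (int i = nc - 1; i >= 0; --i) {
            if (j > i - 1) j = i - 1;
            while (j >= 0 && !((p[j] + 1) + minSep < p[i])) --j;
            prv[i] = j; // -1 means none
        }
    }
    NumericMatrix out(chromLen, 2);
    std::vector<int> thr;
    thr.reserve(64);
    for (int x = 1; x <= chromLen; ++x) {
        // ---- forward term: fragments [x, x + l - 1]
        int lmaxF = clipEdges ? lmax : std::min(lmax, chromLen - x + 1);
        double lamF = 0.0;
        if (lmaxF >= lmin) {
            thr.clear();
            if (nc) {
                int i = lower_idx(p, nc, x);
                while (i < nc) {
                    int e = p[i] - x + 2; // smallest l placing C at <= x+l-2
                    if (e > lmaxF) break;
                    thr.push_back(e < lmin ? lmin : e);
                    i = nxt[i];
                }
            }
            int n = 0, prevl = lmin;
            for (size_t k = 0; k < thr.size(); ++k) {
                if (thr[k] > prevl)
                    lamF += cn[n > cap ? cap : n] * (cum(thr[k] - 1) - cum(prevl - 1));
                prevl = thr[k];
                ++n;
            }
            lamF += cn[n > cap ? cap : n] * (cum(lmaxF) - cum(prevl - 1));
        }
        // ---- reverse term: fragments [x - l + 1, x]
        int lmaxR = clipEdges ? lmax : std::min(lmax, x);
        double lamR = 0.0;
        if (lmaxR >= lmin) {
            thr.clear();
            if (nc) {
                int i = lower_idx(p, nc, x) - 1; // rightmost C <= x - 1
                while (i >= 0) {
                    int e = x - p[i] + 1; // smallest l with x-l+1 <= C
                    if (e > lmaxR) break;
                    thr.push_back(e < lmin ? lmin : e);
                    i = prv[i];
                }
            }
            int n = 0, prevl = lmin;
            for (size_t k = 0; k < thr.size(); ++k) {
                if (thr[k] > prevl)
                    lamR += cn[n > cap ? cap : n] * (cum(thr[k] - 1) - cum(prevl - 1));
                prevl = thr[k];
                ++n;
            }
            lamR += cn[n > cap ? cap : n] * (cum(lmaxR) - cum(prevl - 1));
        }
        out(x - 1, 0) = lamF;
        out(x - 1, 1) = lamR;
    }
    return out;
}

// Rejection-sampling acceptance for candidate pulldown fragments.  Each
// fragment [start, end] carries the CpGs with C in [start, end-1]; each CpG
// is methylated with probability mu[j]; n = greedy accessible count of the
// methylated subset; fragment accepted with probability C(min(n, cap))/C(cap).
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
LogicalVector cpp_pulldown_accept(IntegerVector starts, IntegerVector ends,
                                  IntegerVector cpg, NumericVector mu,
                                  NumericVector cn, int minSep) {
    int nf = starts.size(), nc = cpg.size(), cap = cn.size() - 1;
    if (mu.size() != nc) stop("mu must align with the CpG index");
    LogicalVector out(nf);
    const int* p = nc ? &cpg[0] : NULL;
    double cmax = cn[cap];
    for (int k = 0; k < nf; ++k) {
        int n = 0, last = -1000000;
        if (nc) {
            int i0 = lower_idx(p, nc, starts[k]);
            int i1 = lower_idx(p, nc, ends[k]) - 1;
            for (int i = i0; i <= i1; ++i) {
                if (mu[i] >= 1.0 || unif_rand() < mu[i]) { // methylated copy
                    if (n == 0 || (last + 1) + minSep < p[i]) {
                        ++n;
                        last = p[i];
                    }
                }
            }
        }
        double pacc = cn[n > cap ? cap : n] / cmax;
        out[k] = (pacc >= 1.0) || (unif_rand() < pacc);
    }
    return out;
}
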