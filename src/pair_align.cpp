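#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of two integer-encoded protein
// sequences under a substitution matrix and affine gaps (gap of length L
// costs gapOpen + L * gapExtend).  Alongside the score, the number of
// identical pairs and of aligned (non-gap) columns on the optimal path
// are tracked, so identity and per-sequence coverage come out of one
// pass without a traceback.  Ties are broken deterministically
// (M before Ix before Iy, open before extend), so results are
// reproducible.
//
// a, b: codes 0..(nrow(sub)-1); sub: square substitution matrix.
// [[Rcpp::export(name = ".pairLocalAlign")]]
List pairLocalAlign(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gapOpen, double gapExtend) {
    const int la = a.size(), lb = b.size();
    const double gapInit = gapOpen + gapExtend;
    const long long W = lb + 1;
    const int nsub = sub.nrow();
    const double *S = REAL(sub);           // column-major, stride nsub
    const int *pa = INTEGER(a), *pb = INTEGER(b);

    // per-state value plus propagated (origin, matches, aligned columns)
    std::vector<double> Mv(W, 0.0), Xv(W, R_NegInf), Yv(W, R_NegInf);
    std::vector<double> Mpv(W, 0.0), Xpv(W, R_NegInf), Ypv(W, R_NegInf);
    std::vector<long long> Mo(W), Xo(W, 0), Yo(W, 0), Mpo(W), Xpo(W, 0),
        Ypo(W, 0);
    std::vector<int> Mm(W, 0), Xm(W, 0), Ym(W, 0), Mpm(W, 0), Xpm(W, 0),
        Ypm(W, 0);
    std::vector<int> Mc(W, 0), Xc(W, 0), Yc(W, 0), Mpc(W, 0), Xpc(W, 0),
        Ypc(W, 0);
    for (long long j = 0; j < W; ++j) Mpo[j] = j;

    double best = 0.0;
    long long bestEnd = 0, bestOrig = 0;
    int bestMatch = 0, bestCols = 0;

    for (int i = 1; i <= la; ++i) {
        Mv[0] = 0.0; Mo[0] = (long long)i * W; Mm[0] = 0; Mc[0] = 0;
        Xv[0] = R_NegInf; Yv[0] = R_NegInf;
        const double *Srow = S + (size_t)pa[i - 1];   // sub(a[i-1], .)
        for (int j = 1; j <= lb; ++j) {
            const double s = Srow[(size_t)pb[j - 1] * nsub];
            const int eq = (pa[i - 1] == pb[j - 1]);
            // diagonal from best of three states at (i-1, j-1)
            double dv = Mpv[j - 1];
            long long dorig = Mpo[j - 1];
            int dm = Mpm[j - 1], dc = Mpc[j - 1];
            if (Xpv[j - 1] > dv) {
                dv = Xpv[j - 1]; dorig = Xpo[j - 1];
                dm = Xpm[j - 1]; dc = Xpc[j - 1];
            }
            if (Ypv[j - 1] > dv) {
                dv = Ypv[j - 1]; dorig = Ypo[j - 1];
                dm = Ypm[j - 1]; dc = Ypc[j - 1];
            }
            double mv = dv + s;
            if (mv < 0.0) {
                mv = 0.0; Mo[j] = (long long)i * W + j; Mm[j] = 0; Mc[j] = 0;
            } else {
                Mo[j] = dorig; Mm[j] = dm + eq; Mc[j] = dc + 1;
            }
            Mv[j] = mv;
            // Ix: gap in b (consumes a[i])
            if (Mpv[j] - gapInit >= Xpv[j] - gapExtend) {
                Xv[j] = Mpv[j] - gapInit; Xo[j] = Mpo[j];
                Xm[j] = Mpm[j]; Xc[j] = Mpc[j];
            } else {
                Xv[j] = Xpv[j] - gapExtend; Xo[j] = Xpo[j];
                Xm[j] = Xpm[j]; Xc[j] = Xpc[j];
            }
            // Iy: gap in a (consumes b[j])
            if (Mv[j - 1] - gapInit >= Yv[j - 1] - gapExtend) {
                Yv[j] = Mv[j - 1] - gapInit; Yo[j] = Mo[j - 1];
                Ym[j] = Mm[j - 1]; Yc[j] = Mc[j - 1];
            } else {
                Yv[j] = Yv[j - 1] - gapExtend; Yo[j] = Yo[j - 1];
                Ym[j] = Ym[j - 1]; Yc[j] = Yc[j - 1];
            }
            if (mv > best) {
                best = mv; bestEnd = (long long)i * W + j;
                bestOrig = Mo[j]; bestMatch = Mm[j]; bestCols = Mc[j];
            }
        }
        Mv.swap(Mpv); Xv.swap(Xpv); Yv.swap(Ypv);
        Mo.swap(Mpo); Xo.swap(Xpo); Yo.swap(Ypo);
        Mm.swap(Mpm); Xm.swap(Xpm); Ym.swap(Ypm);
        Mc.swap(Mpc); Xc.swap(Xpc); Yc.swap(Ypc);
    }

    int qend = (int)(bestEnd / W), tend = (int)(bestEnd % W);
    int qstart = (int)(bestOrig / W) + 1, tstart = (int)(bestOrig % W) + 1;
    if (best <= 0.0) {
        best = 0.0; qstart = qend = tstart = tend = 0;
        bestMatch = bestCols = 0;
    }
    return List::create(_["score"] = best, _["qstart"] = qstart,
                        _["qend"] = qend, _["tstart"] = tstart,
                        _["tend"] = tend, _["nmatch"] = bestMatch,
                        _["ncols"] = bestCols);
}
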