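#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a position-specific score matrix
// against an integer-encoded protein sequence, affine gaps: a gap of
// length L costs gapOpen + L * gapExtend (BLAST-style accounting, the
// same convention Biostrings::pairwiseAlignment uses).
//
// scores: 20 x L matrix (rows = residues in fixed A..Y order); seq uses
// codes 0..19, or -1 for X / unknown (substitution score 0 everywhere).
// Returns the best score and 1-based spans on profile (query) and
// sequence (target) coordinates; a best score of 0 means the empty
// alignment (all spans 0).
// [[Rcpp::export(name = ".profileLocalAlign")]]
List profileLocalAlign(NumericMatrix scores, IntegerVector seq,
                       double gapOpen, double gapExtend) {
    const int L = scores.ncol();       // profile length (query)
    const int n = seq.size();          // target length
    const double gapInit = gapOpen + gapExtend;
    const long long W = n + 1;         // packing stride for (i, j) cells

    // rolling rows; o* hold the packed start cell of the local alignment
    // ending in each cell (a cell clamped to 0 is its own start)
    std::vector<double> M(W, 0.0), Ix(W, R_NegInf), Iy(W, R_NegInf);
    std::vector<double> Mp(W, 0.0), Ixp(W, R_NegInf), Iyp(W, R_NegInf);
    std::vector<long long> oM(W, 0), oIx(W, 0), oIy(W, 0);
    std::vector<long long> oMp(W, 0), oIxp(W, 0), oIyp(W, 0);
    for (long long j = 0; j < W; ++j) oMp[j] = j;   // row 0 starts

    double best = 0.0;
    long long bestEnd = 0, bestOrig = 0;

    for (int i = 1; i <= L; ++i) {
        M[0] = 0.0; Ix[0] = R_NegInf; Iy[0] = R_NegInf;
        oM[0] = (long long)i * W;
        for (int j = 1; j <= n; ++j) {
            const int aa = seq[j - 1];
            const double sub = (aa >= 0) ? scores(aa, i - 1) : 0.0;
            // diagonal: best of the three states at (i-1, j-1)
            double diag = Mp[j - 1]; long long dOrig = oMp[j - 1];
            if (Ixp[j - 1] > diag) { diag = Ixp[j - 1]; dOrig = oIxp[j - 1]; }
            if (Iyp[j - 1] > diag) { diag = Iyp[j - 1]; dOrig = oIyp[j - 1]; }
            double m = diag + sub; long long om = dOrig;
            if (m < 0.0) { m = 0.0; om = (long long)(i) * W + j; }
            M[j] = m; oM[j] = om;
            // Ix: gap in the target (consumes profile position i)
            double ixO = Mp[j] - gapInit, ixE = Ixp[j] - gapExtend;
            if (ixO >= ixE) { Ix[j] = ixO; oIx[j] = oMp[j]; }
            else            { Ix[j] = ixE; oIx[j] = oIxp[j]; }
            // Iy: gap in the profile (consumes target residue j)
            double iyO = M[j - 1] - gapInit, iyE = Iy[j - 1] - gapExtend;
            if (iyO >= iyE) { Iy[j] = iyO; oIy[j] = oM[j - 1]; }
            else            { Iy[j] = iyE; oIy[j] = oIy[j - 1]; }
            if (M[j] > best) {
                best = M[j];
                bestEnd = (long long)i * W + j;
                bestOrig = om;
            }
        }
        std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
        std::swap(oM, oMp); std::swap(oIx, oIxp); std::swap(oIy, oIyp);
    }

    int qend = (int)(bestEnd / W), tend = (int)(bestEnd % W);
    int qstart = (int)(bestOrig / W) + 1, tstart = (int)(bestOrig % W) + 1;
    if (best <= 0.0) { qstart = qend = tstart = tend = 0; best = 0.0; }
    return List::create(_["score"] = best, _["qstart"] = qstart,
                        _["qend"] = qend, _["tstart"] = tstart,
                        _["tend"] = tend);
}
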