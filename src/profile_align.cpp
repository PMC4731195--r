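#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment of a position-specific score profile (given
// transposed: rows = residue alphabet, cols = profile columns, so one
// profile column is contiguous in memory) against a subject sequence
// given as 0-based alphabet indices. Affine gap of length k costs
// gapOpen + k * gapExtend (BLAST convention). Returns the single best
// local alignment with a traceback of matched (profile column, subject
// position) pairs; intervals are 0-based half-open.
//
// Traceback codes for H: 0 = stop, 1 = diagonal, 2 = gap in subject
// (profile column skipped, E), 3 = gap in profile (subject consumed, F).

// [[Rcpp::export(name = ".profileLocalAlign")]]
List profileLocalAlign(NumericMatrix prof, IntegerVector subj,
                       double gapOpen, double gapExtend) {
    const int A = prof.nrow();
    const int L = prof.ncol();
    const int M = subj.size();
    const double *pr = REAL(prof);
    const int *sj = INTEGER(subj);
    const double NEG = -1e30;
    const double openCost = gapOpen + gapExtend;

    std::vector<double> Hprev(M + 1, 0.0), Hcur(M + 1, 0.0);
    std::vector<double> Eprev(M + 1, NEG), Ecur(M + 1, NEG);
    // full traceback matrices (small inputs; L, M of order 1e3)
    std::vector<unsigned char> tbH((L + 1) * (M + 1), 0);
    std::vector<unsigned char> tbE((L + 1) * (M + 1), 0); // 1 = extend
    std::vector<unsigned char> tbF((L + 1) * (M + 1), 0);

    double best = 0.0;
    int bi = 0, bj = 0;

    for (int i = 1; i <= L; ++i) {
        Hcur[0] = 0.0;
        Ecur[0] = NEG;
        double Fij = NEG;
        const double *col = pr + (size_t)(i - 1) * A;
        for (int j = 1; j <= M; ++j) {
            const size_t idx = (size_t)i * (M + 1) + j;
            // E: gap in subject (move down the profile), from row i-1
            double eOpen = Hprev[j] - openCost;
            double eExt  = Eprev[j] - gapExtend;
            double E = eOpen >= eExt ? eOpen : eExt;
            tbE[idx] = (eExt > eOpen) ? 1 : 0;
            Ecur[j] = E;
            // F: gap in profile (consume subject), from column j-1
            double fOpen = Hcur[j - 1] - openCost;
            double fExt  = Fij - gapExtend;
            double F = fOpen >= fExt ? fOpen : fExt;
            tbF[idx] = (fExt > fOpen) ? 1 : 0;
            Fij = F;
            // H
            double diag = Hprev[j - 1] + col[sj[j - 1]];
            double h = 0.0;
            unsigned char code = 0;
            if (diag > h) { h = diag; code = 1; }
            if (E > h)    { h = E;    code = 2; }
            if (F > h)    { h = F;    code = 3; }
            Hcur[j] = h;
            tbH[idx] = code;
            // strict > keeps the first (smallest i, then j) maximum:
            // deterministic tie-break
            if (h > best) {
                best = h;
                bi = i; bj = j;
            }
        }
        std::swap(Hprev, Hcur);
        std::swap(Eprev, Ecur);
    }

    std::vector<int> qcols, spos;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
        const size_t idx = (size_t)i * (M + 1) + j;
        if (state == 0) {
            unsigned char c = tbH[idx];
            if (c == 0) break;
            if (c == 1) {
                qcols.push_back(i - 1);
                spos.push_back(j - 1);
                --i; --j;
            } else if (c == 2) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            unsigned char c = tbE[idx];
            --i;
            if (c == 0) state = 0;
        } else {
            unsigned char c = tbF[idx];
            --j;
            if (c == 0) state = 0;
        }
    }
    std::reverse(qcols.begin(), qcols.end());
    std::reverse(spos.begin(), spos.end());

    int qs = 0, qe = 0, ss = 0, se = 0;
    if (!qcols.empty()) {
        qs = qcols.front(); qe = qcols.back() + 1;
        ss = spos.front();  se = spos.back() + 1;
    }
    return List::create(
        _["score"] = best,
        _["q_start"] = qs, _["q_end"] = qe,
        _["s_start"] = ss, _["s_end"] = se,
        _["q_cols"] = wrap(qcols),
        _["s_pos"] = wrap(spos));
}
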