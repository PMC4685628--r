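#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cross-validated MDR over SNP pairs. Genotype codes are 0/1/2; any
// negative value (including NA_INTEGER) is missing.
//
// Per pair and fold, the training 3x3 cell counts are the totals minus
// the held-out fold's counts, so one pass over samples fills every
// fold's grid at once. Cell label rule: empty if the training cell holds
// neither cases nor controls, else high-risk iff cases/controls >= T,
// where by default T is the training case:control ratio (compared by
// cross-multiplication, so no division). policy 0: empty cells and
// missing test genotypes predict control (low risk); policy 1: they
// count as misclassified. The pair's CVV is the mean held-out balanced
// accuracy over folds (folds with no held-out samples are skipped; folds
// missing one class contribute the defined term only).

// [[Rcpp::export]]
NumericVector cpp_scan_cvv(IntegerMatrix G, IntegerVector status,
                           IntegerVector folds, int n_folds,
                           IntegerMatrix pairs, bool use_train_ratio,
                           double T, int policy) {
  const int n = G.nrow();
  const int P = pairs.nrow();
  NumericVector out(P);

  // per-fold class totals (independent of the pair)
  std::vector<int> fold_case(n_folds, 0), fold_ctrl(n_folds, 0);
  int tot_case = 0, tot_ctrl = 0;
  for (int i = 0; i < n; ++i) {
    const int f = folds[i] - 1;
    if (status[i] == 1) { ++fold_case[f]; ++tot_case; }
    else { ++fold_ctrl[f]; ++tot_ctrl; }
  }

  std::vector<int> cc(n_folds * 9), cn(n_folds * 9);
  std::vector<int> tot_cc(9), tot_cn(9);
  std::vector<int> lab(n_folds * 9);
  std::vector<int> tp(n_folds), tn(n_folds);

  for (int p = 0; p < P; ++p) {
    const int v1 = pairs(p, 0), v2 = pairs(p, 1);
    std::fill(cc.begin(), cc.end(), 0);
    std::fill(cn.begin(), cn.end(), 0);
    std::fill(tot_cc.begin(), tot_cc.end(), 0);
    std::fill(tot_cn.begin(), tot_cn.end(), 0);

    for (int i = 0; i < n; ++i) {
      const int g1 = G(i, v1), g2 = G(i, v2);
      if (g1 < 0 || g2 < 0) continue;
      const int c = g1 * 3 + g2;
      const int f = folds[i] - 1;
      if (status[i] == 1) { ++cc[f * 9 + c]; ++tot_cc[c]; }
      else { ++cn[f * 9 + c]; ++tot_cn[c]; }
    }

    for (int f = 0; f < n_folds; ++f) {
      const int tr_case = tot_case - fold_case[f];
      const int tr_ctrl = tot_ctrl - fold_ctrl[f];
      for (int c = 0; c < 9; ++c) {
        const int ca = tot_cc[c] - cc[f * 9 + c];
        const int co = tot_cn[c] - cn[f * 9 + c];
        if (ca == 0 && co == 0) lab[f * 9 + c] = -1;
        else if (use_train_ratio)
          lab[f * 9 + c] = ((double)ca * (double)tr_ctrl >=
                            (double)co * (double)tr_case) ? 1 : 0;
        else
          lab[f * 9 + c] = ((double)ca >= T * (double)co) ? 1 : 0;
      }
    }

    std::fill(tp.begin(), tp.end(), 0);
    std::fill(tn.begin(), tn.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int f = folds[i] - 1;
      const int g1 = G(i, v1), g2 = G(i, v2);
      const int labc = (g1 < 0 || g2 < 0) ? -1 : lab[f * 9 + g1 * 3 + g2];
      int pred;
      if (labc == 1) pred = 1;
      else if (labc == 0) pred = 0;
      else pred = (policy == 0) ? 0 : 1 - status[i];
      if (status[i] == 1) { if (pred == 1) ++tp[f]; }
      else { if (pred == 0) ++tn[f]; }
    }

    long double cvv_sum = 0.0L;
    int n_ba = 0;
    for (int f = 0; f < n_folds; ++f) {
      double ba;
      if (fold_case[f] > 0 && fold_ctrl[f] > 0)
        ba = ((double)tp[f] / fold_case[f] +
              (double)tn[f] / fold_ctrl[f]) / 2.0;
      else if (fold_case[f] > 0) ba = (double)tp[f] / fold_case[f];
      else if (fold_ctrl[f] > 0) ba = (double)tn[f] / fold_ctrl[f];
      else continue;  // empty fold
      cvv_sum += ba;
      ++n_ba;
    }
    out[p] = n_ba ? ((double)cvv_sum) / n_ba : NA_REAL;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
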