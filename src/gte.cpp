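// Plug-in (histogram) estimator of generalized Transfer Entropy for all
// ordered neuron pairs.  Symbol streams are pre-encoded in R into two
// integer codes per neuron and sample:
//   tp[t, i] = x_i[t] + b * (k-step past of x_i)        (target part)
//   sp[t, j] = source history of x_j, including x_j[t] itself when
//              same-bin interactions are enabled
// Only samples whose (latest) time index passes the conditioning mask are
// used; `valid` holds those indices (0-based).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix gte_matrix_cpp(IntegerMatrix tp, IntegerMatrix sp,
                             IntegerVector valid, int b, int n_tp, int n_sp)
{
  const int N = tp.ncol();
  const int n = valid.size();
  const int n_tgt_past = n_tp / b;                // distinct target-past codes
  const int n_joint = n_tp * n_sp;

  NumericMatrix te(N, N);
  std::fill(te.begin(), te.end(), NA_REAL);

  std::vector<int> joint(n_joint);
  std::vector<double> c_tgt_past(n_tgt_past), c_fut_tgt(n_tp);
  std::vector<double> c_tgt_src(n_tgt_past * n_sp);
  const double inv_log2 = 1.0 / std::log(2.0);

  // cache per-target column pointers and validity-filtered target codes
  std::vector<int> tcode(n);

  for (int i = 0; i < N; ++i) {            // target
    const int* tcol = &tp(0, i);
    for (int t = 0; t < n; ++t) tcode[t] = tcol[valid[t]];

    // target-only margins are shared across sources
    std::fill(c_tgt_past.begin(), c_tgt_past.end(), 0.0);
    std::fill(c_fut_tgt.begin(), c_fut_tgt.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      c_fut_tgt[tcode[t]] += 1.0;
      c_tgt_past[tcode[t] / b] += 1.0;
    }

    for (int j = 0; j < N; ++j) {          // source
      if (j == i) continue;
      const int* scol = &sp(0, j);

      std::fill(joint.begin(), joint.end(), 0);
      for (int t = 0; t < n; ++t)
        ++joint[tcode[t] + n_tp * scol[valid[t]]];

      std::fill(c_tgt_src.begin(), c_tgt_src.end(), 0.0);
      for (int s = 0; s < n_sp; ++s) {
        const int off = s * n_tp;
        const int off2 = s * n_tgt_past;
        for (int c = 0; c < n_tp; ++c)
          c_tgt_src[off2 + c / b] += joint[off + c];
      }

      double sum = 0.0;
      for (int s = 0; s < n_sp; ++s) {
        const int off = s * n_tp;
        const int off2 = s * n_tgt_past;
        for (int c = 0; c < n_tp; ++c) {
          const int cnt = joint[off + c];
          if (cnt == 0) continue;
          const double num = (double)cnt * c_tgt_past[c / b];
          const double den = c_tgt_src[off2 + c / b] * c_fut_tgt[c];
          sum += cnt * std::log(num / den);
        }
      }
      te(j, i) = sum * inv_log2 / (double)n;   // row = source, col = target
    }
  }
  return te;
}
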