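#include <Rcpp.h>
using namespace Rcpp;

// Synthesise a V x nvol diffusion-weighted signal matrix from a per-voxel
// region label (0 = background, 1..K-1 = regions) and a K x nvol table of
// noise-free region signals. noise_model: 0 none, 1 additive Gaussian,
// 2 Rician (Gaussian on two quadrature channels, magnitude taken).
// Noise is drawn through R's norm_rand(), so results are reproducible
// under set.seed().
// [[Rcpp::export(name = ".phantom_signal")]]
NumericMatrix phantom_signal(IntegerVector labels, NumericMatrix region_signal,
                             double noise_sd, int noise_model) {
  R_xlen_t V = labels.size();
  int nvol = region_signal.ncol();
  int K = region_signal.nrow();
  NumericMatrix out(V, nvol);
  std::vector<double> s(K);
  const int *lab = INTEGER(labels);
  for (int j = 0; j < nvol; ++j) {
    for (int k = 0; k < K; ++k) s[k] = region_signal(k, j);
    double *col = &out(0, j);
    if (noise_model == 1 && noise_sd > 0) {
      for (R_xlen_t i = 0; i < V; ++i)
        col[i] = s[lab[i]] + norm_rand() * noise_sd;
    } else if (noise_model == 2 && noise_sd > 0) {
      for (R_xlen_t i = 0; i < V; ++i) {
        double re = s[lab[i]] + norm_rand() * noise_sd;
        double im = norm_rand() * noise_sd;
        col[i] = std::sqrt(re * re + im * im);
      }
    } else {
      for (R_xlen_t i = 0; i < V; ++i) col[i] = s[lab[i]];
    }
  }
  return out;
}
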