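// One Laplacian-contraction sweep: for every point, the displacement to its
// neighbourhood mean projected orthogonally to the local principal (curve)
// direction, so contraction squeezes cross-sections without sliding points
// along the structure.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".contract_step_cpp")]]
NumericMatrix contract_step_cpp(NumericMatrix x, List nb) {
  int n = x.nrow();
  NumericMatrix step(n, 3);
  for (int i = 0; i < n; ++i) {
    IntegerVector idx = nb[i];
    int m = idx.size();
    if (m == 0) continue;
    double mu[3] = {0, 0, 0};
    for (int j = 0; j < m; ++j) {
      int p = idx[j] - 1;
      mu[0] += x(p, 0); mu[1] += x(p, 1); mu[2] += x(p, 2);
    }
    mu[0] /= m; mu[1] /= m; mu[2] /= m;
    double d[3] = {mu[0] - x(i, 0), mu[1] - x(i, 1), mu[2] - x(i, 2)};
    if (m >= 3) {
      // covariance of the neighbourhood
      double C[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int j = 0; j < m; ++j) {
        int p = idx[j] - 1;
        double e[3] = {x(p,0)-mu[0], x(p,1)-mu[1], x(p,2)-mu[2]};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) C[a][b] += e[a]*e[b];
      }
      // principal direction by power iteration
      double v[3] = {1.0, 1.0, 1.0};
      for (int it = 0; it < 20; ++it) {
        double w[3];
        for (int a = 0; a < 3; ++a)
          w[a] = C[a][0]*v[0] + C[a][1]*v[1] + C[a][2]*v[2];
        double nv = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
        if (nv < 1e-30) break;
        v[0] = w[0]/nv; v[1] = w[1]/nv; v[2] = w[2]/nv;
      }
      double dv = d[0]*v[0] + d[1]*v[1] + d[2]*v[2];
      d[0] -= dv*v[0]; d[1] -= dv*v[1]; d[2] -= dv*v[2];
    }
    step(i, 0) = d[0]; step(i, 1) = d[1]; step(i, 2) = d[2];
  }
  return step;
}
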