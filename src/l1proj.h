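#ifndef SSAESCREEN_L1PROJ_H
#define SSAESCREEN_L1PROJ_H

#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>

// Exact sort-based Euclidean projection of x onto the l1 ball of the given
// radius (Duchi et al.): sort magnitudes, find the pivot, soft-threshold.
static inline void project_vec_l1(double* x, int m, double radius) {
  double s = 0.0;
  for (int j = 0; j < m; ++j) s += std::fabs(x[j]);
  if (s <= radius) return;
  std::vector<double> u(m);
  for (int j = 0; j < m; ++j) u[j] = std::fabs(x[j]);
  std::sort(u.begin(), u.end(), std::greater<double>());
  double css = 0.0, theta = 0.0;
  for (int j = 0; j < m; ++j) {
    css += u[j];
    double t = (css - radius) / (j + 1);
    if (u[j] - t > 0) theta = t;
  }
  for (int j = 0; j < m; ++j) {
    double a = std::fabs(x[j]) - theta;
    x[j] = a > 0 ? (x[j] > 0 ? a : -a) : 0.0;
  }
}

// Bilevel l1,1 projection on a column-major d x h matrix held in w.
static inline void project_l11_colmajor(double* w, int d, int h, double eta) {
  std::vector<double> t(d, 0.0);
  for (int j = 0; j < h; ++j) {
    const double* col = w + (size_t)j * d;
    for (int i = 0; i < d; ++i) t[i] += std::fabs(col[i]);
  }
  double tot = 0.0;
  for (int i = 0; i < d; ++i) tot += t[i];
  if (tot <= eta) return;
  std::vector<double> budget(t);
  project_vec_l1(budget.data(), d, eta);
  std::vector<double> row(h);
  for (int i = 0; i < d; ++i) {
    if (budget[i] <= 0.0) {
      for (int j = 0; j < h; ++j) w[i + (size_t)j * d] = 0.0;
    } else if (t[i] > budget[i]) {
      for (int j = 0; j < h; ++j) row[j] = w[i + (size_t)j * d];
      project_vec_l1(row.data(), h, budget[i]);
      for (int j = 0; j < h; ++j) w[i + (size_t)j * d] = row[j];
    }
  }
}

#endif
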