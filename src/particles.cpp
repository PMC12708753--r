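#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform radial table. Separations beyond the last
// abscissa (r = L/2) use the final table value; the gradient table ends at 0
// there, so forces vanish smoothly instead of picking up mirror images.
static inline double tab_lookup(double r, const double *tab, int m, double dr) {
  if (r <= 0.0) return tab[0];
  double s = r / dr;
  int i = (int)s;
  if (i >= m - 1) return tab[m - 1];
  double w = s - i;
  return (1.0 - w) * tab[i] + w * tab[i + 1];
}

static inline double min_image(double x, double L) {
  return x - L * std::round(x / L);
}

// Mean pairwise kernel-gradient at each particle:
//   F_i = (1/N) sum_j dV(|x_i - x_j|) * (x_i - x_j)/|x_i - x_j|
// with minimum-image displacements. The j = i term contributes 0 (dV(0) = 0).
// Accumulated pairwise (i<j) so Newton's third law holds to rounding.
// [[Rcpp::export]]
NumericMatrix pair_force_sum(const NumericMatrix &X, double L,
                             const NumericVector &dV_tab, double dr_tab) {
  const int N = X.nrow(), d = X.ncol(), m = dV_tab.size();
  NumericMatrix F(N, d);
  std::vector<double> dx(d);
  const double *tab = dV_tab.begin();
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double r2 = 0.0;
      for (int c = 0; c < d; ++c) {
        dx[c] = min_image(X(i, c) - X(j, c), L);
        r2 += dx[c] * dx[c];
      }
      double r = std::sqrt(r2);
      if (r < 1e-14) continue;
      double f = tab_lookup(r, tab, m, dr_tab) / r;
      for (int c = 0; c < d; ++c) {
        double fc = f * dx[c];
        F(i, c) += fc;
        F(j, c) -= fc;
      }
    }
  }
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < d; ++c) F(i, c) /= N;
  return F;
}

// Interaction energy (1/N^2) sum_{i,j} V(|x_i - x_j|), diagonal included.
// [[Rcpp::export]]
double pair_energy(const NumericMatrix &X, double L,
                   const NumericVector &V_tab, double dr_tab) {
  const int N = X.nrow(), d = X.ncol(), m = V_tab.size();
  const double *tab = V_tab.begin();
  double E = N * tab[0];  // diagonal terms V(0)
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double r2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double dx = min_image(X(i, c) - X(j, c), L);
        r2 += dx * dx;
      }
      E += 2.0 * tab_lookup(std::sqrt(r2), tab, m, dr_tab);
    }
  }
  return E / ((double)N * (double)N);
}

// Cloud-in-cell deposition onto the n^d node lattice of [-L/2, L/2)^d.
// Returns cell weights summing to 1 (divide by h^d for a density).
// [[Rcpp::export]]
NumericVector cic_deposit_cpp(const NumericMatrix &X, int n, double L) {
  const int N = X.nrow(), d = X.ncol();
  const double h = L / n;
  long ncell = 1;
  for (int c = 0; c < d; ++c) ncell *= n;
  NumericVector out(ncell);
  std::vector<int> i0(d);
  std::vector<double> fr(d);
  const int ncorner = 1 << d;
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < d; ++c) {
      double g = (X(i, c) + L / 2.0) / h;
      double fl = std::floor(g);
      i0[c] = (int)fl;
      fr[c] = g - fl;
    }
    for (int corner = 0; corner < ncorner; ++corner) {
      double w = 1.0;
      long idx = 0, stride = 1;
      for (int c = 0; c < d; ++c) {
        int up = (corner >> c) & 1;
        w *= up ? fr[c] : (1.0 - fr[c]);
        int ic = (i0[c] + up) % n;
        if (ic < 0) ic += n;
        idx += stride * ic;
        stride *= n;
      }
      out[idx] += w;
    }
  }
  for (long k = 0; k < ncell; ++k) out[k] /= N;
  return out;
}

// Nearest-grid-point deposition; same normalization as cic_deposit_cpp.
// [[Rcpp::export]]
NumericVector ngp_deposit_cpp(const NumericMatrix &X, int n, double L) {
  const int N = X.nrow(), d = X.ncol();
  const double h = L / n;
  long ncell = 1;
  for (int c = 0; c < d; ++c) ncell *= n;
  NumericVector out(ncell);
  for (int i = 0; i < N; ++i) {
    long idx = 0, stride = 1;
    for (int c = 0; c < d; ++c) {
      int ic = (int)std::floor((X(i, c) + L / 2.0) / h + 0.5);
      ic %= n;
      if (ic < 0) ic += n;
      idx += stride * ic;
      stride *= n;
    }
    out[idx] += 1.0;
  }
  for (long k = 0; k < ncell; ++k) out[k] /= N;
  return out;
}

// Multilinear (CIC) gather of a nodal field at particle positions.
// [[Rcpp::export]]
NumericVector cic_gather_cpp(const NumericVector &field, const NumericMatrix &X,
                             int n, double L) {
  const int N = X.nrow(), d = X.ncol();
  const double h = L / n;
  NumericVector out(N);
  std::vector<int> i0(d);
  std::vector<double> fr(d);
  const int ncorner = 1 << d;
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < d; ++c) {
      double g = (X(i, c) + L / 2.0) / h;
      double fl = std::floor(g);
      i0[c] = (int)fl;
      fr[c] = g - fl;
    }
    double acc = 0.0;
    for (int corner = 0; corner < ncorner; ++corner) {
      double w = 1.0;
      long idx = 0, stride = 1;
      for (int c = 0; c < d; ++c) {
        int up = (corner >> c) & 1;
        w *= up ? fr[c] : (1.0 - fr[c]);
        int ic = (i0[c] + up) % n;
        if (ic < 0) ic += n;
        idx += stride * ic;
        stride *= n;
      }
      acc += w * field[idx];
    }
    out[i] = acc;
  }
  return out;
}
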