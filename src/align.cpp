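// Alignment and distance kernels.
//
// Sequences are passed from R as integer vectors with the encoding
// A=0, C=1, G=2, T=3, anything else (N, gap) >= 4.  Ambiguous bases score 0
// against everything; gap costs follow the gapOpening + L*gapExtension
// convention, i.e. a gap of length L costs open + L * extend.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double subst(int a, int b, double match, double mismatch) {
  if (a >= 4 || b >= 4) return 0.0;
  return (a == b) ? match : mismatch;
}

// Optimal local alignment score, affine gaps, score only (linear memory).
// Hot path: raw buffers, finite sentinels, F kept in its own row buffer.
double sw_score_raw(const int *a, int m, const int *b, int n, double match,
                    double mismatch, double gap_open, double gap_extend) {
  if (m == 0 || n == 0) return 0.0;
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;
  std::vector<double> H(n + 1, 0.0), F(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    double diag = 0.0;       // H[i-1][j-1]
    double h_left = 0.0;     // H[i][j-1]
    double e_left = NEG;     // E[i][j-1]
    double *Hp = H.data();
    double *Fp = F.data();
    for (int j = 1; j <= n; ++j) {
      const int bj = b[j - 1];
      double e = e_left - gap_extend;
      double eo = h_left - go;
      if (eo > e) e = eo;
      double f = Fp[j] - gap_extend;
      double fo = Hp[j] - go;
      if (fo > f) f = fo;
      Fp[j] = f;
      double s = (ai >= 4 || bj >= 4) ? 0.0 : (ai == bj ? match : mismatch);
      double h = diag + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      diag = Hp[j];
      Hp[j] = h;
      h_left = h;
      e_left = e;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score_cpp(IntegerVector a, IntegerVector b, double match,
                    double mismatch, double gap_open, double gap_extend) {
  return sw_score_raw(a.begin(), a.size(), b.begin(), b.size(), match,
                      mismatch, gap_open, gap_extend);
}

// Score every query against every subject; returns |queries| x |subjects|.
// [[Rcpp::export(name = ".sw_score_matrix")]]
NumericMatrix sw_score_matrix_cpp(List queries, List subjects, double match,
                                  double mismatch, double gap_open,
                                  double gap_extend) {
  const int nq = queries.size(), ns = subjects.size();
  NumericMatrix out(nq, ns);
  std::vector<std::vector<int>> subj(ns);
  for (int j = 0; j < ns; ++j) {
    IntegerVector s = subjects[j];
    subj[j].assign(s.begin(), s.end());
  }
  for (int i = 0; i < nq; ++i) {
    IntegerVector qv = queries[i];
    std::vector<int> q(qv.begin(), qv.end());
    for (int j = 0; j < ns; ++j) {
      out(i, j) = sw_score_raw(q.data(), q.size(), subj[j].data(),
                               subj[j].size(), match, mismatch, gap_open,
                               gap_extend);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full local alignment with traceback.  Returns score plus the summary
// quantities of a blast-style tabular hit (identities over alignment
// columns, gap opens, endpoints, 1-based inclusive).
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback_cpp(IntegerVector a, IntegerVector b, double match,
                      double mismatch, double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  arma::mat H(m + 1, n + 1, arma::fill::zeros);
  arma::mat E(m + 1, n + 1), F(m + 1, n + 1);
  E.fill(R_NegInf);
  F.fill(R_NegInf);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(E(i, j - 1) - gap_extend,
                         H(i, j - 1) - gap_open - gap_extend);
      F(i, j) = std::max(F(i - 1, j) - gap_extend,
                         H(i - 1, j) - gap_open - gap_extend);
      double h = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch);
      h = std::max(std::max(h, E(i, j)), std::max(F(i, j), 0.0));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, mismatches = 0, gapopen = 0, gapres = 0, cols = 0;
  int i = bi, j = bj, qend = bi, send = bj;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) <= 0.0) break;
      double d = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch);
      if (H(i, j) == d) {
        ++cols;
        if (a[i - 1] < 4 && a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
        --i; --j;
      } else if (H(i, j) == E(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++cols; ++gapres;
      if (E(i, j) == H(i, j - 1) - gap_open - gap_extend) {
        ++gapopen; state = 0;
      }
      --j;
    } else {
      ++cols; ++gapres;
      if (F(i, j) == H(i - 1, j) - gap_open - gap_extend) {
        ++gapopen; state = 0;
      }
      --i;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["mismatches"] = mismatches, _["gap_opens"] = gapopen,
                      _["gap_residues"] = gapres, _["aln_length"] = cols,
                      _["q_start"] = i + 1, _["q_end"] = qend,
                      _["s_start"] = j + 1, _["s_end"] = send);
}

// Global profile-profile alignment in codon units (Needleman-Wunsch,
// affine gaps, end gaps charged).  Profiles are (#codon columns) x 12
// matrices: positions 1..3 within the codon times letters A,C,G,T, holding
// per-position letter frequencies over the rows of the group (gap rows
// contribute no mass).  Returns the merge path as a vector of moves:
// 0 = consume a column of both profiles, 1 = column of profile 1 only
// (gap inserted into profile 2), 2 = column of profile 2 only.
// [[Rcpp::export(name = ".nw_profile")]]
IntegerVector nw_profile_cpp(NumericMatrix p1, NumericMatrix p2,
                             double gap_open, double gap_extend) {
  const int m = p1.nrow(), n = p2.nrow();
  // Pre-compute per-position occupancy (sum of letter mass).
  arma::mat a1(p1.begin(), m, 12, false), a2(p2.begin(), n, 12, false);
  arma::mat occ1(m, 3), occ2(n, 3);
  for (int p = 0; p < 3; ++p) {
    occ1.col(p) = arma::sum(a1.cols(4 * p, 4 * p + 3), 1);
    occ2.col(p) = arma::sum(a2.cols(4 * p, 4 * p + 3), 1);
  }
  arma::mat M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  arma::imat tbM(m + 1, n + 1, arma::fill::zeros),
      tbX(m + 1, n + 1, arma::fill::zeros),
      tbY(m + 1, n + 1, arma::fill::zeros);
  const double NEG = -1e30;
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) {  // X: gap in profile 2 (consume p1)
    X(i, 0) = -gap_open - gap_extend * i;
    tbX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y(0, j) = -gap_open - gap_extend * j;
    tbY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // match score: sum over positions of (2 * dot - occ1*occ2) for +1/-1
      double s = 0.0;
      for (int p = 0; p < 3; ++p) {
        double dot = arma::dot(a1(arma::span(i - 1, i - 1), arma::span(4 * p, 4 * p + 3)),
                               a2(arma::span(j - 1, j - 1), arma::span(4 * p, 4 * p + 3)));
        s += 2.0 * dot - occ1(i - 1, p) * occ2(j - 1, p);
      }
      double m0 = M(i - 1, j - 1), x0 = X(i - 1, j - 1), y0 = Y(i - 1, j - 1);
      double bestPrev = m0; int tb = 0;
      if (x0 > bestPrev) { bestPrev = x0; tb = 1; }
      if (y0 > bestPrev) { bestPrev = y0; tb = 2; }
      M(i, j) = bestPrev + s; tbM(i, j) = tb;

      double xo = M(i - 1, j) - gap_open - gap_extend;
      double xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 0; }
      else          { X(i, j) = xe; tbX(i, j) = 1; }

      double yo = M(i, j - 1) - gap_open - gap_extend;
      double ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 0; }
      else          { Y(i, j) = ye; tbY(i, j) = 2; }
    }
  }
  int state = 0;
  double fin = M(m, n);
  if (X(m, n) > fin) { fin = X(m, n); state = 1; }
  if (Y(m, n) > fin) { fin = Y(m, n); state = 2; }
  std::vector<int> path;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      state = tbM(i, j);
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      state = tbX(i, j);
      --i;
    } else {
      path.push_back(2);
      state = tbY(i, j);
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// ---------------------------------------------------------------------------
// GTR pairwise distances.
//
// d = -tr(Pi logm(Pi^-1 F)) with F the symmetrised divergence matrix and
// Pi = diag of its marginal frequencies; gamma rate heterogeneity applies
// the transform -log(e) -> alpha * (e^(-1/alpha) - 1) to the eigenvalues
// (the standard gamma correction, exact for JC, an approximation for GTR).
// Bases absent from both sequences are dropped from the state space.

static double gtr_pair_dist(const int *x, const int *y, const int *idx,
                            int L, double gamma_shape, double max_dist) {
  double C[4][4] = {{0}};
  double total = 0.0, offdiag = 0.0;
  for (int s = 0; s < L; ++s) {
    int k = idx ? idx[s] : s;
    int a = x[k], b = y[k];
    if (a < 4 && b < 4) {
      C[a][b] += 1.0;
      total += 1.0;
      if (a != b) offdiag += 1.0;
    }
  }
  if (total == 0.0) return max_dist;
  if (offdiag == 0.0) return 0.0;
  // symmetrise and keep only bases actually observed
  int keep[4], nk = 0;
  double rowmass[4];
  for (int a = 0; a < 4; ++a) {
    rowmass[a] = 0.0;
    for (int b = 0; b < 4; ++b) rowmass[a] += C[a][b] + C[b][a];
    if (rowmass[a] > 0) keep[nk++] = a;
  }
  arma::mat F(nk, nk), Pi(nk, nk, arma::fill::zeros);
  for (int i = 0; i < nk; ++i) {
    double pi_i = 0.0;
    for (int j = 0; j < nk; ++j) {
      F(i, j) = (C[keep[i]][keep[j]] + C[keep[j]][keep[i]]) / (2.0 * total);
      pi_i += F(i, j);
    }
    Pi(i, i) = pi_i;
  }
  arma::mat A = arma::solve(Pi, F);
  arma::cx_vec eigval;
  arma::cx_mat eigvec;
  if (!arma::eig_gen(eigval, eigvec, A)) return max_dist;
  for (int i = 0; i < nk; ++i)
    if (eigval(i).real() <= 1e-12) return max_dist;  // saturated
  arma::cx_mat W;
  bool ok = true;
  try {
    W = arma::inv(eigvec) * arma::cx_mat(Pi, arma::zeros(nk, nk)) * eigvec;
  } catch (...) {
    ok = false;
  }
  if (!ok) return max_dist;
  std::complex<double> acc(0.0, 0.0);
  for (int i = 0; i < nk; ++i) {
    std::complex<double> lam = eigval(i);
    std::complex<double> h;
    if (R_finite(gamma_shape) && gamma_shape > 0) {
      h = gamma_shape * (std::pow(lam, -1.0 / gamma_shape) - 1.0);
    } else {
      h = -std::log(lam);
    }
    acc += W(i, i) * h;
  }
  double d = acc.real();
  if (!R_finite(d) || d < 0.0) d = (d < 0.0 && d > -1e-9) ? 0.0 : max_dist;
  return std::min(d, max_dist);
}

// [[Rcpp::export(name = ".gtr_dist")]]
NumericMatrix gtr_dist_cpp(IntegerMatrix x, double gamma_shape,
                           double max_dist) {
  const int n = x.nrow(), L = x.ncol();
  // row-major copies for cache-friendly pair scans
  std::vector<std::vector<int>> rows(n, std::vector<int>(L));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) rows[i][s] = x(i, s);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = gtr_pair_dist(rows[i].data(), rows[j].data(), nullptr, L,
                               gamma_shape, max_dist);
      out(i, j) = d;
      out(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Bootstrap distance matrices: idx is a (reps x L') matrix of 1-based
// column indices into x; one distance matrix per replicate.
// [[Rcpp::export(name = ".gtr_boot_dist")]]
List gtr_boot_dist_cpp(IntegerMatrix x, IntegerMatrix idx, double gamma_shape,
                       double max_dist) {
  const int n = x.nrow(), L = x.ncol(), reps = idx.nrow(), Lb = idx.ncol();
  std::vector<std::vector<int>> rows(n, std::vector<int>(L));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) rows[i][s] = x(i, s);
  List out(reps);
  std::vector<int> cols(Lb);
  for (int r = 0; r < reps; ++r) {
    for (int s = 0; s < Lb; ++s) cols[s] = idx(r, s) - 1;
    NumericMatrix D(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = gtr_pair_dist(rows[i].data(), rows[j].data(), cols.data(),
                                 Lb, gamma_shape, max_dist);
        D(i, j) = d;
        D(j, i) = d;
      }
    out[r] = D;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
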