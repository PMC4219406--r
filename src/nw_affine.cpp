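#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-vs-column score matrix S (rows = positions of A, cols = positions
// of B). A gap run of length L costs open + ext * L. Used for profile-profile
// merges in the progressive aligner and for profile-to-sequence scoring, so
// the same kernel serves both; only S changes.
//
// Returns the optimal score and the aligned path as two integer vectors of
// equal length holding 1-based positions into A and B, with 0 marking a gap.

static const int ST_M = 0, ST_X = 1, ST_Y = 2; // X: gap in B (consume A)

// [[Rcpp::export(name = ".nw_affine_path")]]
List nw_affine_path(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<unsigned char> bM((n + 1) * (m + 1), 0), bX(bM), bY(bM);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(open + ext * i);
    bX[at(i, 0)] = (i == 1) ? ST_M : ST_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(open + ext * j);
    bY[at(0, j)] = (j == 1) ? ST_M : ST_Y;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = dM; unsigned char bs = ST_M;
      if (dX > best) { best = dX; bs = ST_X; }
      if (dY > best) { best = dY; bs = ST_Y; }
      M[at(i, j)] = best + S(i - 1, j - 1);
      bM[at(i, j)] = bs;
      // X: consume A[i], gap in B
      double oM = M[at(i - 1, j)] - (open + ext), oX = X[at(i - 1, j)] - ext;
      if (oM >= oX) { X[at(i, j)] = oM; bX[at(i, j)] = ST_M; }
      else          { X[at(i, j)] = oX; bX[at(i, j)] = ST_X; }
      // Y: consume B[j], gap in A
      double pM = M[at(i, j - 1)] - (open + ext), pY = Y[at(i, j - 1)] - ext;
      if (pM >= pY) { Y[at(i, j)] = pM; bY[at(i, j)] = ST_M; }
      else          { Y[at(i, j)] = pY; bY[at(i, j)] = ST_Y; }
    }
  }
  double sM = M[at(n, m)], sX = X[at(n, m)], sY = Y[at(n, m)];
  double score = sM; int st = ST_M;
  if (sX > score) { score = sX; st = ST_X; }
  if (sY > score) { score = sY; st = ST_Y; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == ST_M) {
      int prev = bM[at(i, j)];
      pa.push_back(i); pb.push_back(j); --i; --j; st = prev;
    } else if (st == ST_X) {
      int prev = bX[at(i, j)];
      pa.push_back(i); pb.push_back(0); --i; st = prev;
    } else {
      int prev = bY[at(i, j)];
      pa.push_back(0); pb.push_back(j); --j; st = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}

// Score-only variant with rolling rows (used when scanning a large pool of
// sequences against a profile, where the traceback is not needed).

// [[Rcpp::export(name = ".nw_affine_score")]]
double nw_affine_score(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  std::vector<double> M0(m + 1, NEG), X0(m + 1, NEG), Y0(m + 1, NEG),
      M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = 0.0;
  for (int j = 1; j <= m; ++j) Y0[j] = -(open + ext * j);
  for (int i = 1; i <= n; ++i) {
    M1.assign(m + 1, NEG); Y1.assign(m + 1, NEG);
    X1[0] = -(open + ext * i);
    for (int j = 1; j <= m; ++j) {
      double d = std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
      M1[j] = d + S(i - 1, j - 1);
      X1[j] = std::max(M0[j] - (open + ext), X0[j] - ext);
      Y1[j] = std::max(M1[j - 1] - (open + ext), Y1[j - 1] - ext);
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return std::max(M0[m], std::max(X0[m], Y0[m]));
}
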