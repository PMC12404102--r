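#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// Greedy farthest point sampling over xyz coordinates only.
// pts: M x 3, start: 1-based index of the first selection.
// Returns k distinct 1-based indices; ties broken by lowest index.
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int k, int start) {
  const int m = pts.nrow();
  if (k < 1 || k > m) stop("k must be in [1, nrow(pts)]");
  if (start < 1 || start > m) stop("invalid start index");
  const double *x = REAL(pts), *y = x + m, *z = y + m;
  IntegerVector out(k);
  std::vector<double> d2(m, R_PosInf);
  std::vector<char> used(m, 0);
  int cur = start - 1;
  out[0] = cur + 1;
  used[cur] = 1;
  for (int i = 1; i < k; ++i) {
    const double cx = x[cur], cy = y[cur], cz = z[cur];
    double best = -1.0;
    int bestIdx = -1;
    for (int j = 0; j < m; ++j) {
      const double dx = x[j] - cx, dy = y[j] - cy, dz = z[j] - cz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < d2[j]) d2[j] = dd;
      if (!used[j] && d2[j] > best) {
        best = d2[j];
        bestIdx = j;
      }
    }
    cur = bestIdx;
    out[i] = cur + 1;
    used[cur] = 1;
  }
  return out;
}

// Ball query: for each center, up to nsample point indices within radius,
// nearest first (ties by index), padded by repeating the nearest index.
// Nearest-first capping makes the selected neighbor set a function of the
// point coordinates alone, which the permutation invariance of the
// eval-mode forward pass requires; index-order capping would make groups
// depend on input order. Falls back to the nearest point if nothing lies
// within the radius. Returns 1-based indices as an nCenter x nsample
// matrix.
// [[Rcpp::export]]
IntegerMatrix ball_query_cpp(NumericMatrix centers, NumericMatrix pts,
                             double radius, int nsample) {
  const int nc = centers.nrow(), m = pts.nrow();
  if (radius <= 0) stop("radius must be > 0");
  if (nsample < 1) stop("nsample must be >= 1");
  const double *x = REAL(pts), *y = x + m, *z = y + m;
  const double *cxv = REAL(centers), *cyv = cxv + nc, *czv = cyv + nc;
  IntegerMatrix out(nc, nsample);
  int *o = INTEGER(out);
  const double r2 = radius * radius;
  std::vector<std::pair<double, int> > inR;
  for (int c = 0; c < nc; ++c) {
    const double cx = cxv[c], cy = cyv[c], cz = czv[c];
    inR.clear();
    int nearest = 0;
    double nearestD = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x[j] - cx, dy = y[j] - cy, dz = z[j] - cz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < nearestD) { nearestD = dd; nearest = j; }
      if (dd <= r2) inR.push_back(std::make_pair(dd, j));
    }
    int cnt = (int)inR.size();
    if (cnt > nsample) {
      std::partial_sort(inR.begin(), inR.begin() + nsample, inR.end());
      cnt = nsample;
    } else {
      std::sort(inR.begin(), inR.end());
    }
    int first;
    if (cnt == 0) { first = nearest; o[c] = nearest + 1; cnt = 1; }
    else {
      first = inR[0].second;
      for (int t = 0; t < cnt; ++t)
        o[c + (std::size_t)nc * t] = inR[t].second + 1;
    }
    for (int t = cnt; t < nsample; ++t)
      o[c + (std::size_t)nc * t] = first + 1;
  }
  return out;
}

// Max distance from any point to its nearest selected point (covering radius).
// sel: 1-based indices into pts.
// [[Rcpp::export]]
double covering_radius_cpp(NumericMatrix pts, IntegerVector sel) {
  const int m = pts.nrow(), k = sel.size();
  const double *x = REAL(pts), *y = x + m, *z = y + m;
  double worst = 0.0;
  for (int j = 0; j < m; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < k; ++i) {
      const int s = sel[i] - 1;
      const double dx = x[j] - x[s], dy = y[j] - y[s], dz = z[j] - z[s];
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}
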