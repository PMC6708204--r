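#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// SLIC / SLIC0 core loop. Coordinates are 1-based (matching R matrices);
// all arithmetic is plain double so a pure-R oracle can reproduce the
// assignments bit-for-bit (same expressions, same strict-< tie rule,
// same center scan order).
//
// centers: matrix with columns (gray, row, col); S = sqrt(N/K_requested).
// When adaptive = true the per-center compactness starts at init_compactness
// for the first iteration and thereafter equals
//   max(comp_floor, running max of |I_i - I_center| observed among members),
// the published zero-parameter (SLIC0) rule.
// [[Rcpp::export]]
List cpp_slic(NumericMatrix img, NumericMatrix centers0, double S,
              double compactness, int iterations, bool adaptive,
              double comp_floor) {
  const int h = img.nrow(), w = img.ncol();
  const int K = centers0.nrow();
  std::vector<double> cg(K), cr(K), cc(K), comp(K), runmax(K, 0.0);
  for (int k = 0; k < K; ++k) {
    cg[k] = centers0(k, 0);
    cr[k] = centers0(k, 1);
    cc[k] = centers0(k, 2);
    comp[k] = compactness;
  }
  IntegerMatrix lab(h, w);
  NumericMatrix dist(h, w);

  for (int it = 0; it < iterations; ++it) {
    std::fill(lab.begin(), lab.end(), -1);
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int lo_r = std::max(1, (int)std::floor(cr[k] - S));
      int hi_r = std::min(h, (int)std::ceil(cr[k] + S));
      int lo_c = std::max(1, (int)std::floor(cc[k] - S));
      int hi_c = std::min(w, (int)std::ceil(cc[k] + S));
      double Ck = comp[k];
      for (int c = lo_c; c <= hi_c; ++c) {
        for (int r = lo_r; r <= hi_r; ++r) {
          double dcol = std::fabs(img(r - 1, c - 1) - cg[k]);
          double dr = r - cr[k], dc2 = c - cc[k];
          double ds = std::sqrt(dr * dr + dc2 * dc2);
          double t = ds / S;
          double D = std::sqrt(dcol * dcol + (t * t) * (Ck * Ck));
          if (D < dist(r - 1, c - 1)) {
            dist(r - 1, c - 1) = D;
            lab(r - 1, c - 1) = k;
          }
        }
      }
    }
    // fallback: pixels outside every search window go to the spatially
    // nearest center (rare; only for degenerate center layouts)
    for (int c = 1; c <= w; ++c)
      for (int r = 1; r <= h; ++r)
        if (lab(r - 1, c - 1) < 0) {
          double best = R_PosInf; int bk = 0;
          for (int k = 0; k < K; ++k) {
            double dr = r - cr[k], dc2 = c - cc[k];
            double ds = dr * dr + dc2 * dc2;
            if (ds < best) { best = ds; bk = k; }
          }
          lab(r - 1, c - 1) = bk;
        }

    if (adaptive) {
      std::vector<double> mx(K, 0.0);
      for (int c = 0; c < w; ++c)
        for (int r = 0; r < h; ++r) {
          int k = lab(r, c);
          double dcol = std::fabs(img(r, c) - cg[k]);
          if (dcol > mx[k]) mx[k] = dcol;
        }
      for (int k = 0; k < K; ++k) {
        if (mx[k] > runmax[k]) runmax[k] = mx[k];
        comp[k] = std::max(comp_floor, runmax[k]);
      }
    }

    // update centers to the mean gray/position of their members;
    // long-double accumulation in column-major order matches R's sum()
    std::vector<long double> sg(K, 0.0L), sr(K, 0.0L), sc(K, 0.0L);
    std::vector<int> n(K, 0);
    for (int c = 1; c <= w; ++c)
      for (int r = 1; r <= h; ++r) {
        int k = lab(r - 1, c - 1);
        sg[k] += img(r - 1, c - 1); sr[k] += r; sc[k] += c; n[k]++;
      }
    for (int k = 0; k < K; ++k)
      if (n[k] > 0) {
        cg[k] = (double)sg[k] / n[k];
        cr[k] = (double)sr[k] / n[k];
        cc[k] = (double)sc[k] / n[k];
      }
  }

  NumericMatrix cen(K, 3);
  for (int k = 0; k < K; ++k) {
    cen(k, 0) = cg[k]; cen(k, 1) = cr[k]; cen(k, 2) = cc[k];
  }
  return List::create(_["labels"] = lab, _["centers"] = cen,
                      _["compactness"] = NumericVector(comp.begin(), comp.end()));
}

// Relabel an arbitrary integer label grid into 4-connected components and
// absorb components smaller than min_size into their largest adjacent
// component. Final labels are 0..count-1 in order of first occurrence
// (column-major, matching R storage).
// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix labels, double min_size) {
  const int h = labels.nrow(), w = labels.ncol(), n = h * w;
  std::vector<int> comp(n, -1);
  std::vector<int> csize;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};

  int ncomp = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (comp[idx] >= 0) continue;
    int lab0 = labels[idx];
    std::queue<int> q;
    q.push(idx); comp[idx] = ncomp;
    int sz = 0;
    while (!q.empty()) {
      int p = q.front(); q.pop(); sz++;
      int r = p % h, c = p / h;
      for (int d = 0; d < 4; ++d) {
        int rr = r + dr[d], cc2 = c + dc[d];
        if (rr < 0 || rr >= h || cc2 < 0 || cc2 >= w) continue;
        int p2 = cc2 * h + rr;
        if (comp[p2] < 0 && labels[p2] == lab0) { comp[p2] = ncomp; q.push(p2); }
      }
    }
    csize.push_back(sz);
    ncomp++;
  }

  // union-find over components
  std::vector<int> parent(ncomp);
  std::vector<double> usize(csize.begin(), csize.end());
  for (int i = 0; i < ncomp; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  // component pixel lists (for adjacency scans), visit smallest first
  std::vector<std::vector<int>> pixels(ncomp);
  for (int idx = 0; idx < n; ++idx) pixels[comp[idx]].push_back(idx);
  std::vector<int> order(ncomp);
  for (int i = 0; i < ncomp; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return csize[a] < csize[b]; });

  for (int oi = 0; oi < ncomp; ++oi) {
    int ci = order[oi];
    int root = find(ci);
    if (usize[root] >= min_size) continue;
    // largest adjacent root (ties: smallest root id)
    int best = -1; double bestsz = -1.0;
    for (int p : pixels[ci]) {
      int r = p % h, c = p / h;
      for (int d = 0; d < 4; ++d) {
        int rr = r + dr[d], cc2 = c + dc[d];
        if (rr < 0 || rr >= h || cc2 < 0 || cc2 >= w) continue;
        int r2 = find(comp[cc2 * h + rr]);
        if (r2 == root) continue;
        if (usize[r2] > bestsz || (usize[r2] == bestsz && r2 < best)) {
          bestsz = usize[r2]; best = r2;
        }
      }
    }
    if (best >= 0) {
      parent[root] = best;
      usize[best] += usize[root];
    }
  }

  IntegerMatrix out(h, w);
  std::vector<int> newid(ncomp, -1);
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    int r = find(comp[idx]);
    if (newid[r] < 0) newid[r] = next++;
    out[idx] = newid[r];
  }
  return out;
}

// The 13 classic Haralick texture features from a normalized co-occurrence
// matrix. Entropies are in bits (log2); log arguments are guarded with
// eps = 1e-12 so every feature is finite. An all-zero matrix yields zeros.
// Sum variance is computed about the sum average.
// [[Rcpp::export]]
NumericVector cpp_haralick(NumericMatrix P) {
  const int L = P.nrow();
  const double eps = 1e-12;
  NumericVector f(13);
  double tot = 0.0;
  for (int i = 0; i < L * L; ++i) tot += P[i];
  if (tot <= 0.0) return f;

  std::vector<double> px(L, 0.0), py(L, 0.0), psum(2 * L - 1, 0.0), pdiff(L, 0.0);
  double asm_ = 0.0, contrast = 0.0, idm = 0.0, ent = 0.0, sij = 0.0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      double p = P(i, j);
      px[i] += p; py[j] += p;
      psum[i + j] += p; pdiff[std::abs(i - j)] += p;
      asm_ += p * p;
      contrast += (double)(i - j) * (i - j) * p;
      idm += p / (1.0 + (double)(i - j) * (i - j));
      ent -= p * std::log2(p + eps);
      sij += (double)i * j * p;
    }
  double mux = 0.0, muy = 0.0;
  for (int i = 0; i < L; ++i) { mux += i * px[i]; muy += i * py[i]; }
  double sx2 = 0.0, sy2 = 0.0;
  for (int i = 0; i < L; ++i) {
    sx2 += (i - mux) * (i - mux) * px[i];
    sy2 += (i - muy) * (i - muy) * py[i];
  }
  double corr = 0.0;
  double sxsy = std::sqrt(sx2) * std::sqrt(sy2);
  if (sxsy > eps) corr = (sij - mux * muy) / sxsy;

  double var = 0.0;  // sum of squares about the marginal mean
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) var += (i - mux) * (i - mux) * P(i, j);

  double sa = 0.0, se = 0.0;
  for (int k = 0; k < 2 * L - 1; ++k) {
    sa += k * psum[k];
    se -= psum[k] * std::log2(psum[k] + eps);
  }
  double sv = 0.0;
  for (int k = 0; k < 2 * L - 1; ++k) sv += (k - sa) * (k - sa) * psum[k];

  double mud = 0.0, de = 0.0;
  for (int k = 0; k < L; ++k) {
    mud += k * pdiff[k];
    de -= pdiff[k] * std::log2(pdiff[k] + eps);
  }
  double dv = 0.0;
  for (int k = 0; k < L; ++k) dv += (k - mud) * (k - mud) * pdiff[k];

  double hx = 0.0, hy = 0.0, hxy1 = 0.0, hxy2 = 0.0;
  for (int i = 0; i < L; ++i) {
    hx -= px[i] * std::log2(px[i] + eps);
    hy -= py[i] * std::log2(py[i] + eps);
  }
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      double pp = px[i] * py[j];
      hxy1 -= P(i, j) * std::log2(pp + eps);
      hxy2 -= pp * std::log2(pp + eps);
    }
  double imc1 = 0.0;
  if (std::max(hx, hy) > eps) imc1 = (ent - hxy1) / std::max(hx, hy);
  // IMC2 uses natural-log entropies; convert from bits
  double imc2arg = 1.0 - std::exp(-2.0 * M_LN2 * (hxy2 - ent));
  double imc2 = imc2arg > 0.0 ? std::sqrt(imc2arg) : 0.0;

  f[0] = asm_; f[1] = contrast; f[2] = corr; f[3] = var; f[4] = idm;
  f[5] = sa; f[6] = sv; f[7] = se; f[8] = ent; f[9] = dv; f[10] = de;
  f[11] = imc1; f[12] = imc2;
  f.attr("names") = CharacterVector::create(
    "asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "difference_variance",
    "difference_entropy", "imc1", "imc2");
  return f;
}
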