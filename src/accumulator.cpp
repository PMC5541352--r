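// Voxelized four-chart covering of orientation space with geodesic ray
// tracing, plus the matching kernel used during orientation refinement.
//
// Chart construction: a rotation with unit quaternion q lives in chart k,
// k = argmax_i |q_i| (lowest index on ties), with local coordinates the
// remaining three components divided by q_k.  The chart domain is then
// exactly the cube [-1,1]^3, and the dominance regions tile the quaternion
// sphere, so the four cubes jointly cover orientation space once (up to
// shared faces).  A geodesic -- the set of rotations mapping one unit vector
// onto another -- is a great circle of S3, i.e. a 2-plane through the origin
// of R^4; its central projection into any chart hyperplane {q_k = 1} is a
// straight line.  Tracing therefore reduces to clipping one line per chart
// to the cube and walking the voxel grid with an exact DDA
// (Amanatides & Woo): no point sampling, deterministic visit sets, and each
// voxel incremented at most once per geodesic because a convex clip yields a
// single segment per chart.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

struct Accum {
  int nv;
  std::vector<uint16_t> c;   // 4 * nv^3 counters, x fastest then y, z, chart
  uint64_t total;            // sum of all counters (pre-saturation)
  Accum(int nv_) : nv(nv_), c((size_t)4 * nv_ * nv_ * nv_, 0), total(0) {}
  inline size_t idx(int chart, int ix, int iy, int iz) const {
    return (((size_t)chart * nv + iz) * nv + iy) * nv + ix;
  }
  inline void hit(size_t i) {
    if (c[i] < std::numeric_limits<uint16_t>::max()) c[i]++;
    total++;
  }
};

typedef XPtr<Accum> AccPtr;

// [[Rcpp::export]]
SEXP acc_create(int nv) {
  if (nv < 1) stop("voxels per axis must be >= 1");
  Accum* a = new Accum(nv);
  return AccPtr(a, true);
}

// [[Rcpp::export]]
int acc_nv(SEXP p) { return AccPtr(p)->nv; }

// [[Rcpp::export]]
void acc_reset(SEXP p) {
  AccPtr a(p);
  std::fill(a->c.begin(), a->c.end(), 0);
  a->total = 0;
}

// [[Rcpp::export]]
double acc_total(SEXP p) { return (double)AccPtr(p)->total; }

// [[Rcpp::export]]
double acc_max(SEXP p) {
  AccPtr a(p);
  uint16_t m = 0;
  for (uint16_t v : a->c) if (v > m) m = v;
  return (double)m;
}

// Full counter dump of one chart (guarded for small grids; test use only).
// [[Rcpp::export]]
IntegerVector acc_counts(SEXP p, int chart) {
  AccPtr a(p);
  if (chart < 0 || chart > 3) stop("chart must be in 0..3");
  if (a->nv > 64) stop("full counter dump is only supported for nv <= 64");
  size_t n = (size_t)a->nv * a->nv * a->nv;
  IntegerVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = a->c[(size_t)chart * n + i];
  return out;
}

// Counters at given addresses (chart 0-based, ijk 1-based).
// [[Rcpp::export]]
IntegerVector acc_count_at(SEXP p, IntegerVector chart, IntegerVector i,
                           IntegerVector j, IntegerVector k) {
  AccPtr a(p);
  int n = chart.size();
  IntegerVector out(n);
  for (int t = 0; t < n; t++) {
    if (chart[t] < 0 || chart[t] > 3 || i[t] < 1 || i[t] > a->nv ||
        j[t] < 1 || j[t] > a->nv || k[t] < 1 || k[t] > a->nv)
      stop("voxel address out of range");
    out[t] = a->c[a->idx(chart[t], i[t] - 1, j[t] - 1, k[t] - 1)];
  }
  return out;
}

// Set a counter directly (diagnostics / tests of the maxima criterion).
// [[Rcpp::export]]
void acc_poke(SEXP p, int chart, int i, int j, int k, int value) {
  AccPtr a(p);
  if (chart < 0 || chart > 3 || i < 1 || i > a->nv || j < 1 || j > a->nv ||
      k < 1 || k > a->nv || value < 0 || value > 65535)
    stop("invalid poke");
  size_t id = a->idx(chart, i - 1, j - 1, k - 1);
  a->total += (uint64_t)value - a->c[id];
  a->c[id] = (uint16_t)value;
}

// --- geometry helpers -------------------------------------------------------

// Clip line P + t*D to the cube [-1,1]^3 (Liang-Barsky).  Returns false if
// the line misses the cube.
static bool clip_cube(const double P[3], const double D[3],
                      double& t0, double& t1) {
  t0 = -std::numeric_limits<double>::infinity();
  t1 =  std::numeric_limits<double>::infinity();
  for (int aix = 0; aix < 3; aix++) {
    if (std::fabs(D[aix]) < 1e-300) {
      if (P[aix] < -1.0 || P[aix] > 1.0) return false;
    } else {
      double ta = (-1.0 - P[aix]) / D[aix];
      double tb = ( 1.0 - P[aix]) / D[aix];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return t0 <= t1;
}

struct Visit { int chart, ix, iy, iz; };

// Walk the voxel grid along segment [t0,t1] of P + t*D in one chart.
// Collects linear voxel indices into `buf` (counters are incremented by the
// caller in a prefetched pass); optionally records visited voxel addresses.
static int dda_chart(Accum& A, int chart, const double P[3], const double D[3],
                     double t0, double t1, std::vector<uint32_t>& buf,
                     std::vector<Visit>* rec) {
  const int nv = A.nv;
  const double h = 2.0 / nv;
  // entry point, nudged inward to stabilise the starting voxel
  double eps = (t1 - t0) * 1e-12 + 1e-300;
  double x0[3];
  int ix[3], stepd[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; a++) {
    x0[a] = P[a] + (t0 + eps) * D[a];
    int v = (int)std::floor((x0[a] + 1.0) / h);
    if (v < 0) v = 0;
    if (v > nv - 1) v = nv - 1;
    ix[a] = v;
    if (D[a] > 0) {
      stepd[a] = 1;
      tMax[a] = t0 + (((v + 1) * h - 1.0) - (P[a] + t0 * D[a])) / D[a];
      tDelta[a] = h / D[a];
    } else if (D[a] < 0) {
      stepd[a] = -1;
      tMax[a] = t0 + ((v * h - 1.0) - (P[a] + t0 * D[a])) / D[a];
      tDelta[a] = -h / D[a];
    } else {
      stepd[a] = 0;
      tMax[a] = std::numeric_limits<double>::infinity();
      tDelta[a] = std::numeric_limits<double>::infinity();
    }
  }
  int count = 0;
  while (true) {
    buf.push_back((uint32_t)A.idx(chart, ix[0], ix[1], ix[2]));
    if (rec) rec->push_back({chart, ix[0], ix[1], ix[2]});
    count++;
    int m = 0;
    if (tMax[1] < tMax[m]) m = 1;
    if (tMax[2] < tMax[m]) m = 2;
    if (tMax[m] > t1) break;
    ix[m] += stepd[m];
    if (ix[m] < 0 || ix[m] > nv - 1) break;
    tMax[m] += tDelta[m];
  }
  return count;
}

// Apply buffered visits with software prefetch: the accumulator is much
// larger than cache, so the increments are DRAM-latency bound unless
// upcoming addresses are prefetched ahead of use.
static void flush_visits(Accum& A, std::vector<uint32_t>& buf) {
  const size_t n = buf.size();
  const size_t PF = 24;
  for (size_t i = 0; i < n; i++) {
    if (i + PF < n) __builtin_prefetch(&A.c[buf[i + PF]], 1, 0);
    A.hit(buf[i]);
  }
  buf.clear();
}

// Trace the great circle spanned by orthogonal unit quaternions qa, qb
// through all four charts.  Returns total voxels visited.
static int trace_circle(Accum& A, const double* qa, const double* qb,
                        std::vector<uint32_t>& buf, std::vector<Visit>* rec) {
  int count = 0;
  for (int k = 0; k < 3 + 1; k++) {
    double ak = qa[k], bk = qb[k];
    if (std::fabs(ak) < 1e-14 && std::fabs(bk) < 1e-14) continue;  // circle in q_k = 0
    // line = (plane spanned by qa,qb) intersect {q_k = 1}
    double pt4[4], dir4[4];
    if (std::fabs(ak) >= std::fabs(bk))
      for (int i = 0; i < 4; i++) pt4[i] = qa[i] / ak;
    else
      for (int i = 0; i < 4; i++) pt4[i] = qb[i] / bk;
    for (int i = 0; i < 4; i++) dir4[i] = bk * qa[i] - ak * qb[i];
    double P[3], D[3];
    int j = 0;
    for (int i = 0; i < 4; i++) {
      if (i == k) continue;
      P[j] = pt4[i];
      D[j] = dir4[i];
      j++;
    }
    double dn = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
    if (dn < 1e-14) continue;
    for (int i = 0; i < 3; i++) D[i] /= dn;
    double t0, t1;
    if (!clip_cube(P, D, t0, t1)) continue;
    count += dda_chart(A, k, P, D, t0, t1, buf, rec);
  }
  flush_visits(A, buf);
  return count;
}

// [[Rcpp::export]]
List acc_trace(SEXP p, NumericVector qa, NumericVector qb, bool collect) {
  AccPtr a(p);
  if (qa.size() != 4 || qb.size() != 4) stop("quaternions must have length 4");
  std::vector<Visit> rec;
  std::vector<uint32_t> buf;
  buf.reserve(4096);
  int n = trace_circle(*a, REAL(qa), REAL(qb), buf, collect ? &rec : nullptr);
  List out = List::create(_["count"] = n);
  if (collect) {
    int m = rec.size();
    IntegerVector ch(m), vi(m), vj(m), vk(m);
    for (int t = 0; t < m; t++) {
      ch[t] = rec[t].chart;
      vi[t] = rec[t].ix + 1;
      vj[t] = rec[t].iy + 1;
      vk[t] = rec[t].iz + 1;
    }
    out["chart"] = ch; out["i"] = vi; out["j"] = vj; out["k"] = vk;
  }
  return out;
}

// Build and trace one geodesic per (g, h) combination.  G and H hold unit
// direction vectors; gi/hi are 0-based row indices.  The minimal rotation
// taking h onto g has axis h x g; the maximal is the half-turn about h + g;
// together they span the great circle of all solutions.  Antipodal pairs
// (g = -h) have no finite Rodrigues anchor and are skipped (visits = -1).
// [[Rcpp::export]]
IntegerVector acc_trace_pairs(SEXP p, NumericMatrix G, NumericMatrix H,
                              IntegerVector gi, IntegerVector hi) {
  AccPtr a(p);
  int n = gi.size();
  if (hi.size() != n) stop("gi and hi must have equal length");
  IntegerVector visits(n);
  std::vector<uint32_t> buf;
  buf.reserve(8192);
  for (int t = 0; t < n; t++) {
    double gd[3], hd[3];
    double gn = 0, hn = 0;
    for (int i = 0; i < 3; i++) {
      gd[i] = G(gi[t], i); gn += gd[i] * gd[i];
      hd[i] = H(hi[t], i); hn += hd[i] * hd[i];
    }
    gn = std::sqrt(gn); hn = std::sqrt(hn);
    if (gn < 1e-300 || hn < 1e-300) { visits[t] = -1; continue; }
    for (int i = 0; i < 3; i++) { gd[i] /= gn; hd[i] /= hn; }
    double s[3] = {hd[0] + gd[0], hd[1] + gd[1], hd[2] + gd[2]};
    double sn = std::sqrt(s[0] * s[0] + s[1] * s[1] + s[2] * s[2]);
    if (sn < 1e-9) { visits[t] = -1; continue; }  // antipodal: degenerate
    double qb[4] = {0.0, s[0] / sn, s[1] / sn, s[2] / sn};
    double cr[3] = {hd[1] * gd[2] - hd[2] * gd[1],
                    hd[2] * gd[0] - hd[0] * gd[2],
                    hd[0] * gd[1] - hd[1] * gd[0]};
    double crn = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
    double dotp = hd[0] * gd[0] + hd[1] * gd[1] + hd[2] * gd[2];
    double qa[4];
    if (crn < 1e-14) {           // collinear: identity is the minimal rotation
      qa[0] = 1.0; qa[1] = qa[2] = qa[3] = 0.0;
    } else {
      double ang = std::atan2(crn, dotp);
      double c2 = std::cos(ang / 2), s2 = std::sin(ang / 2);
      qa[0] = c2;
      for (int i = 0; i < 3; i++) qa[i + 1] = s2 * cr[i] / crn;
    }
    visits[t] = trace_circle(*a, qa, qb, buf, nullptr);
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return visits;
}

// Local maxima: counters that are >= all (up to 26) in-chart neighbours and
// satisfy V >= vmin and V >= fv * Vmax (global max over all charts).
// Sorted by visits descending, ties by (chart, linear index) ascending.
// [[Rcpp::export]]
DataFrame acc_local_maxima(SEXP p, double vmin, double fv) {
  AccPtr a(p);
  const int nv = a->nv;
  uint16_t vmax = 0;
  for (uint16_t v : a->c) if (v > vmax) vmax = v;
  double thr = std::max(vmin, fv * (double)vmax);
  if (thr < 1) thr = 1;
  struct Peak { int chart, ix, iy, iz, v; size_t lin; };
  std::vector<Peak> peaks;
  const size_t n3 = (size_t)nv * nv * nv;
  for (int chart = 0; chart < 4; chart++) {
    const uint16_t* base = a->c.data() + (size_t)chart * n3;
    for (int iz = 0; iz < nv; iz++)
      for (int iy = 0; iy < nv; iy++)
        for (int ix = 0; ix < nv; ix++) {
          size_t lin = ((size_t)iz * nv + iy) * nv + ix;
          uint16_t v = base[lin];
          if ((double)v < thr) continue;
          bool ismax = true;
          for (int dz = -1; dz <= 1 && ismax; dz++)
            for (int dy = -1; dy <= 1 && ismax; dy++)
              for (int dx = -1; dx <= 1 && ismax; dx++) {
                if (!dx && !dy && !dz) continue;
                int jx = ix + dx, jy = iy + dy, jz = iz + dz;
                if (jx < 0 || jx >= nv || jy < 0 || jy >= nv ||
                    jz < 0 || jz >= nv) continue;
                if (base[((size_t)jz * nv + jy) * nv + jx] > v) ismax = false;
              }
          if (ismax) peaks.push_back({chart, ix, iy, iz, (int)v, lin});
        }
  }
  std::sort(peaks.begin(), peaks.end(), [](const Peak& x, const Peak& y) {
    if (x.v != y.v) return x.v > y.v;
    if (x.chart != y.chart) return x.chart < y.chart;
    return x.lin < y.lin;
  });
  int m = peaks.size();
  IntegerVector ch(m), vi(m), vj(m), vk(m), vv(m);
  for (int t = 0; t < m; t++) {
    ch[t] = peaks[t].chart;
    vi[t] = peaks[t].ix + 1;
    vj[t] = peaks[t].iy + 1;
    vk[t] = peaks[t].iz + 1;
    vv[t] = peaks[t].v;
  }
  return DataFrame::create(_["chart"] = ch, _["i"] = vi, _["j"] = vj,
                           _["k"] = vk, _["visits"] = vv);
}

// --- matching kernel --------------------------------------------------------

// Greedy unique assignment of observed g vectors to predicted reciprocal
// points q = U.h over a precomputed candidate (g, h) combination list.
// RH holds the rotated candidate vectors U.h (one row per unique h), G the
// observed g vectors.  A combination is admissible iff
//   (a) the residual rotation about the lab axis `axis` bringing q onto g is
//       at most domega (pre-selection), and
//   (b) the angle between unit(q) and unit(g) is at most tol.
// Admissible combinations are assigned greedily by smallest angular
// deviation; each g and each h row is used at most once.
// [[Rcpp::export]]
List match_combos(NumericMatrix RH, NumericMatrix G, IntegerVector gi,
                  IntegerVector hi, double tol, double domega, int axis) {
  int nc = gi.size();
  int ng = G.nrow(), nh = RH.nrow();
  if (axis < 0 || axis > 2) stop("axis must be 0 (x), 1 (y) or 2 (z)");
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  // per-row precomputation (the combination list is far longer than either
  // input table, so azimuths and norms are cached per row)
  std::vector<double> wg(ng), gnv(ng), wq(nh), qnv(nh);
  for (int g = 0; g < ng; g++) {
    double x = G(g, 0), y = G(g, 1), z = G(g, 2);
    double v[3] = {x, y, z};
    wg[g] = std::atan2(v[a2], v[a1]);
    gnv[g] = std::sqrt(x * x + y * y + z * z);
  }
  for (int h = 0; h < nh; h++) {
    double x = RH(h, 0), y = RH(h, 1), z = RH(h, 2);
    double v[3] = {x, y, z};
    wq[h] = std::atan2(v[a2], v[a1]);
    qnv[h] = std::sqrt(x * x + y * y + z * z);
  }
  double cos_tol = std::cos(tol);
  struct Cand { double dev; int c; };
  std::vector<Cand> ok;
  ok.reserve(1024);
  for (int t = 0; t < nc; t++) {
    int g = gi[t], h = hi[t];
    // (a) equivalent rotation about the reference axis
    double dw = std::fabs(wq[h] - wg[g]);
    if (dw > M_PI) dw = 2 * M_PI - dw;
    if (dw > domega) continue;
    // (b) angular deviation between the unit vectors
    if (qnv[h] < 1e-300 || gnv[g] < 1e-300) continue;
    double cosv = (RH(h, 0) * G(g, 0) + RH(h, 1) * G(g, 1) +
                   RH(h, 2) * G(g, 2)) / (qnv[h] * gnv[g]);
    if (cosv < cos_tol) continue;
    if (cosv > 1) cosv = 1;
    double ang = std::acos(cosv);
    ok.push_back({ang, t});
  }
  std::sort(ok.begin(), ok.end(), [&](const Cand& x, const Cand& y) {
    if (x.dev != y.dev) return x.dev < y.dev;
    return x.c < y.c;  // deterministic tie-break by combination order
  });
  std::vector<char> gtaken(ng, 0), htaken(nh, 0);
  IntegerVector assign_h(ng, -1), assign_combo(ng, -1);
  NumericVector dev(ng, NA_REAL);
  for (const Cand& cd : ok) {
    int g = gi[cd.c], h = hi[cd.c];
    if (gtaken[g] || htaken[h]) continue;
    gtaken[g] = 1; htaken[h] = 1;
    assign_h[g] = h;
    assign_combo[g] = cd.c;
    dev[g] = cd.dev;
  }
  return List::create(_["h_index"] = assign_h, _["combo"] = assign_combo,
                      _["deviation"] = dev);
}
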