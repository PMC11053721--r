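#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5: region classification via barycentric signs.
static inline void closest_on_triangle(const double *p,
                                       const double *a, const double *b,
                                       const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix closest(np, 3);

  // Per-triangle bounding boxes for a quick lower-bound reject.
  std::vector<double> blo(3 * nf), bhi(3 * nf), tri(9 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int i = 0; i < 3; ++i) tri[9 * f + 3 * k + i] = V(vi, i);
    }
    for (int i = 0; i < 3; ++i) {
      double lo = tri[9 * f + i], hi = lo;
      for (int k = 1; k < 3; ++k) {
        double v = tri[9 * f + 3 * k + i];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      blo[3 * f + i] = lo;
      bhi[3 * f + i] = hi;
    }
  }

  int prev_best = 0;
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    double best = DBL_MAX, cbest[3] = {0, 0, 0};
    int fbest = -1;
    // Seed with the previous point's winning face: query points are spatially
    // coherent (sampled region by region), which tightens the reject bound.
    for (int pass = 0; pass < 2; ++pass) {
      int f0 = (pass == 0) ? prev_best : 0;
      int f1 = (pass == 0) ? prev_best + 1 : nf;
      for (int f = f0; f < f1; ++f) {
        double d2lo = 0.0;
        for (int i = 0; i < 3; ++i) {
          double d = 0.0;
          if (p[i] < blo[3 * f + i]) d = blo[3 * f + i] - p[i];
          else if (p[i] > bhi[3 * f + i]) d = p[i] - bhi[3 * f + i];
          d2lo += d * d;
        }
        if (d2lo >= best) continue;
        double q[3];
        closest_on_triangle(p, &tri[9 * f], &tri[9 * f + 3], &tri[9 * f + 6], q);
        double d2 = 0.0;
        for (int i = 0; i < 3; ++i) {
          double d = p[i] - q[i];
          d2 += d * d;
        }
        if (d2 < best) {
          best = d2;
          fbest = f;
          for (int i = 0; i < 3; ++i) cbest[i] = q[i];
        }
      }
    }
    prev_best = fbest;
    dist[ip] = std::sqrt(best);
    face[ip] = fbest + 1;
    for (int i = 0; i < 3; ++i) closest(ip, i) = cbest[i];
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["closest"] = closest);
}
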