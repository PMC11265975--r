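#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, 5.1.5). Writes the barycentric coordinates of the closest
// point into bary.
static inline double closest_pt_triangle(const double *p, const double *a,
                                         const double *b, const double *c,
                                         double *bary) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u = 0, v = 0;  // bary of b and c
  bool done = false;
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0; v = 0; done = true; }
  if (!done) {
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) { u = 1; v = 0; done = true; }
    if (!done) {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        u = (d1 - d3 != 0) ? d1 / (d1 - d3) : 0.0;
        v = 0;
        done = true;
      }
    }
    if (!done) {
      for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
      const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
      const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
      if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 1; done = true; }
      if (!done) {
        const double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          u = 0;
          v = (d2 - d6 != 0) ? d2 / (d2 - d6) : 0.0;
          done = true;
        }
      }
      if (!done) {
        const double d43 = d4 - d3, d56 = d5 - d6;
        const double va = d3 * d6 - d5 * d4;
        if (va <= 0.0 && d43 >= 0.0 && d56 >= 0.0) {
          const double w = (d43 + d56 != 0) ? d43 / (d43 + d56) : 0.0;
          u = 1 - w;
          v = w;
          done = true;
        }
      }
      if (!done) {
        const double vc = d1 * d4 - d3 * d2;
        const double vb = d5 * d2 - d1 * d6;
        const double va = d3 * d6 - d5 * d4;
        const double denom = va + vb + vc;
        if (denom != 0) {
          u = vb / denom;
          v = vc / denom;
        } else {
          u = 0;
          v = 0;
        }
      }
    }
  }
  bary[0] = 1 - u - v;
  bary[1] = u;
  bary[2] = v;
  double q[3], diff, d2sum = 0;
  for (int i = 0; i < 3; ++i) {
    q[i] = a[i] + ab[i] * u + ac[i] * v;
    diff = p[i] - q[i];
    d2sum += diff * diff;
  }
  return d2sum;
}

// Closest point on a triangle mesh surface for each query point.
// vf_ptr / vf_idx give the vertex->incident-face adjacency in CSR form
// (1-based, vf_ptr length n+1). The search scans vertices once for the
// nearest vertex, then tests only faces incident to vertices within
// (nearest vertex distance + max edge length), which must contain the
// closest surface point.
// [[Rcpp::export(name = ".closest_surface")]]
List closest_surface(NumericMatrix query, NumericMatrix verts,
                     IntegerMatrix faces, IntegerVector vf_ptr,
                     IntegerVector vf_idx) {
  const int nq = query.nrow(), nv = verts.nrow(), nf = faces.nrow();
  if (nv == 0 || nf == 0) stop("empty target mesh");
  const double *qx = query.begin(), *qy = qx + nq, *qz = qy + nq;
  const double *vx = verts.begin(), *vy = vx + nv, *vz = vy + nv;
  const int *f1 = faces.begin(), *f2 = f1 + nf, *f3 = f2 + nf;

  // longest edge of the current mesh
  double max_e2 = 0;
  for (int t = 0; t < nf; ++t) {
    const int a = f1[t] - 1, b = f2[t] - 1, c = f3[t] - 1;
    double dx, dy, dz, e2;
    dx = vx[a] - vx[b]; dy = vy[a] - vy[b]; dz = vz[a] - vz[b];
    e2 = dx * dx + dy * dy + dz * dz; if (e2 > max_e2) max_e2 = e2;
    dx = vx[b] - vx[c]; dy = vy[b] - vy[c]; dz = vz[b] - vz[c];
    e2 = dx * dx + dy * dy + dz * dz; if (e2 > max_e2) max_e2 = e2;
    dx = vx[c] - vx[a]; dy = vy[c] - vy[a]; dz = vz[c] - vz[a];
    e2 = dx * dx + dy * dy + dz * dz; if (e2 > max_e2) max_e2 = e2;
  }
  const double max_e = std::sqrt(max_e2);

  IntegerVector face_out(nq);
  NumericVector dist(nq);
  NumericMatrix bary(nq, 3);
  std::vector<int> stamp(nf, -1);
  double pt[3], tri_a[3], tri_b[3], tri_c[3], bc[3];
  for (int i = 0; i < nq; ++i) {
    pt[0] = qx[i]; pt[1] = qy[i]; pt[2] = qz[i];
    double dnn = R_PosInf;
    for (int j = 0; j < nv; ++j) {
      const double dx = pt[0] - vx[j];
      const double dy = pt[1] - vy[j];
      const double dz = pt[2] - vz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dnn) dnn = d2;
    }
    const double radius = std::sqrt(dnn) + max_e;
    const double rad2 = radius * radius;
    double best = R_PosInf;
    int best_face = 0;
    double best_bc[3] = {1, 0, 0};
    for (int j = 0; j < nv; ++j) {
      const double dx = pt[0] - vx[j];
      const double dy = pt[1] - vy[j];
      const double dz = pt[2] - vz[j];
      if (dx * dx + dy * dy + dz * dz > rad2) continue;
      for (int kk = vf_ptr[j] - 1; kk < vf_ptr[j + 1] - 1; ++kk) {
        const int t = vf_idx[kk] - 1;
        if (stamp[t] == i) continue;
        stamp[t] = i;
        const int a = f1[t] - 1, b = f2[t] - 1, c = f3[t] - 1;
        tri_a[0] = vx[a]; tri_a[1] = vy[a]; tri_a[2] = vz[a];
        tri_b[0] = vx[b]; tri_b[1] = vy[b]; tri_b[2] = vz[b];
        tri_c[0] = vx[c]; tri_c[1] = vy[c]; tri_c[2] = vz[c];
        const double d2 = closest_pt_triangle(pt, tri_a, tri_b, tri_c, bc);
        if (d2 < best || (d2 == best && t < best_face)) {
          best = d2;
          best_face = t;
          best_bc[0] = bc[0]; best_bc[1] = bc[1]; best_bc[2] = bc[2];
        }
      }
    }
    face_out[i] = best_face + 1;
    dist[i] = std::sqrt(best);
    bary(i, 0) = best_bc[0];
    bary(i, 1) = best_bc[1];
    bary(i, 2) = best_bc[2];
  }
  return List::create(_["face"] = face_out, _["bary"] = bary,
                      _["distance"] = dist);
}
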