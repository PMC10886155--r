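// Compact kernels for the hex8 finite-element engine and geometric queries:
// B-bar stiffness assembly, stress/strain recovery, Jacobian checks,
// nearest-neighbour search and closest-point-on-facet projection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double GP = 0.5773502691896257645091488;

// natural coordinates of the 8 nodes
static const double XI[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
static const double ET[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
static const double ZE[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

// shape-function derivatives w.r.t. natural coords at (xi, eta, zeta)
static void dshape(double xi, double eta, double zeta, arma::mat &G) {
  for (int i = 0; i < 8; ++i) {
    G(0, i) = 0.125 * XI[i] * (1 + eta * ET[i]) * (1 + zeta * ZE[i]);
    G(1, i) = 0.125 * ET[i] * (1 + xi * XI[i]) * (1 + zeta * ZE[i]);
    G(2, i) = 0.125 * ZE[i] * (1 + xi * XI[i]) * (1 + eta * ET[i]);
  }
}

static void material_matrix(double E, double nu, arma::mat &D) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  D.zeros(6, 6);
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) D(a, b) = lam;
    D(a, a) = lam + 2 * mu;
    D(a + 3, a + 3) = mu;
  }
}

// build the B-bar matrix from dNdx (3x8) and the element-average gbar (3x8)
static void bbar_matrix(const arma::mat &g, const arma::mat &gbar, arma::mat &B) {
  B.zeros(6, 24);
  for (int i = 0; i < 8; ++i) {
    double gx = g(0, i), gy = g(1, i), gz = g(2, i);
    double cx = (gbar(0, i) - gx) / 3.0;
    double cy = (gbar(1, i) - gy) / 3.0;
    double cz = (gbar(2, i) - gz) / 3.0;
    int c = 3 * i;
    // volumetric-corrected normal rows
    B(0, c) = gx + cx; B(0, c + 1) = cy;      B(0, c + 2) = cz;
    B(1, c) = cx;      B(1, c + 1) = gy + cy; B(1, c + 2) = cz;
    B(2, c) = cx;      B(2, c + 1) = cy;      B(2, c + 2) = gz + cz;
    // engineering shear rows
    B(3, c) = gy; B(3, c + 1) = gx;
    B(4, c + 1) = gz; B(4, c + 2) = gy;
    B(5, c) = gz; B(5, c + 2) = gx;
  }
}

// per-element quadrature data: dNdx and detJ at the 8 Gauss points + gbar
static bool element_quadrature(const arma::mat &X, arma::cube &dndx,
                               arma::vec &detj, arma::mat &gbar) {
  arma::mat G(3, 8), J(3, 3);
  gbar.zeros(3, 8);
  double vol = 0.0;
  int q = 0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c, ++q) {
        double xi = (a ? GP : -GP), eta = (b ? GP : -GP), zeta = (c ? GP : -GP);
        dshape(xi, eta, zeta, G);
        J = G * X;
        double dj = arma::det(J);
        detj(q) = dj;
        if (dj <= 0) return false;
        arma::mat gq = arma::solve(J, G);
        dndx.slice(q) = gq;
        gbar += gq * dj;
        vol += dj;
      }
  gbar /= vol;
  return true;
}

// Assemble B-bar material stiffness, optionally augmented with the
// geometric (initial-stress) stiffness from an element stress state
// sig0 (ne x 6 Voigt), which supplies membrane stress-stiffening.
// [[Rcpp::export]]
List hex8_assemble(const arma::mat &nodes, const arma::imat &elems,
                   const arma::vec &Evec, const arma::vec &nuvec,
                   Rcpp::Nullable<Rcpp::NumericMatrix> sig0 = R_NilValue) {
  int ne = elems.n_rows;
  arma::mat S0;
  bool has_sig = sig0.isNotNull();
  if (has_sig) S0 = Rcpp::as<arma::mat>(sig0);
  NumericVector ii(576 * (R_xlen_t)ne), jj(576 * (R_xlen_t)ne),
      vv(576 * (R_xlen_t)ne);
  arma::vec vols(ne);
  arma::mat X(8, 3), D(6, 6), B(6, 24), Ke(24, 24), gbar(3, 8);
  arma::cube dndx(3, 8, 8);
  arma::vec detj(8);
  size_t p = 0;
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 8; ++i) X.row(i) = nodes.row(elems(e, i) - 1);
    if (!element_quadrature(X, dndx, detj, gbar))
      stop("non-positive Jacobian in element %d", e + 1);
    material_matrix(Evec(e), nuvec(e), D);
    Ke.zeros();
    arma::mat DB(6, 24);
    arma::mat33 sig;
    if (has_sig) {
      sig = {{S0(e, 0), S0(e, 3), S0(e, 5)},
             {S0(e, 3), S0(e, 1), S0(e, 4)},
             {S0(e, 5), S0(e, 4), S0(e, 2)}};
    }
    for (int q = 0; q < 8; ++q) {
      bbar_matrix(dndx.slice(q), gbar, B);
      DB = D * B;
      DB *= detj(q);
      Ke += B.t() * DB;
      if (has_sig) {
        // K_sigma(ai, bj) = delta_ij * g_a' sigma g_b
        const arma::mat &g = dndx.slice(q);
        arma::mat gs = g.t() * sig * g; // 8 x 8
        for (int a_ = 0; a_ < 8; ++a_)
          for (int b_ = 0; b_ < 8; ++b_) {
            double v = gs(a_, b_) * detj(q);
            Ke(3 * a_, 3 * b_) += v;
            Ke(3 * a_ + 1, 3 * b_ + 1) += v;
            Ke(3 * a_ + 2, 3 * b_ + 2) += v;
          }
      }
    }
    vols(e) = arma::accu(detj);
    int dof[24];
    for (int i = 0; i < 8; ++i)
      for (int d = 0; d < 3; ++d) dof[3 * i + d] = 3 * (elems(e, i) - 1) + d;
    for (int a = 0; a < 24; ++a)
      for (int b = 0; b < 24; ++b, ++p) {
        ii[p] = dof[a];
        jj[p] = dof[b];
        vv[p] = Ke(a, b);
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["v"] = vv,
                      _["volumes"] = vols);
}

// [[Rcpp::export]]
arma::vec hex8_min_detj(const arma::mat &nodes, const arma::imat &elems) {
  int ne = elems.n_rows;
  arma::vec out(ne);
  arma::mat X(8, 3), G(3, 8), J(3, 3);
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 8; ++i) X.row(i) = nodes.row(elems(e, i) - 1);
    double mn = arma::datum::inf;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          dshape(a ? GP : -GP, b ? GP : -GP, c ? GP : -GP, G);
          J = G * X;
          double dj = arma::det(J);
          if (dj < mn) mn = dj;
        }
    out(e) = mn;
  }
  return out;
}

// volume-weighted element-mean stress (Voigt xx,yy,zz,xy,yz,zx) and
// displacement gradient H(a,b) = du_a/dx_b (row-major 9) from displacements
// [[Rcpp::export]]
List hex8_recover(const arma::mat &nodes, const arma::imat &elems,
                  const arma::vec &Evec, const arma::vec &nuvec,
                  const arma::mat &U) {
  int ne = elems.n_rows;
  arma::mat stress(ne, 6), hgrad(ne, 9);
  arma::vec vols(ne);
  arma::mat X(8, 3), Ue(8, 3), D(6, 6), B(6, 24), gbar(3, 8);
  arma::cube dndx(3, 8, 8);
  arma::vec detj(8), ue(24), sig(6);
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 8; ++i) {
      X.row(i) = nodes.row(elems(e, i) - 1);
      Ue.row(i) = U.row(elems(e, i) - 1);
      for (int d = 0; d < 3; ++d) ue(3 * i + d) = Ue(i, d);
    }
    if (!element_quadrature(X, dndx, detj, gbar))
      stop("non-positive Jacobian in element %d", e + 1);
    material_matrix(Evec(e), nuvec(e), D);
    arma::vec smean(6, arma::fill::zeros);
    arma::mat hmean(3, 3, arma::fill::zeros);
    double vol = 0;
    for (int q = 0; q < 8; ++q) {
      bbar_matrix(dndx.slice(q), gbar, B);
      sig = D * (B * ue);
      smean += sig * detj(q);
      // H = Ue^T * dndx^T : (3x8)^T? H(a,b) = sum_i Ue(i,a) dndx(b,i)
      hmean += (Ue.t() * dndx.slice(q).t()) * detj(q);
      vol += detj(q);
    }
    smean /= vol;
    hmean /= vol;
    for (int k = 0; k < 6; ++k) stress(e, k) = smean(k);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) hgrad(e, 3 * a + b) = hmean(a, b);
    vols(e) = vol;
  }
  return List::create(_["stress"] = stress, _["hgrad"] = hgrad,
                      _["volumes"] = vols);
}

// [[Rcpp::export]]
IntegerVector nn_index(const arma::mat &P, const arma::mat &Q) {
  int m = P.n_rows, n = Q.n_rows;
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = arma::datum::inf;
    int bj = 0;
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    for (int j = 0; j < n; ++j) {
      double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

static double closest_on_tri(const arma::rowvec &p, const arma::rowvec &a,
                             const arma::rowvec &b, const arma::rowvec &c,
                             arma::rowvec &cp, double &w0, double &w1,
                             double &w2) {
  arma::rowvec ab = b - a, ac = c - a, ap = p - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { cp = a; w0 = 1; w1 = 0; w2 = 0; return arma::norm(p - a); }
  arma::rowvec bp = p - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { cp = b; w0 = 0; w1 = 1; w2 = 0; return arma::norm(p - b); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    cp = a + v * ab; w0 = 1 - v; w1 = v; w2 = 0; return arma::norm(p - cp);
  }
  arma::rowvec cpv = p - c;
  double d5 = arma::dot(ab, cpv), d6 = arma::dot(ac, cpv);
  if (d6 >= 0 && d5 <= d6) { cp = c; w0 = 0; w1 = 0; w2 = 1; return arma::norm(p - c); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    cp = a + w * ac; w0 = 1 - w; w1 = 0; w2 = w; return arma::norm(p - cp);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    cp = b + w * (c - b); w0 = 0; w1 = 1 - w; w2 = w; return arma::norm(p - cp);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  cp = a + ab * v + ac * w;
  w0 = 1 - v - w; w1 = v; w2 = w;
  return arma::norm(p - cp);
}

// Closest point of each slave node on a quad-facet surface (each quad split
// into triangles 1-2-3 and 1-3-4). Returns facet index (1-based), closest
// point, signed gap along the facet-triangle normal (positive on the
// outward side), and interpolation weights on the 4 facet nodes.
// [[Rcpp::export]]
List closest_facet_points(const arma::mat &S, const arma::mat &nodes,
                          const arma::imat &facets) {
  int m = S.n_rows, nf = facets.n_rows;
  IntegerVector fidx(m);
  NumericMatrix cps(m, 3), Wts(m, 4), Nrm(m, 3);
  NumericVector gap(m), dist(m);
  arma::rowvec cp(3), cbest(3);
  // facet bounding spheres for early rejection
  arma::mat fc(nf, 3);
  arma::vec fr(nf);
  for (int f = 0; f < nf; ++f) {
    arma::rowvec ctr(3, arma::fill::zeros);
    for (int k = 0; k < 4; ++k) ctr += nodes.row(facets(f, k) - 1);
    ctr *= 0.25;
    double rr = 0;
    for (int k = 0; k < 4; ++k) {
      double d2 = arma::norm(nodes.row(facets(f, k) - 1) - ctr);
      if (d2 > rr) rr = d2;
    }
    fc.row(f) = ctr;
    fr(f) = rr;
  }
  for (int i = 0; i < m; ++i) {
    arma::rowvec p = S.row(i);
    double best = arma::datum::inf;
    int bf = 0;
    double bw[4] = {0, 0, 0, 0};
    arma::rowvec bn(3);
    for (int f = 0; f < nf; ++f) {
      double dx = p(0) - fc(f, 0), dy = p(1) - fc(f, 1), dz = p(2) - fc(f, 2);
      double dctr = std::sqrt(dx * dx + dy * dy + dz * dz) - fr(f);
      if (dctr > best) continue;
      const arma::rowvec a = nodes.row(facets(f, 0) - 1);
      const arma::rowvec b = nodes.row(facets(f, 1) - 1);
      const arma::rowvec c = nodes.row(facets(f, 2) - 1);
      const arma::rowvec d = nodes.row(facets(f, 3) - 1);
      double w0, w1, w2;
      double dd = closest_on_tri(p, a, b, c, cp, w0, w1, w2);
      if (dd < best) {
        best = dd; bf = f; cbest = cp;
        bw[0] = w0; bw[1] = w1; bw[2] = w2; bw[3] = 0;
        arma::rowvec n = arma::cross(b - a, c - a);
        bn = n / std::max(arma::norm(n), 1e-300);
      }
      dd = closest_on_tri(p, a, c, d, cp, w0, w1, w2);
      if (dd < best) {
        best = dd; bf = f; cbest = cp;
        bw[0] = w0; bw[1] = 0; bw[2] = w1; bw[3] = w2;
        arma::rowvec n = arma::cross(c - a, d - a);
        bn = n / std::max(arma::norm(n), 1e-300);
      }
    }
    fidx[i] = bf + 1;
    for (int k = 0; k < 3; ++k) { cps(i, k) = cbest(k); Nrm(i, k) = bn(k); }
    for (int k = 0; k < 4; ++k) Wts(i, k) = bw[k];
    gap[i] = arma::dot(S.row(i) - cbest, bn);
    dist[i] = best;
  }
  return List::create(_["facet"] = fidx, _["point"] = cps, _["gap"] = gap,
                      _["dist"] = dist, _["weights"] = Wts,
                      _["normal"] = Nrm);
}

// Locate scattered query points in a quad-facet surface by inverse bilinear
// mapping in the XY plane and interpolate nodal values (exact for linear
// fields). Queries outside every facet get NA.
// [[Rcpp::export]]
NumericVector facet_interpolate_xy(const arma::mat &nodes,
                                   const arma::imat &facets,
                                   const arma::vec &values,
                                   const arma::vec &qx, const arma::vec &qy) {
  int nf = facets.n_rows, nq = qx.n_elem;
  NumericVector out(nq, NA_REAL);
  // facet bounding boxes
  arma::mat bb(nf, 4);
  for (int f = 0; f < nf; ++f) {
    double xmn = arma::datum::inf, xmx = -arma::datum::inf;
    double ymn = arma::datum::inf, ymx = -arma::datum::inf;
    for (int k = 0; k < 4; ++k) {
      double x = nodes(facets(f, k) - 1, 0), y = nodes(facets(f, k) - 1, 1);
      xmn = std::min(xmn, x); xmx = std::max(xmx, x);
      ymn = std::min(ymn, y); ymx = std::max(ymx, y);
    }
    bb(f, 0) = xmn; bb(f, 1) = xmx; bb(f, 2) = ymn; bb(f, 3) = ymx;
  }
  for (int i = 0; i < nq; ++i) {
    double px = qx(i), py = qy(i);
    for (int f = 0; f < nf; ++f) {
      if (px < bb(f, 0) - 1e-9 || px > bb(f, 1) + 1e-9 ||
          py < bb(f, 2) - 1e-9 || py > bb(f, 3) + 1e-9)
        continue;
      double x[4], y[4], v[4];
      for (int k = 0; k < 4; ++k) {
        x[k] = nodes(facets(f, k) - 1, 0);
        y[k] = nodes(facets(f, k) - 1, 1);
        v[k] = values(facets(f, k) - 1);
      }
      // Newton for (s,t) in [-1,1]^2 with bilinear map
      double s = 0, t = 0;
      bool ok = false;
      for (int it = 0; it < 20; ++it) {
        double N0 = 0.25 * (1 - s) * (1 - t), N1 = 0.25 * (1 + s) * (1 - t);
        double N2 = 0.25 * (1 + s) * (1 + t), N3 = 0.25 * (1 - s) * (1 + t);
        double fx = N0 * x[0] + N1 * x[1] + N2 * x[2] + N3 * x[3] - px;
        double fy = N0 * y[0] + N1 * y[1] + N2 * y[2] + N3 * y[3] - py;
        if (std::abs(fx) < 1e-12 && std::abs(fy) < 1e-12) { ok = true; break; }
        double dxs = 0.25 * (-(1 - t) * x[0] + (1 - t) * x[1] + (1 + t) * x[2] - (1 + t) * x[3]);
        double dxt = 0.25 * (-(1 - s) * x[0] - (1 + s) * x[1] + (1 + s) * x[2] + (1 - s) * x[3]);
        double dys = 0.25 * (-(1 - t) * y[0] + (1 - t) * y[1] + (1 + t) * y[2] - (1 + t) * y[3]);
        double dyt = 0.25 * (-(1 - s) * y[0] - (1 + s) * y[1] + (1 + s) * y[2] + (1 - s) * y[3]);
        double det = dxs * dyt - dxt * dys;
        if (std::abs(det) < 1e-300) break;
        s -= (fx * dyt - fy * dxt) / det;
        t -= (fy * dxs - fx * dys) / det;
        if (s < -2 || s > 2 || t < -2 || t > 2) break;
      }
      if (!ok) {
        // check convergence state once more
        double N0 = 0.25 * (1 - s) * (1 - t), N1 = 0.25 * (1 + s) * (1 - t);
        double N2 = 0.25 * (1 + s) * (1 + t), N3 = 0.25 * (1 - s) * (1 + t);
        double fx = N0 * x[0] + N1 * x[1] + N2 * x[2] + N3 * x[3] - px;
        double fy = N0 * y[0] + N1 * y[1] + N2 * y[2] + N3 * y[3] - py;
        if (std::abs(fx) < 1e-9 && std::abs(fy) < 1e-9) ok = true;
      }
      if (ok && s >= -1.0000001 && s <= 1.0000001 && t >= -1.0000001 &&
          t <= 1.0000001) {
        double N0 = 0.25 * (1 - s) * (1 - t), N1 = 0.25 * (1 + s) * (1 - t);
        double N2 = 0.25 * (1 + s) * (1 + t), N3 = 0.25 * (1 - s) * (1 + t);
        out[i] = N0 * v[0] + N1 * v[1] + N2 * v[2] + N3 * v[3];
        break;
      }
    }
  }
  return out;
}

// accumulate v into n slots by 1-based index map (duplicate-summing)
// [[Rcpp::export]]
NumericVector accum_by_index(const NumericVector &v, const IntegerVector &map,
                             int n) {
  NumericVector out(n);
  int m = v.size();
  for (int k = 0; k < m; ++k) out[map[k] - 1] += v[k];
  return out;
}

// Moving least-squares quadratic interpolation of scattered surface heights
// z(x, y): for each query, the k nearest nodes (plan-view distance) are fit
// with a Gaussian-weighted full quadratic; reproduces quadratic surfaces
// exactly, so curvature survives resampling.
// [[Rcpp::export]]
NumericMatrix mls_quadratic_fit(const arma::mat &pts, const arma::vec &qx,
                                const arma::vec &qy, int k = 25) {
  int n = pts.n_rows, m = qx.n_elem;
  if (k > n) k = n;
  NumericMatrix out(m, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  arma::vec d2(n);
  arma::uvec ord;
  arma::mat A(k, 6);
  arma::vec w(k), b(k);
  for (int q = 0; q < m; ++q) {
    double x0 = qx(q), y0 = qy(q);
    for (int i = 0; i < n; ++i) {
      double dx = pts(i, 0) - x0, dy = pts(i, 1) - y0;
      d2(i) = dx * dx + dy * dy;
    }
    ord = arma::sort_index(d2);
    double h = 1.1 * std::sqrt(d2(ord(k - 1))) + 1e-12;
    for (int j = 0; j < k; ++j) {
      int i = ord(j);
      double dx = pts(i, 0) - x0, dy = pts(i, 1) - y0;
      // Wendland C2 weight: vanishes smoothly at the support edge, so the
      // interpolant stays smooth as the neighbour set changes
      double dd = std::sqrt(d2(i)) / h;
      double wt = (dd < 1.0) ? std::pow(1.0 - dd, 4) * (4.0 * dd + 1.0) : 0.0;
      A(j, 0) = wt;
      A(j, 1) = wt * dx;
      A(j, 2) = wt * dy;
      A(j, 3) = wt * dx * dx;
      A(j, 4) = wt * dx * dy;
      A(j, 5) = wt * dy * dy;
      b(j) = wt * pts(i, 2);
    }
    arma::vec c;
    bool ok = arma::solve(c, A, b);
    if (ok) {
      out(q, 0) = c(0);
      out(q, 1) = c(1);
      out(q, 2) = c(2);
    }
  }
  return out;
}
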