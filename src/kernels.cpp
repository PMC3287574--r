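#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-neighbourhood offsets in row-major scan order of the 3x3 window
static const int DR[8] = {-1, -1, -1,  0, 0,  1, 1, 1};
static const int DC[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): marker is dilated geodesically under mask until stability.
// Requires marker <= mask elementwise; 8-connected.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask shapes differ");
  NumericMatrix J(clone(marker));

  // forward raster scan: neighbours already visited (N+)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) { // (-1,-1),(-1,0),(-1,1),(0,-1)
        int rr = r + DR[k], cc = c + DC[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  // backward scan with N-; collect queue seeds
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 4; k < 8; ++k) { // (0,1),(1,-1),(1,0),(1,1)
        int rr = r + DR[k], cc = c + DC[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
      for (int k = 4; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(c * nr + r);
          break;
        }
      }
    }
  }
  // FIFO propagation
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        fifo.push(cc * nr + rr);
      }
    }
  }
  return J;
}

// 8-connected components of nonzero pixels, labelled 1..K in row-major
// discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (bw(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(c * nr + r);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = pr + DR[k], cc = pc + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (bw(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

struct FloodEntry {
  double h;
  long long counter;
  int idx;
  int label;
};
struct FloodCmp {
  // min-heap on (height, insertion counter)
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.h != b.h) return a.h > b.h;
    return a.counter > b.counter;
  }
};

// Marker-controlled watershed by priority flooding. Marker pixels are
// enqueued (row-major) at their own gradient height; pixels pop in
// (height, insertion order) and claim unlabelled 8-neighbours, enqueued at
// max(own height, popped height). Total labelling, no ridge label.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix grad, IntegerMatrix markers) {
  int nr = grad.nrow(), nc = grad.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("gradient and marker shapes differ");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long long counter = 0;
  bool any = false;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int m = markers(r, c);
      if (m != 0) {
        any = true;
        lab(r, c) = m;
        pq.push(FloodEntry{grad(r, c), counter++, c * nr + r, m});
      }
    }
  }
  if (!any) stop("marker map has no nonzero marker");
  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) == 0) {
        lab(rr, cc) = e.label;
        double h = grad(rr, cc) > e.h ? grad(rr, cc) : e.h;
        pq.push(FloodEntry{h, counter++, cc * nr + rr, e.label});
      }
    }
  }
  return lab;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// One explicit Chan-Vese update: phi += dt * delta_eps(phi) *
// (mu*curvature + l1*(I-c1)^2 - l2*(I-c2)^2), replicate boundaries,
// central-difference curvature with a small denominator guard.
// Sign convention: phi < 0 inside, so a pixel resembling the inside mean
// c1 is pushed negative and one resembling c2 positive.
// [[Rcpp::export]]
NumericMatrix cpp_cv_step(NumericMatrix phi, NumericMatrix img,
                          double c1, double c2,
                          double l1, double l2, double mu,
                          double eps, double dt) {
  int nr = phi.nrow(), nc = phi.ncol();
  NumericMatrix out(nr, nc);
  const double guard = 1e-8;
  for (int c = 0; c < nc; ++c) {
    int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
    for (int r = 0; r < nr; ++r) {
      int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      double p = phi(r, c);
      double px = (phi(r, cp) - phi(r, cm)) / 2.0;
      double py = (phi(rp, c) - phi(rm, c)) / 2.0;
      double pxx = phi(r, cp) - 2.0 * p + phi(r, cm);
      double pyy = phi(rp, c) - 2.0 * p + phi(rm, c);
      double pxy = (phi(rp, cp) - phi(rp, cm) - phi(rm, cp) + phi(rm, cm)) / 4.0;
      double g2 = px * px + py * py;
      double kappa = (pxx * py * py - 2.0 * px * py * pxy + pyy * px * px) /
                     (std::pow(g2, 1.5) + guard);
      double I = img(r, c);
      double delta = eps / (M_PI * (eps * eps + p * p));
      double force = mu * kappa + l1 * (I - c1) * (I - c1) -
                     l2 * (I - c2) * (I - c2);
      out(r, c) = p + dt * delta * force;
    }
  }
  return out;
}

// Discretised Chan-Vese energy: sharp-partition data terms (phi<0 inside)
// with region means c1, c2, plus mu * sum(delta_eps(phi) * |grad phi|)
// (co-area contour length), central differences, replicate boundaries.
// [[Rcpp::export]]
List cpp_cv_energy(NumericMatrix img, NumericMatrix phi,
                   double l1, double l2, double mu, double eps) {
  int nr = phi.nrow(), nc = phi.ncol();
  double s1 = 0, s2 = 0;
  long n1 = 0, n2 = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (phi(r, c) < 0) { s1 += img(r, c); ++n1; }
      else               { s2 += img(r, c); ++n2; }
    }
  double c1 = n1 > 0 ? s1 / n1 : NA_REAL;
  double c2 = n2 > 0 ? s2 / n2 : NA_REAL;
  double data1 = 0, data2 = 0, len = 0;
  for (int c = 0; c < nc; ++c) {
    int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
    for (int r = 0; r < nr; ++r) {
      int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      double I = img(r, c), p = phi(r, c);
      if (p < 0) { if (n1 > 0) data1 += (I - c1) * (I - c1); }
      else       { if (n2 > 0) data2 += (I - c2) * (I - c2); }
      double px = (phi(r, cp) - phi(r, cm)) / 2.0;
      double py = (phi(rp, c) - phi(rm, c)) / 2.0;
      double delta = eps / (M_PI * (eps * eps + p * p));
      len += delta * std::sqrt(px * px + py * py);
    }
  }
  double total = l1 * data1 + l2 * data2 + mu * len;
  return List::create(_["energy"] = total, _["data1"] = data1,
                      _["data2"] = data2, _["length"] = len,
                      _["c1"] = c1, _["c2"] = c2);
}
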