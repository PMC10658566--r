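#include <Rcpp.h>
using namespace Rcpp;

// Explicit FTCS time stepping of the 2D diffusion equation on the half
// unit cell, in conservative (flux) form. `conc` holds mass per cell; a
// face flux ax*(C_l - C_r) moves mass between neighbours, so the total of
// grid + receptor is conserved to rounding error. Boundaries with no
// neighbour (symmetry axis, outer midline, top) exchange nothing; the
// bottom row optionally exchanges with a receptor compartment:
//   bottom_mode 0: closed (no receptor)
//   bottom_mode 1: perfect sink (receptor concentration pinned at zero)
//   bottom_mode 2: finite well-mixed receptor of 2D capacity recv_area;
//                  flux = ay * (cell mass - recv_mass * cell_area/recv_area)
// record_steps: sorted 0-based step counts (0 = initial state) at which the
// receptor mass is recorded. snapshot_steps: steps at which the full field
// is copied out.
// [[Rcpp::export]]
List ftcs_run(NumericMatrix conc0, double D, double dx, double dy, double dt,
              int nsteps, IntegerVector record_steps,
              int bottom_mode, double recv_area, double recv_mass0,
              IntegerVector snapshot_steps) {
  const int nr = conc0.nrow(), nc = conc0.ncol();
  NumericMatrix C = clone(conc0);
  const double ax = D * dt / (dx * dx);
  const double ay = D * dt / (dy * dy);
  const double cell_area = dx * dy;
  double recv = recv_mass0;

  NumericVector rec(record_steps.size());
  List snaps(snapshot_steps.size());
  int irec = 0, isnap = 0;
  while (irec < record_steps.size() && record_steps[irec] <= 0)
    rec[irec++] = recv;
  while (isnap < snapshot_steps.size() && snapshot_steps[isnap] <= 0)
    snaps[isnap++] = clone(C);

  NumericMatrix B(nr, nc); // write buffer, swapped with C each step
  for (int s = 1; s <= nsteps; ++s) {
    NumericMatrix N = B;
    std::copy(C.begin(), C.end(), N.begin());
    // horizontal faces between columns j-1 and j
    for (int j = 1; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double f = ax * (C(i, j - 1) - C(i, j));
        N(i, j - 1) -= f;
        N(i, j) += f;
      }
    }
    // vertical faces between rows i-1 and i
    for (int i = 1; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double f = ay * (C(i - 1, j) - C(i, j));
        N(i - 1, j) -= f;
        N(i, j) += f;
      }
    }
    // receptor exchange across the bottom boundary
    if (bottom_mode == 1) {
      for (int j = 0; j < nc; ++j) {
        double f = ay * C(nr - 1, j);
        N(nr - 1, j) -= f;
        recv += f;
      }
    } else if (bottom_mode == 2) {
      double ur = recv * cell_area / recv_area; // receptor mass per cell eq.
      for (int j = 0; j < nc; ++j) {
        double f = ay * (C(nr - 1, j) - ur);
        N(nr - 1, j) -= f;
        recv += f;
      }
    }
    B = C;
    C = N;
    if (s % 64 == 0 || s == nsteps) {
      double mn = 0.0, scale = 0.0;
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) {
          if (C(i, j) < mn) mn = C(i, j);
          if (std::abs(C(i, j)) > scale) scale = std::abs(C(i, j));
        }
      if (mn < -1e-12 * std::max(scale, 1e-300))
        stop("negative concentration detected: the explicit scheme is "
             "unstable, reduce dt below the stability limit");
    }
    while (irec < record_steps.size() && record_steps[irec] == s)
      rec[irec++] = recv;
    while (isnap < snapshot_steps.size() && snapshot_steps[isnap] == s)
      snaps[isnap++] = clone(C);
  }
  while (irec < record_steps.size()) rec[irec++] = recv;

  return List::create(_["receptor"] = rec, _["conc"] = C,
                      _["receptor_mass"] = recv, _["snapshots"] = snaps);
}
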