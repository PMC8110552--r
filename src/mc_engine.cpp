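#include <Rcpp.h>
using namespace Rcpp;

// Rejection kinetic Monte Carlo on a periodic rectangular lattice.
//
// One iteration = one event ATTEMPT: draw a focal site uniformly, draw a
// reaction channel with its normalized probability, and fire it only if the
// focal state (and, when required, the state of a partner site drawn at the
// channel's range) matches the channel's requirements. Failed attempts
// consume an iteration. At most one cell changes per iteration.
//
// Partner geometry at range 1 is always the 4 nearest (axial) neighbors.
// At longer ranges it is configurable:
//   0 = axial:     the 4 sites at offset +/-h along a row or column
//   1 = euclidean: a site at Euclidean distance ~h (uniform angle, rounded)
//   2 = chebyshev: uniform over the 8h sites of the square ring
//                  max(|dr|, |dc|) = h
// The square ring is the default at the R level: it preserves the
// one-dimensional wavelength selection (offset exactly h along each axis)
// and reproduces the ~2h pattern wavelength in 2D.
//
// All randomness comes from R's RNG in a fixed draw order (site, channel,
// then partner when the channel needs one and the focal state matched), so
// trajectories are bit-reproducible from set.seed().

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
List mc_run_cpp(IntegerMatrix grid_in,
                IntegerVector focal,
                IntegerVector partner_state,
                IntegerVector partner_range,
                IntegerVector product,
                NumericVector cumprob,
                double n_iter,
                int geometry) {
  IntegerMatrix grid = clone(grid_in);
  const int nr = grid.nrow(), nc = grid.ncol();
  const R_xlen_t n_sites = (R_xlen_t)nr * nc;
  const int n_chan = focal.size();
  long long changed = 0;
  const long long iters = (long long)n_iter;

  for (long long it = 0; it < iters; ++it) {
    R_xlen_t site = (R_xlen_t)(unif_rand() * n_sites);
    if (site >= n_sites) site = n_sites - 1;
    double u = unif_rand();
    int ch = n_chan - 1;
    for (int c = 0; c < n_chan; ++c) {
      if (u < cumprob[c]) { ch = c; break; }
    }
    int r0 = (int)(site % nr), c0 = (int)(site / nr);
    if (grid(r0, c0) != focal[ch]) continue;
    if (partner_range[ch] != NA_INTEGER) {
      const int h = partner_range[ch];
      int pr = r0, pc = c0;
      if (h == 1 || geometry == 0) {
        int dir = (int)(unif_rand() * 4.0);
        if (dir > 3) dir = 3;
        switch (dir) {
          case 0: pr = wrap(r0 - h, nr); break;
          case 1: pr = wrap(r0 + h, nr); break;
          case 2: pc = wrap(c0 - h, nc); break;
          default: pc = wrap(c0 + h, nc);
        }
      } else if (geometry == 1) {
        double th = unif_rand() * 2.0 * M_PI;
        pr = wrap(r0 + (int)std::lround(h * std::sin(th)), nr);
        pc = wrap(c0 + (int)std::lround(h * std::cos(th)), nc);
      } else {
        int m = (int)(unif_rand() * 8.0 * h);
        if (m >= 8 * h) m = 8 * h - 1;
        int side = m / (2 * h), off = m % (2 * h) - h;  // off in [-h, h-1]
        int dr, dc;
        switch (side) {
          case 0:  dc = h;  dr = off;      break;
          case 1:  dc = -h; dr = off + 1;  break;
          case 2:  dr = h;  dc = off + 1;  break;
          default: dr = -h; dc = off;
        }
        pr = wrap(r0 + dr, nr);
        pc = wrap(c0 + dc, nc);
      }
      if (grid(pr, pc) != partner_state[ch]) continue;
    }
    if (grid(r0, c0) != product[ch]) {
      grid(r0, c0) = product[ch];
      ++changed;
    }
  }
  return List::create(_["grid"] = grid, _["changed"] = (double)changed);
}
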