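# Independent oracle for the discrete mean-field right-hand side on a
# periodic 1D ring, written directly from the reaction channels with plain
# index arithmetic (no reuse of package internals).
oracle_rhs_1d <- function(x, m, p) {
  n <- length(x)
  at <- function(f, i, k) f[((i - 1 + k) %% n) + 1]
  s <- 1 - x - m
  dx <- dm <- numeric(n)
  for (i in seq_len(n)) {
    dx[i] <- p$b_X * s[i] - p$d_X * x[i] -
      0.5 * p$s_M * x[i] * (at(m, i, 1) + at(m, i, -1))
    dm[i] <- p$b_M * s[i] -
      0.5 * p$s_X * m[i] * (at(x, i, 1) + at(x, i, -1)) -
      0.5 * p$d_MX * m[i] * (at(x, i, p$h) + at(x, i, -p$h)) -
      0.5 * p$d_M * m[i] * (at(s, i, p$h) + at(s, i, -p$h) +
                              at(m, i, p$h) + at(m, i, -p$h))
  }
  list(dx = dx, dm = dm)
}

# Quadratic polynomial helpers: for quadratic fields the second-order
# Taylor expansion is exact, so the discrete channel sums must equal the
# continuum reaction + cross-diffusion form to machine precision.
qpoly <- function(coef) function(r) coef[1] + coef[2] * r + coef[3] * r^2
qpoly_dd <- function(coef) 2 * coef[3]

# Discrete per-node rate of change at position r for quadratic fields
# x(.), m(.), lattice spacing a, long range offset h*a; from the channel
# definitions, independently of the package implementation.
oracle_discrete_at <- function(xf, mf, r, p, a) {
  s_at <- function(rr) 1 - xf(rr) - mf(rr)
  dx <- p$b_X * s_at(r) - p$d_X * xf(r) -
    0.5 * p$s_M * xf(r) * (mf(r + a) + mf(r - a))
  dm <- p$b_M * s_at(r) -
    0.5 * p$s_X * mf(r) * (xf(r + a) + xf(r - a)) -
    0.5 * p$d_MX * mf(r) * (xf(r + p$h * a) + xf(r - p$h * a)) -
    0.5 * p$d_M * mf(r) * (s_at(r + p$h * a) + s_at(r - p$h * a) +
                             mf(r + p$h * a) + mf(r - p$h * a))
  c(dx = dx, dm = dm)
}

# Orientation of the central block (used for ablation recovery checks).
central_block <- function(f, frac = 0.75) {
  nr <- nrow(f); nc <- ncol(f)
  br <- floor(frac * nr); bc <- floor(frac * nc)
  r0 <- floor((nr - br) / 2); c0 <- floor((nc - bc) / 2)
  f[(r0 + 1):(r0 + br), (c0 + 1):(c0 + bc)]
}
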