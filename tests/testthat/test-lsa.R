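stripe_regime_params <- function(h = 15) {
  survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = h)
}

test_that("simplified continuum coefficients reduce to the canonical form", {
  p <- stripe_regime_params(h = 15)
  co <- continuum_coefficients(p, a = 1)
  xs <- seq(0.1, 0.9, by = 0.2)
  ms <- seq(0.05, 0.45, by = 0.1)
  for (x in xs) for (m in ms) {
    s <- p$s_X
    expect_equal(co$R_x(x, m), p$b_X * (1 - x - m) - s * m * x)
    expect_equal(co$R_m(x, m),
                 p$b_M * (1 - x - m) - s * m * x - p$d_M * m * (1 - x))
    expect_equal(co$D_xm(x, m), -(s / 2) * x)
    expect_equal(co$D_mx(x, m), (p$h^2 / 2) * p$d_M * m - (s / 2) * m)
    D <- co$D(x, m)
    expect_equal(diag(D), c(0, 0))
  }
  # no cross-diffusion into x when s_M = 0
  p0 <- survival_params(b_X = 1, b_M = 2, d_M = 3, s_X = 1, s_M = 0, h = 4)
  co0 <- continuum_coefficients(p0)
  expect_equal(co0$D_xm(0.7, 0.2), 0)
})

test_that("continuum coefficients match the exact-quadratic Taylor oracle", {
  # for quadratic fields the second-order expansion is exact, so the
  # discrete channel sums must equal reaction + cross-diffusion forms to
  # machine precision, term by term, for arbitrary (rational) rates
  set.seed(31)
  for (i in 1:10) {
    p <- survival_params(b_X = sample(1:8, 1) / sample(1:4, 1),
                         b_M = sample(1:20, 1) / sample(1:4, 1),
                         d_X = sample(0:4, 1) / 4,
                         d_M = sample(1:20, 1) / 2,
                         d_MX = sample(0:3, 1) / 8,
                         s_X = sample(1:6, 1) / 3,
                         s_M = sample(1:6, 1) / 3,
                         h = sample(2:12, 1))
    a <- sample(c(0.5, 1, 2), 1)
    co <- continuum_coefficients(p, a = a)
    xc <- stats::runif(3, -0.1, 0.1)
    mc <- stats::runif(3, -0.1, 0.1)
    xf <- qpoly(xc); mf <- qpoly(mc)
    r0 <- stats::runif(1, -2, 2)
    disc <- oracle_discrete_at(xf, mf, r0, p, a)
    x <- xf(r0); m <- mf(r0)
    cont_dx <- co$R_x(x, m) + co$D_xm(x, m) * qpoly_dd(mc)
    cont_dm <- co$R_m(x, m) + co$D_mx(x, m) * qpoly_dd(xc)
    expect_equal(unname(disc["dx"]), cont_dx, tolerance = 1e-10)
    expect_equal(unname(disc["dm"]), cont_dm, tolerance = 1e-10)
  }
})

test_that("the reaction Jacobian matches the closed forms at the mixed state", {
  p <- stripe_regime_params()
  jac <- jacobian_at(p, 0.6, 0.25)
  expect_equal(jac$J, matrix(c(-1.25, -5, -1.6, -11.2), 2, 2))
  expect_equal(jac$trace, -12.45)
  expect_equal(jac$determinant, 6)
  expect_equal(jac$determinant, (p$b_M - p$b_X) * p$s_X)
})

test_that("Det(J) = (b_M - b_X) s at the mixed state for random rates", {
  set.seed(33)
  for (i in 1:10) {
    p <- survival_params(b_X = stats::runif(1, 0.5, 2),
                         b_M = stats::runif(1, 0.5, 9),
                         d_M = stats::runif(1, 0.5, 9),
                         s = stats::runif(1, 0.3, 2), h = 3)
    ss <- homogeneous_steady_states(p)
    jac <- jacobian_at(p, ss$x[2], ss$m[2])
    expect_equal(jac$determinant, (p$b_M - p$b_X) * p$s_X,
                 tolerance = 1e-10)
    expect_lt(jac$trace, 0)
  }
  # transcritical degeneracy
  p0 <- survival_params(b_X = 2, b_M = 2, d_M = 5, s = 1, h = 3)
  ss0 <- homogeneous_steady_states(p0)
  expect_equal(jacobian_at(p0, ss0$x[2], ss0$m[2])$determinant, 0,
               tolerance = 1e-12)
})

test_that("dispersion relation reduces to the Jacobian at k = 0", {
  p <- stripe_regime_params()
  dc <- dispersion_relation(p, k = c(0, 0.5, 1))
  jac <- jacobian_at(p, 0.6, 0.25)
  ev <- sort(Re(eigen(jac$J, only.values = TRUE)$values))
  expect_equal(sort(Re(c(dc$omega1[1], dc$omega2[1]))), ev,
               tolerance = 1e-10)
  expect_true(all(Re(c(dc$omega1[1], dc$omega2[1])) < 0))
})

test_that("Det(L) is the hand-derived quadratic in k^2 at the reference stripe-regime point", {
  co <- stripesim:::detL_quadratic(stripe_regime_params(h = 15))
  expect_equal(unname(co["c0"]), 6)
  expect_equal(unname(co["c1"]), -403.3)
  expect_equal(unname(co["c2"]), 75.9)
  # negative minimum -> an unstable band of wavenumbers exists
  expect_lt(co["c0"] - co["c1"]^2 / (4 * co["c2"]), 0)
})

test_that("the destabilizing mode is real (stationary) inside the band", {
  dc <- dispersion_relation(stripe_regime_params(h = 15),
                            k = seq(0.01, 2, length.out = 400))
  i <- which.max(dc$re_max)
  expect_gt(dc$re_max[i], 0)
  expect_equal(Im(dc$omega1[i]), 0)
  expect_true(dc$stationary[i])
})

test_that("dispersion analysis rejects an unphysical mixed state", {
  expect_error(dispersion_relation(
    survival_params(b_X = 2, b_M = 1, d_M = 5, s = 1, h = 4)),
    "transcritical|unphysical")
})

test_that("turing_threshold satisfies the simultaneous bifurcation conditions", {
  p <- stripe_regime_params()
  thr <- turing_threshold(p)
  expect_lt(thr$h_T, 15)
  expect_equal(thr$lambda_T, 2 * pi / thr$k_T)
  co <- stripesim:::detL_quadratic(p, h = thr$h_T)
  # min over k^2 of Det(L) vanishes at the bifurcation ...
  expect_lt(abs(co["c0"] - co["c1"]^2 / (4 * co["c2"])), 1e-8)
  # ... and the k^2-derivative vanishes at k_T
  expect_lt(abs(co["c1"] + 2 * co["c2"] * thr$k_T^2), 1e-8)
  # just above threshold a narrow unstable band exists; just below, none
  up <- stripesim:::detL_quadratic(p, h = thr$h_T + 0.01)
  dn <- stripesim:::detL_quadratic(p, h = thr$h_T - 0.01)
  expect_lt(up["c0"] - up["c1"]^2 / (4 * up["c2"]), 0)
  expect_gt(dn["c0"] - dn["c1"]^2 / (4 * dn["c2"]), 0)
  expect_error(turing_threshold(p, h_range = c(100, 200)), "bifurcation")
})

test_that("h_T equals half the critical wavelength along d_M = b_M s", {
  for (bM in c(2, 4, 7)) {
    thr <- turing_threshold(
      survival_params(b_X = 1, b_M = bM, d_M = bM, s = 1, h = 1))
    expect_equal(thr$h_T, thr$lambda_T / 2, tolerance = 0.02)
  }
})

test_that("threshold surface marks undefined cells and finds the contour", {
  surf <- threshold_surface(b_M = c(0.5, 2, 3, 4),
                            d_M = seq(0.5, 6, by = 0.25))
  expect_true(all(!surf$defined[surf$b_M <= 1]))
  expect_true(all(surf$defined[surf$b_M > 1 & surf$d_M > 0.5]))
  contour <- attr(surf, "equal_contour")
  hit <- contour[!is.na(contour$d_M_equal), ]
  # the h_T = lambda_T / 2 contour tracks d_M = b_M s within one grid cell
  expect_true(all(abs(hit$d_M_equal - hit$b_M) <= 0.25 + 1e-9))
})

test_that("linear stability summaries are tidy", {
  res <- linear_stability(stripe_regime_params())
  g <- glance(res)
  expect_true(g$homogeneous_stable)
  expect_true(g$turing_unstable)
  expect_lt(g$h_T, 15)
  td <- tidy(res)
  expect_equal(td$value[td$term == "J_xx"], -1.25)
})
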