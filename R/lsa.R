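#' Continuum (PDE) coefficients of the Survival model
#'
#' Second-order continuum approximation of the discrete mean-field
#' equations on a lattice with cell diameter `a`: the discrete short- and
#' long-range interaction averages Taylor-expand into reaction terms plus
#' *cross-diffusion* couplings (no diagonal diffusion — the cells do not
#' move). The reaction terms are
#' `R_x = b_X (1 - x - m) - d_X x - s_M m x` and
#' `R_m = b_M (1 - x - m) - d_M m - (-d_M + d_MX + s_X) x m`;
#' the cross-diffusion matrix has entries
#' `D_xm = -(a^2/2) s_M x` and
#' `D_mx = (h^2 a^2 / 2) d_M m - (a^2/2) s_X m - (h^2 a^2/2) d_MX m`,
#' with zero diagonal.
#'
#' @param params A [survival_params()] object (general regime allowed).
#' @param a Cell diameter setting the space scale (default 1).
#' @return A `continuum_coefficients` list with functions `R_x(x, m)`,
#'   `R_m(x, m)`, `D_xm(x, m)`, `D_mx(x, m)` and `D(x, m)` (the 2x2
#'   matrix).
#' @export
continuum_coefficients <- function(params, a = 1) {
  stopifnot(inherits(params, "survival_params"), a > 0)
  p <- params
  R_x <- function(x, m) p$b_X * (1 - x - m) - p$d_X * x - p$s_M * m * x
  R_m <- function(x, m) {
    p$b_M * (1 - x - m) - p$d_M * m - (-p$d_M + p$d_MX + p$s_X) * x * m
  }
  D_xm <- function(x, m) -(a^2 / 2) * p$s_M * x
  D_mx <- function(x, m) {
    (p$h^2 * a^2 / 2) * p$d_M * m - (a^2 / 2) * p$s_X * m -
      (p$h^2 * a^2 / 2) * p$d_MX * m
  }
  structure(list(
    R_x = R_x, R_m = R_m, D_xm = D_xm, D_mx = D_mx,
    D = function(x, m) matrix(c(0, D_mx(x, m), D_xm(x, m), 0), 2, 2),
    a = a, params = params), class = "continuum_coefficients")
}

#' Jacobian of the simplified reaction terms at a state
#'
#' Analytic Jacobian of the reaction part of the simplified continuum
#' system (`d_X = d_MX = 0`, `s_X = s_M = s`):
#' rows `(-b_X - s m, -b_X - s x)` and
#' `(-b_M + d_M m - s m, -b_M - d_M + d_M x - s x)`.
#' At the mixed steady state the determinant collapses to
#' `(b_M - b_X) s` and every term of the trace is negative, so the state is
#' stable to spatially uniform perturbations whenever `b_M > b_X`.
#'
#' @param params Simplified [survival_params()].
#' @param x,m Occupancies at which to evaluate.
#' @return A list with `J` (2x2 matrix), `trace` and `determinant`.
#' @examples
#' jacobian_at(survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 15),
#'             x = 0.6, m = 0.25)
#' @export
jacobian_at <- function(params, x, m) {
  check_simplified(params)
  b_X <- params$b_X; b_M <- params$b_M
  d_M <- params$d_M; s <- params$s_X
  J <- matrix(c(-b_X - s * m, -b_M + d_M * m - s * m,
                -b_X - s * x, -b_M - d_M + d_M * x - s * x), 2, 2)
  list(J = J, trace = sum(diag(J)), determinant = det(J))
}

# Det(J - k^2 D) as a quadratic in k^2: c0 + c1 k^2 + c2 k^4,
# at the mixed steady state, optionally overriding h.
detL_quadratic <- function(params, h = params$h) {
  ss <- homogeneous_steady_states(params)
  x <- ss$x[2]; m <- ss$m[2]
  jac <- jacobian_at(params, x, m)
  s <- params$s_X
  D_xm <- -(s / 2) * x
  D_mx <- (h^2 / 2) * params$d_M * m - (s / 2) * m
  J <- jac$J
  c(c0 = jac$determinant,
    c1 = J[1, 2] * D_mx + J[2, 1] * D_xm,
    c2 = -D_xm * D_mx)
}

#' Dispersion relation of the simplified Survival model
#'
#' Linearizes the continuum system about the mixed homogeneous steady state
#' and, for each wavenumber `k`, solves the characteristic equation of
#' `L = J - k^2 D` for its two eigenvalues `omega`. A Turing instability is
#' present when some `k > 0` has a real eigenvalue with positive real part
#' (a stationary, spatially periodic mode).
#'
#' @param params Simplified [survival_params()] with `b_M > b_X`.
#' @param k Wavenumbers to evaluate (radians per lattice unit).
#' @return A tibble of class `dispersion_curve` with columns `k`,
#'   `trace_L`, `det_L`, `omega1`, `omega2` (complex; `omega1` has the
#'   larger real part), `re_max`, and `stationary` (destabilizing root real
#'   and positive). Attributes carry the Jacobian and steady state.
#' @examples
#' p <- survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 15)
#' dc <- dispersion_relation(p)
#' dc[which.max(dc$re_max), ]
#' @export
dispersion_relation <- function(params, k = seq(0, 2, length.out = 401)) {
  check_simplified(params)
  if (params$b_M <= params$b_X) {
    stop("the mixed steady state is unphysical/unstable for b_M <= b_X ",
         "(transcritical point at b_M = b_X)", call. = FALSE)
  }
  ss <- homogeneous_steady_states(params)
  x <- ss$x[2]; m <- ss$m[2]
  jac <- jacobian_at(params, x, m)
  co <- detL_quadratic(params)
  s <- params$s_X
  D_mx <- (params$h^2 / 2) * params$d_M * m - (s / 2) * m
  k2 <- k^2
  tr_L <- jac$trace                       # zero-diagonal D leaves Tr unchanged
  det_L <- co["c0"] + co["c1"] * k2 + co["c2"] * k2^2
  disc <- as.complex(tr_L^2 - 4 * det_L)
  om1 <- (tr_L + sqrt(disc)) / 2
  om2 <- (tr_L - sqrt(disc)) / 2
  tbl <- tibble::tibble(
    k = k, trace_L = tr_L, det_L = as.numeric(det_L),
    omega1 = om1, omega2 = om2,
    re_max = pmax(Re(om1), Re(om2)),
    stationary = abs(Im(om1)) < 1e-12 & Re(om1) > 0)
  structure(tbl, class = c("dispersion_curve", class(tibble::tibble())),
            params = params, steady_state = c(x = x, m = m),
            jacobian = jac$J)
}

#' Critical long-range distance of the Turing bifurcation
#'
#' Solves simultaneously `Det(L) = 0` and `d Det(L) / d k^2 = 0` for the
#' critical long-range interaction distance `h_T` and wavenumber `k_T`.
#' `Det(L)` is quadratic in `k^2`, so the inner minimization over `k` is
#' closed-form (`k_T^2 = -c1 / (2 c2)`); `h_T` is then the root in `h` of
#' the minimum of `Det(L)`, found by bisection (the minimum decreases
#' monotonically with `h^2` near onset). The critical wavelength is
#' `lambda_T = 2 pi / k_T`. For every `h > h_T` the mixed steady state is
#' unstable to a band of spatial perturbations.
#'
#' @param params Simplified [survival_params()] with `b_M > b_X`; its `h`
#'   field is ignored.
#' @param h_range Bracket for the search.
#' @param tol Bisection tolerance on `h`.
#' @return A list of class `turing_point` with `h_T`, `k_T`, `lambda_T`.
#' @examples
#' turing_threshold(survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1))
#' @export
turing_threshold <- function(params, h_range = c(1, 200), tol = 1e-10) {
  check_simplified(params)
  if (params$b_M <= params$b_X) {
    stop("no physical mixed steady state for b_M <= b_X", call. = FALSE)
  }
  min_detL <- function(h) {
    co <- detL_quadratic(params, h = h)
    if (co["c2"] <= 0) return(-Inf)       # unstable at arbitrarily large k
    if (co["c1"] >= 0) return(co["c0"])   # minimum over k^2 > 0 is at k -> 0
    unname(co["c0"] - co["c1"]^2 / (4 * co["c2"]))
  }
  # below h = sqrt(s / d_M) the cross-diffusion entry D_mx is negative and
  # the quadratic Det(L) loses its positive k^4 coefficient; bracket above
  lo <- max(h_range[1], sqrt(params$s_X / params$d_M) * (1 + 1e-9))
  hi <- h_range[2]
  if (min_detL(lo) <= 0) {
    stop("already Turing-unstable at h = ", lo,
         ": no bifurcation in range", call. = FALSE)
  }
  if (min_detL(hi) > 0) {
    stop("no Turing bifurcation in h range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  while (hi - lo > max(tol, 1e-15 * hi)) {
    mid <- (lo + hi) / 2
    if (min_detL(mid) > 0) lo <- mid else hi <- mid
  }
  h_T <- (lo + hi) / 2
  co <- detL_quadratic(params, h = h_T)
  k_T <- sqrt(-co["c1"] / (2 * co["c2"]))
  structure(list(h_T = h_T, k_T = unname(k_T),
                 lambda_T = unname(2 * pi / k_T)),
            class = "turing_point")
}

#' @export
print.turing_point <- function(x, ...) {
  cat(sprintf("Turing bifurcation: h_T = %.4f, k_T = %.4f, lambda_T = %.4f\n",
              x$h_T, x$k_T, x$lambda_T))
  invisible(x)
}

#' Full linear stability summary at a parameter set
#'
#' Bundles the mixed steady state, reaction Jacobian, homogeneous-stability
#' flags, the Turing threshold `h_T`, and whether the supplied `h` lies
#' above it.
#'
#' @param params Simplified [survival_params()] with `b_M > b_X`.
#' @param h_range Passed to [turing_threshold()].
#' @return An `lsa_result` list; see [tidy.lsa_result()] and
#'   [glance.lsa_result()].
#' @export
linear_stability <- function(params, h_range = c(1, 200)) {
  check_simplified(params)
  ss <- homogeneous_steady_states(params)
  jac <- jacobian_at(params, ss$x[2], ss$m[2])
  thr <- tryCatch(turing_threshold(params, h_range), error = function(e) e)
  structure(list(params = params,
                 steady_state = c(x = ss$x[2], m = ss$m[2]),
                 jacobian = jac$J, trace = jac$trace,
                 determinant = jac$determinant,
                 homogeneous_stable = jac$trace < 0 && jac$determinant > 0,
                 threshold = if (inherits(thr, "turing_point")) thr,
                 turing_unstable = inherits(thr, "turing_point") &&
                   params$h > thr$h_T),
            class = "lsa_result")
}

#' @export
print.lsa_result <- function(x, ...) {
  cat(sprintf("Linear stability at (x, m) = (%.4f, %.4f)\n",
              x$steady_state[1], x$steady_state[2]))
  cat(sprintf("  Tr(J) = %.4f, Det(J) = %.4f (%s to uniform perturbations)\n",
              x$trace, x$determinant,
              if (x$homogeneous_stable) "stable" else "unstable"))
  if (!is.null(x$threshold)) {
    cat(sprintf("  h_T = %.4f, lambda_T = %.4f; h = %d is %s\n",
                x$threshold$h_T, x$threshold$lambda_T, x$params$h,
                if (x$turing_unstable) "Turing-unstable" else "stable"))
  }
  invisible(x)
}

#' Tidy and one-line summaries of a linear stability result
#'
#' @param x An `lsa_result` from [linear_stability()].
#' @param ... Unused.
#' @return `tidy()`: a tibble of the Jacobian entries and eigenvalues;
#'   `glance()`: a one-row tibble with the steady state, trace,
#'   determinant, stability flags and Turing threshold.
#' @export
tidy.lsa_result <- function(x, ...) {
  ev <- eigen(x$jacobian, only.values = TRUE)$values
  tibble::tibble(
    term = c("J_xx", "J_xm", "J_mx", "J_mm", "eigen1", "eigen2"),
    value = c(x$jacobian[1, 1], x$jacobian[1, 2],
              x$jacobian[2, 1], x$jacobian[2, 2],
              Re(ev[1]), Re(ev[2])))
}

#' @rdname tidy.lsa_result
#' @export
glance.lsa_result <- function(x, ...) {
  obj <- x
  tibble::tibble(
    x = unname(obj$steady_state[1]), m = unname(obj$steady_state[2]),
    trace = obj$trace, determinant = obj$determinant,
    homogeneous_stable = obj$homogeneous_stable,
    h = obj$params$h,
    h_T = if (is.null(obj$threshold)) NA_real_ else obj$threshold$h_T,
    k_T = if (is.null(obj$threshold)) NA_real_ else obj$threshold$k_T,
    lambda_T = if (is.null(obj$threshold)) NA_real_
               else obj$threshold$lambda_T,
    turing_unstable = obj$turing_unstable)
}

#' Turing threshold surface over a (b_M, d_M) grid
#'
#' Computes `h_T` and `lambda_T / 2` for every combination of the supplied
#' melanophore birth and death rates, marking as undefined the cells with
#' `b_M <= b_X` (no physical mixed state). The contour where
#' `h_T = lambda_T / 2` is extracted by linear interpolation in `d_M` for
#' each `b_M`; along it the onset distance equals half the emerging
#' wavelength, which coincides with the large-amplitude condition
#' `d_M = b_M s`.
#'
#' @param b_M,d_M Numeric grids of rates.
#' @param b_X,s Fixed rates.
#' @param h_range Passed to [turing_threshold()].
#' @return A tibble with columns `b_M`, `d_M`, `defined`, `h_T`,
#'   `lambda_T_half`; the extracted contour is in attribute
#'   `"equal_contour"` (tibble of `b_M`, `d_M_equal`).
#' @export
threshold_surface <- function(b_M, d_M, b_X = 1, s = 1,
                              h_range = c(1e-3, 200)) {
  grid <- tidyr::expand_grid(b_M = b_M, d_M = d_M)
  res <- purrr::pmap_dfr(grid, function(b_M, d_M) {
    if (b_M <= b_X || d_M <= 0) {
      return(tibble::tibble(defined = FALSE, h_T = NA_real_,
                            lambda_T_half = NA_real_))
    }
    p <- survival_params(b_X = b_X, b_M = b_M, d_M = d_M, s = s, h = 1)
    thr <- tryCatch(turing_threshold(p, h_range), error = function(e) NULL)
    if (is.null(thr)) {
      tibble::tibble(defined = FALSE, h_T = NA_real_,
                     lambda_T_half = NA_real_)
    } else {
      tibble::tibble(defined = TRUE, h_T = thr$h_T,
                     lambda_T = thr$lambda_T,
                     lambda_T_half = thr$lambda_T / 2)
    }
  })
  out <- dplyr::bind_cols(grid, res)
  contour <- out |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$b_M) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$d_M)
      gap <- df$h_T - df$lambda_T_half
      sgn <- sign(gap)
      flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      if (!length(flip)) return(tibble::tibble(d_M_equal = NA_real_))
      i <- flip[1]
      w <- gap[i] / (gap[i] - gap[i + 1])
      tibble::tibble(d_M_equal = df$d_M[i] + w * (df$d_M[i + 1] - df$d_M[i]))
    }) |>
    dplyr::ungroup()
  attr(out, "equal_contour") <- contour
  out
}
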