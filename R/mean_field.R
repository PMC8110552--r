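#' Mean-field occupancy state
#'
#' Deterministic counterpart of the lattice: per-node expected occupancies
#' `x` (xanthophore) and `m` (melanophore) on a periodic 1D ring or 2D
#' grid, with the closure `s = 1 - x - m` holding identically at every node.
#'
#' @param x,m Numeric vectors (1D) or matrices (2D) of equal shape with
#'   `0 <= x`, `0 <= m` and `x + m <= 1` (within `tol`).
#' @param tol Validation tolerance.
#' @return A `mean_field_state`.
#' @export
mean_field_state <- function(x, m, tol = 1e-9) {
  if (!identical(dim(x), dim(m)) || length(x) != length(m)) {
    stop("x and m must have the same shape", call. = FALSE)
  }
  if (any(x < -tol) || any(m < -tol) || any(x + m > 1 + tol)) {
    stop("occupancies must satisfy 0 <= x, m and x + m <= 1", call. = FALSE)
  }
  structure(list(x = pmax(x, 0), m = pmax(m, 0)),
            class = "mean_field_state")
}

#' @export
print.mean_field_state <- function(x, ...) {
  geom <- if (is.matrix(x$x)) paste(dim(x$x), collapse = " x ")
          else paste0("ring of ", length(x$x))
  cat(sprintf("<mean_field_state, %s>  mean x: %.4f  mean m: %.4f\n",
              geom, mean(x$x), mean(x$m)))
  invisible(x)
}

# periodic shift: f_{i+k} (1D) or along a margin (2D)
shift_per <- function(f, k, margin = 1L) {
  if (is.matrix(f)) {
    n <- dim(f)[margin]
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    if (margin == 1L) f[idx, , drop = FALSE] else f[, idx, drop = FALSE]
  } else {
    n <- length(f)
    f[((seq_len(n) - 1 + k) %% n) + 1]
  }
}

# average of the interaction partners at axial range r:
# 1D pair mean (f_{i+r} + f_{i-r})/2; 2D mean over the 4 axial sites,
# the exact expectation of the uniform partner draw in the MC engine.
partner_mean <- function(f, r) {
  if (is.matrix(f)) {
    (shift_per(f, r, 1L) + shift_per(f, -r, 1L) +
       shift_per(f, r, 2L) + shift_per(f, -r, 2L)) / 4
  } else {
    (shift_per(f, r) + shift_per(f, -r)) / 2
  }
}

#' Mean-field time derivatives of the Survival model
#'
#' Right-hand side of the deterministic mean-field equations on a periodic
#' lattice: per node,
#' `dx/dt = b_X s - d_X x - s_M x <m at range 1>` and
#' `dm/dt = b_M s - s_X m <x at range 1> - d_MX m <x at range h>
#'  - d_M m (<s at range h> + <m at range h>)`,
#' where `< >` denotes the average over the interaction partners at the
#' given axial range and `s = 1 - x - m`.
#'
#' @param state A [mean_field_state()].
#' @param params A [survival_params()] object.
#' @return A list with per-node derivative fields `dx` and `dm`.
#' @export
mean_field_rhs <- function(state, params) {
  stopifnot(inherits(state, "mean_field_state"),
            inherits(params, "survival_params"))
  x <- state$x
  m <- state$m
  extent <- if (is.matrix(x)) min(dim(x)) else length(x)
  if (params$h >= extent) {
    stop("h (", params$h, ") must be smaller than the lattice extent (",
         extent, "): the periodic wrap would alias the interaction",
         call. = FALSE)
  }
  s <- 1 - x - m
  dx <- params$b_X * s - params$d_X * x - params$s_M * x * partner_mean(m, 1)
  dm <- params$b_M * s -
    params$s_X * m * partner_mean(x, 1) -
    params$d_MX * m * partner_mean(x, params$h) -
    params$d_M * m * (partner_mean(s, params$h) + partner_mean(m, params$h))
  list(dx = dx, dm = dm)
}

#' Homogeneous steady states of the simplified Survival model
#'
#' In the simplified regime (`d_X = d_MX = 0`, `s_X = s_M = s`) the
#' mean-field equations admit two spatially uniform steady states: the
#' all-xanthophore state `(x, m) = (1, 0)` and a mixed state
#' `x = b_X d_M / (b_X (d_M - s) + b_M s)`,
#' `m = (b_M - b_X) s / (b_X (d_M - s) + (b_M + d_M) s)`.
#' The two exchange stability in a transcritical bifurcation at
#' `b_M = b_X`; the mixed state is physical (and stable to uniform
#' perturbations) for `b_M > b_X`.
#'
#' @param params A [survival_params()] in the simplified regime.
#' @return A tibble with columns `state` (`"SS1"`, `"SS2"`), `x`, `m`.
#' @examples
#' homogeneous_steady_states(
#'   survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 15))
#' @export
homogeneous_steady_states <- function(params) {
  check_simplified(params)
  b_X <- params$b_X; b_M <- params$b_M
  d_M <- params$d_M; s <- params$s_X
  x2 <- b_X * d_M / (b_X * (d_M - s) + b_M * s)
  m2 <- (b_M - b_X) * s / (b_X * (d_M - s) + (b_M + d_M) * s)
  tibble::tibble(state = c("SS1", "SS2"), x = c(1, x2), m = c(0, m2))
}

check_simplified <- function(params) {
  if (!inherits(params, "survival_params") ||
      params$d_X != 0 || params$d_MX != 0 || params$s_X != params$s_M) {
    stop("unsimplified regime: closed forms require d_X = d_MX = 0 and ",
         "s_X = s_M; use numeric root finding for general parameters",
         call. = FALSE)
  }
  invisible(params)
}

#' Perturbed mixed-steady-state initial condition
#'
#' The default initial condition for pattern runs: the mixed homogeneous
#' steady state plus i.i.d. uniform perturbations of the given amplitude on
#' both fields, from a seeded RNG.
#'
#' @param params Simplified [survival_params()].
#' @param geometry Ring length `n` (1D) or `c(n_rows, n_cols)` (2D).
#' @param amplitude Perturbation half-width.
#' @param seed Integer seed.
#' @return A [mean_field_state()].
#' @export
mean_field_init <- function(params, geometry, amplitude = 1e-3, seed = 1L) {
  ss <- homogeneous_steady_states(params)
  n <- prod(geometry)
  set.seed(seed)
  px <- stats::runif(n, -amplitude, amplitude)
  pm <- stats::runif(n, -amplitude, amplitude)
  if (length(geometry) == 2) {
    px <- matrix(px, geometry[1], geometry[2])
    pm <- matrix(pm, geometry[1], geometry[2])
  }
  mean_field_state(pmin(pmax(ss$x[2] + px, 0), 1),
                   pmin(pmax(ss$m[2] + pm, 0), 1))
}

#' Integrate the mean-field equations
#'
#' Adaptive time integration of [mean_field_rhs()] on a periodic 1D or 2D
#' domain. Small systems default to the stiff-capable `lsoda` solver; large
#' 2D systems to `adams` (the equations are non-stiff — interaction terms
#' carry O(1) coefficients, unlike a refined diffusion stencil). Negative
#' occupancies below tolerance are clipped to zero in the output.
#'
#' @param state0 Initial [mean_field_state()].
#' @param params A [survival_params()] object.
#' @param t_end Final time.
#' @param n_out Number of output times (including 0 and `t_end`).
#' @param rtol,atol Solver tolerances.
#' @param method `deSolve` method; default `lsoda` for systems up to 500
#'   unknowns, `adams` above.
#' @return A `mean_field_trajectory`: list with `times`, `states` (list of
#'   `mean_field_state`), and `final`.
#' @examples
#' p <- survival_params(b_X = 1, b_M = 7, d_M = 4, s = 1, h = 10)
#' tr <- mean_field_integrate(mean_field_init(p, 50, seed = 1), p, 200)
#' pattern_amplitude(tr$final$x)
#' @export
mean_field_integrate <- function(state0, params, t_end, n_out = 25,
                                 rtol = 1e-6, atol = 1e-9, method = NULL) {
  stopifnot(inherits(state0, "mean_field_state"), t_end > 0)
  dims <- dim(state0$x)
  n <- length(state0$x)
  if (is.null(method)) method <- if (2 * n > 500) "adams" else "lsoda"
  unpack <- function(y) {
    x <- unname(y[seq_len(n)])
    m <- unname(y[n + seq_len(n)])
    if (!is.null(dims)) { dim(x) <- dims; dim(m) <- dims }
    list(x = x, m = m)
  }
  deriv <- function(t, y, parms) {
    st <- unpack(y)
    d <- mean_field_rhs(structure(st, class = "mean_field_state"), params)
    list(c(as.vector(d$dx), as.vector(d$dm)))
  }
  times <- seq(0, t_end, length.out = max(2, n_out))
  sol <- deSolve::ode(y = c(as.vector(state0$x), as.vector(state0$m)),
                      times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("mean-field integration failed; solver diagnostics:\n",
         paste(utils::capture.output(deSolve::diagnostics(sol)),
               collapse = "\n"), call. = FALSE)
  }
  states <- lapply(seq_len(nrow(sol)), function(i) {
    st <- unpack(sol[i, -1])
    st$x[st$x < 0 & st$x > -10 * atol] <- 0
    st$m[st$m < 0 & st$m > -10 * atol] <- 0
    mean_field_state(st$x, st$m, tol = 1e-6)
  })
  structure(list(times = sol[, 1], states = states,
                 final = states[[length(states)]], params = params),
            class = "mean_field_trajectory")
}

#' @export
print.mean_field_trajectory <- function(x, ...) {
  cat(sprintf("<mean_field_trajectory: %d times in [0, %g]>\n",
              length(x$times), max(x$times)))
  print(x$final)
  invisible(x)
}

#' Long-format view of a mean-field trajectory
#'
#' @param x A `mean_field_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `node` (or `row`/`col`), `x`, `m`.
#' @export
tidy.mean_field_trajectory <- function(x, ...) {
  purrr::map2_dfr(x$times, x$states, function(t, st) {
    if (is.matrix(st$x)) {
      tibble::tibble(time = t,
                     row = as.vector(row(st$x)),
                     col = as.vector(col(st$x)),
                     x = as.vector(st$x), m = as.vector(st$m))
    } else {
      tibble::tibble(time = t, node = seq_along(st$x),
                     x = st$x, m = st$m)
    }
  })
}
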