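#' Lattice cell states
#'
#' Integer codes for the ternary occupancy of a lattice node, matching the
#' CSV export convention: 0 = empty site (S), 1 = xanthophore (X),
#' 2 = melanophore (M).
#'
#' @format A named integer vector.
#' @export
CELL_STATES <- c(S = 0L, X = 1L, M = 2L)

state_code <- function(x) {
  code <- CELL_STATES[[x]]
  if (is.null(code)) stop("unknown cell state: ", x, call. = FALSE)
  code
}

#' Build the stochastic reaction channels of the Survival model
#'
#' Turns a parameter set into the normalized process table consumed by the
#' Monte Carlo engine. Each channel names a focal-state requirement, an
#' optional partner requirement (state at an axial offset of 1 or `h`), and
#' the product written at the focal site. Channel probabilities are the rate
#' constants divided by the sum of all rate constants; zero-weight channels
#' are retained with probability 0 so that channel ordering (and hence the
#' stream of random draws) is stable across parameter sets.
#'
#' The Survival model has exactly 8 channels. There is no simple
#' (partner-free) melanophore death: melanophore death is split into three
#' long-range channels at range `h` — partner M or partner S at rate `d_M`,
#' partner X at rate `d_MX` — so that remote xanthophores protect
#' melanophores from dying.
#'
#' @param params A [survival_params()] object.
#' @return A tibble of class `process_table` with columns `channel`, `rate`,
#'   `focal`, `partner_state`, `partner_range`, `product`, `prob`.
#' @examples
#' build_survival_processes(survival_params(b_X = 1, b_M = 7, d_M = 9,
#'                                          s = 1, h = 15))
#' @export
build_survival_processes <- function(params) {
  stopifnot(inherits(params, "survival_params"))
  p <- params
  tbl <- tibble::tibble(
    channel = c("birth_X", "birth_M", "death_X", "comp_X_by_M", "comp_M_by_X",
                "death_M_remote_M", "death_M_remote_S", "death_M_remote_X"),
    rate = c(p$b_X, p$b_M, p$d_X, p$s_M, p$s_X, p$d_M, p$d_M, p$d_MX),
    focal = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L),
    partner_state = c(NA, NA, NA, 2L, 1L, 2L, 0L, 1L),
    partner_range = c(NA, NA, NA, 1L, 1L, p$h, p$h, p$h),
    product = c(1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L)
  )
  new_process_table(tbl, model = "survival", params = params)
}

#' Build the stochastic reaction channels of the Promotion model
#'
#' The Promotion model has 7 channels: simple birth of X and M, simple death
#' of X and M, mutual short-range competition at range 1, and long-range
#' promotion of melanophore birth by a xanthophore at range `h` (rate `l_X`).
#'
#' @param params A [promotion_params()] object.
#' @inherit build_survival_processes return
#' @examples
#' build_promotion_processes(promotion_params(b_X = 1, s = 1, l_X = 2.5,
#'                                            h = 16))
#' @export
build_promotion_processes <- function(params) {
  stopifnot(inherits(params, "promotion_params"))
  p <- params
  tbl <- tibble::tibble(
    channel = c("birth_X", "birth_M", "death_X", "death_M",
                "comp_X_by_M", "comp_M_by_X", "promo_M_by_remote_X"),
    rate = c(p$b_X, p$b_M, p$d_X, p$d_M, p$s_M, p$s_X, p$l_X),
    focal = c(0L, 0L, 1L, 2L, 1L, 2L, 0L),
    partner_state = c(NA, NA, NA, NA, 2L, 1L, 1L),
    partner_range = c(NA, NA, NA, NA, 1L, 1L, p$h),
    product = c(1L, 2L, 0L, 0L, 0L, 0L, 2L)
  )
  new_process_table(tbl, model = "promotion", params = params)
}

new_process_table <- function(tbl, model, params) {
  total <- sum(tbl$rate)
  if (total <= 0) {
    stop("all rate constants are zero: no process can ever occur",
         call. = FALSE)
  }
  tbl$prob <- tbl$rate / total
  structure(tbl,
            class = c("process_table", class(tibble::tibble())),
            model = model, params = params)
}

#' @export
print.process_table <- function(x, ...) {
  cat("Process table (", attr(x, "model"), " model), ",
      nrow(x), " channels\n", sep = "")
  NextMethod()
}
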