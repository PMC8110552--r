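#' Single Monte Carlo event attempt
#'
#' Performs one iteration of the rejection kinetic Monte Carlo algorithm:
#' a focal site is drawn uniformly, a channel is drawn with its table
#' probability, and the channel fires only when the focal state (and, for
#' interaction channels, the state of a partner site sampled at the
#' channel's range) matches its requirements. At most one cell changes.
#' Uses the current R RNG state; call `set.seed()` for reproducibility.
#'
#' @param lattice A `lattice`.
#' @param table A `process_table`.
#' @param partner_geometry Long-range partner geometry, see [run_static()].
#' @return A list with elements `lattice` (possibly updated) and `changed`
#'   (logical).
#' @export
mc_step <- function(lattice, table, partner_geometry = "euclidean") {
  res <- mc_chunk(lattice, table, 1, partner_geometry)
  list(lattice = as_lattice(res$grid), changed = res$changed > 0)
}

geometry_code <- function(partner_geometry) {
  match(match.arg(partner_geometry, c("axial", "euclidean", "chebyshev")),
        c("axial", "euclidean", "chebyshev")) - 1L
}

mc_chunk <- function(grid, table, n_iter, partner_geometry = "euclidean") {
  mc_run_cpp(grid,
             as.integer(table$focal),
             as.integer(table$partner_state),
             as.integer(table$partner_range),
             as.integer(table$product),
             cumsum(table$prob),
             n_iter,
             geometry_code(partner_geometry))
}

#' Run the stochastic lattice model on a static domain
#'
#' Applies [mc_step()] dynamics for `n_iterations` event attempts on a fixed
#' periodic lattice, recording snapshots every `snapshot_every` iterations
#' plus the initial and final states. The run is bit-reproducible from
#' `seed`.
#'
#' @param lattice Initial `lattice` (see [init_lattice()]).
#' @param table A `process_table`.
#' @param n_iterations Number of event attempts (may exceed 2^31).
#' @param snapshot_every Snapshot cadence in iterations.
#' @param seed Integer seed.
#' @param partner_geometry Geometry of the long-range (range > 1) partner
#'   draw. `"euclidean"` (default) picks a site at Euclidean distance `h`
#'   (uniform angle, rounded): its isotropic ring kernel yields 2D patterns
#'   of wavelength ~`1.7 h` and reproduces the growth-orientation threshold
#'   (only wavelengths above a critical size align with a growing
#'   boundary). `"chebyshev"` picks uniformly on the square ring of sites
#'   at Chebyshev distance `h`, preserving the one-dimensional `+/-h`
#'   wavelength selection along each axis (2D wavelength ~`2 h`, but all
#'   wavelengths align under growth). `"axial"` uses the 4 sites at offset
#'   `+/-h` along a row or column, the literal 2D extension of the 1D
#'   rules; it favors diagonal modes of wavelength ~`sqrt(2) h`.
#'   Nearest-neighbor (range 1) partners are always the 4 axial
#'   neighbors.
#' @return A `simulation_record`: list with `model`, `params`, `seed`,
#'   `snapshots` (tibble of `iteration` and `lattice` list-column) and
#'   `final` lattice.
#' @examples
#' tbl <- build_survival_processes(
#'   survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 5))
#' rec <- run_static(init_lattice(40, 40), tbl, 2e5, seed = 1)
#' tidy(rec)
#' @export
run_static <- function(lattice, table, n_iterations,
                       snapshot_every = 1e7, seed = 1L,
                       partner_geometry = "euclidean") {
  stopifnot(n_iterations >= 0)
  set.seed(seed)
  snaps <- list(lattice)
  iters <- numeric(1)
  done <- 0
  grid <- lattice
  while (done < n_iterations) {
    step <- min(snapshot_every, n_iterations - done)
    res <- mc_chunk(grid, table, step, partner_geometry)
    grid <- as_lattice(res$grid)
    done <- done + step
    snaps <- c(snaps, list(grid))
    iters <- c(iters, done)
  }
  rec <- new_simulation_record(table, seed, iters, snaps, grid)
  rec$partner_geometry <- partner_geometry
  rec
}

new_simulation_record <- function(table, seed, iterations, snapshots, final,
                                  phase = NULL) {
  snap_tbl <- tibble::tibble(
    iteration = iterations,
    n_rows = vapply(snapshots, nrow, 0L),
    n_cols = vapply(snapshots, ncol, 0L),
    lattice = snapshots
  )
  if (!is.null(phase)) snap_tbl$phase <- phase
  structure(list(model = attr(table, "model"),
                 params = attr(table, "params"),
                 seed = seed,
                 snapshots = snap_tbl,
                 final = final),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf(
    "<simulation_record: %s model, seed %s, %d snapshots, final %d x %d>\n",
    x$model, format(x$seed), nrow(x$snapshots),
    nrow(x$final), ncol(x$final)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-snapshot occupancy summary of a simulation record
#'
#' @param x A `simulation_record`.
#' @param ... Unused.
#' @return A tibble with one row per snapshot: `iteration`, dimensions, and
#'   the fractions of empty sites, xanthophores and melanophores.
#' @export
tidy.simulation_record <- function(x, ...) {
  fr <- purrr::map(x$snapshots$lattice, occupancy_fractions)
  dplyr::bind_cols(
    x$snapshots[setdiff(names(x$snapshots), "lattice")],
    dplyr::bind_rows(fr))
}

#' @rdname tidy.simulation_record
#' @export
glance.simulation_record <- function(x, ...) {
  fr <- occupancy_fractions(x$final)
  tibble::tibble(model = x$model, seed = x$seed,
                 iterations = max(x$snapshots$iteration),
                 n_rows = nrow(x$final), n_cols = ncol(x$final),
                 frac_S = fr$frac_S, frac_X = fr$frac_X, frac_M = fr$frac_M)
}

occupancy_fractions <- function(lattice) {
  counts <- tabulate(as.integer(lattice) + 1L, nbins = 3L)
  n <- length(lattice)
  tibble::tibble(frac_S = counts[1] / n, frac_X = counts[2] / n,
                 frac_M = counts[3] / n)
}

#' Specify stepwise domain growth
#'
#' Growth enlarges the lattice by appending one column of sites at the
#' growing (right) boundary every `iterations_per_growth` event attempts,
#' until `target_cols` columns are reached. Optionally rows are added too
#' (trapezoidal growth), interleaved evenly across the column-growth events.
#'
#' @param target_cols Final number of columns.
#' @param iterations_per_growth Event attempts between growth events.
#' @param fill_mode `"empty"` (new sites empty) or `"copy"` (duplicate the
#'   boundary line).
#' @param pre_growth_iterations Attempts before the first growth event.
#' @param post_growth_iterations Attempts after growth completes; default
#'   is 17% of the growth-phase iterations.
#' @param target_rows Optional final number of rows (trapezoidal growth).
#' @return A `growth_schedule` list.
#' @export
growth_schedule <- function(target_cols, iterations_per_growth = 1e7,
                            fill_mode = "empty",
                            pre_growth_iterations = 0,
                            post_growth_iterations = NULL,
                            target_rows = NULL) {
  stopifnot(target_cols >= 1, iterations_per_growth >= 1,
            pre_growth_iterations >= 0)
  fill_mode <- match.arg(fill_mode, c("empty", "copy"))
  structure(list(target_cols = target_cols,
                 iterations_per_growth = iterations_per_growth,
                 fill_mode = fill_mode,
                 pre_growth_iterations = pre_growth_iterations,
                 post_growth_iterations = post_growth_iterations,
                 target_rows = target_rows),
            class = "growth_schedule")
}

#' Run the stochastic lattice model on a growing domain
#'
#' Runs `pre_growth_iterations` attempts, then alternates
#' `iterations_per_growth` attempts with one growth event until the target
#' size is reached, then runs the post-growth phase on the final static
#' domain. If `ablation` is given, the central block is emptied once, after
#' the growth event closest to the requested fraction of total growth.
#' Snapshots are taken at phase boundaries and (approximately) every
#' `snapshot_every` iterations, aligned to growth events.
#'
#' @param lattice Initial `lattice` (e.g. `init_lattice(300, 1)`).
#' @param table A `process_table`.
#' @param schedule A [growth_schedule()].
#' @param ablation Optional [ablation_spec()].
#' @param seed Integer seed.
#' @param snapshot_every Snapshot cadence in iterations (default: ~10
#'   snapshots over the growth phase).
#' @param partner_geometry Long-range partner geometry, see [run_static()].
#' @return A `simulation_record` whose snapshot tibble carries a `phase`
#'   column (`initial`, `growth`, `ablation`, `post_growth`, `final`).
#' @export
run_growing <- function(lattice, table, schedule, ablation = NULL,
                        seed = 1L, snapshot_every = NULL,
                        partner_geometry = "euclidean") {
  stopifnot(inherits(schedule, "growth_schedule"))
  n_events <- schedule$target_cols - ncol(lattice)
  if (n_events < 0) stop("target_cols smaller than the initial lattice",
                         call. = FALSE)
  growth_iters <- n_events * schedule$iterations_per_growth
  post <- schedule$post_growth_iterations
  if (is.null(post)) post <- ceiling(0.17 * growth_iters)
  if (is.null(snapshot_every)) {
    snapshot_every <- max(1, ceiling(growth_iters / 10))
  }
  row_add_at <- integer(0)
  if (!is.null(schedule$target_rows)) {
    n_rows_add <- schedule$target_rows - nrow(lattice)
    stopifnot(n_rows_add >= 0)
    if (n_rows_add > 0) {
      row_add_at <- unique(round(seq(1, max(n_events, 1),
                                     length.out = n_rows_add)))
    }
  }
  ablate_after <- if (!is.null(ablation)) round(ablation$trigger * n_events)

  set.seed(seed)
  grid <- lattice
  snaps <- list(grid)
  iters <- 0
  phases <- "initial"
  done <- 0
  take <- function(grid, it, phase) {
    snaps[[length(snaps) + 1L]] <<- grid
    iters[length(iters) + 1L] <<- it
    phases[length(phases) + 1L] <<- phase
  }

  if (schedule$pre_growth_iterations > 0) {
    res <- mc_chunk(grid, table, schedule$pre_growth_iterations,
                    partner_geometry)
    grid <- as_lattice(res$grid)
    done <- done + schedule$pre_growth_iterations
  }
  if (!is.null(ablate_after) && ablate_after == 0) {
    grid <- apply_ablation(grid, ablation)
    take(grid, done, "ablation")
  }
  last_snap <- 0
  for (ev in seq_len(n_events)) {
    res <- mc_chunk(grid, table, schedule$iterations_per_growth,
                    partner_geometry)
    done <- done + schedule$iterations_per_growth
    grid <- apply_growth(as_lattice(res$grid), schedule$fill_mode, "col")
    if (ev %in% row_add_at) {
      grid <- apply_growth(grid, schedule$fill_mode, "row")
    }
    if (!is.null(ablate_after) && ev == ablate_after) {
      take(grid, done, "growth")
      grid <- apply_ablation(grid, ablation)
      take(grid, done, "ablation")
      last_snap <- done
    } else if (done - last_snap >= snapshot_every || ev == n_events) {
      take(grid, done, "growth")
      last_snap <- done
    }
  }
  if (post > 0) {
    res <- mc_chunk(grid, table, post, partner_geometry)
    grid <- as_lattice(res$grid)
    done <- done + post
    take(grid, done, "post_growth")
  }
  rec <- new_simulation_record(table, seed, iters, snaps, grid,
                               phase = phases)
  rec$schedule <- schedule
  rec$ablation <- ablation
  rec$partner_geometry <- partner_geometry
  rec
}
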