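#' Create a lattice of pigment cells
#'
#' A lattice is an integer matrix of cell-state codes (0 = empty S,
#' 1 = xanthophore X, 2 = melanophore M) with periodic boundaries in both
#' axes and class `"lattice"`. Coordinates are `(row, col)`, 1-based in R.
#'
#' @param n_rows,n_cols Dimensions, each at least 1.
#' @param init_mode One of `"empty"`, `"random"` (i.i.d. uniform over the
#'   three states), `"all_X"`, `"all_M"`.
#' @param seed Optional integer seed used for `init_mode = "random"`.
#' @return A `lattice` object.
#' @examples
#' init_lattice(50, 50)
#' init_lattice(20, 20, "random", seed = 1)
#' @export
init_lattice <- function(n_rows, n_cols, init_mode = "empty", seed = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  init_mode <- match.arg(init_mode, c("empty", "random", "all_X", "all_M"))
  grid <- switch(init_mode,
    empty = matrix(0L, n_rows, n_cols),
    all_X = matrix(1L, n_rows, n_cols),
    all_M = matrix(2L, n_rows, n_cols),
    random = {
      if (!is.null(seed)) set.seed(seed)
      matrix(sample(0:2, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
    })
  as_lattice(grid)
}

#' Coerce an integer matrix of state codes to a lattice
#'
#' @param grid Integer matrix with entries in `{0, 1, 2}`.
#' @return A `lattice` object.
#' @export
as_lattice <- function(grid) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  bad <- which(!(grid %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(grid))
    stop("invalid cell state code ", grid[bad[1]], " at row ", rc[1],
         ", col ", rc[2], " (codes must be 0, 1 or 2)", call. = FALSE)
  }
  structure(grid, class = c("lattice", "matrix", "array"))
}

#' @export
print.lattice <- function(x, ...) {
  counts <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf("<lattice %d x %d, periodic>  S: %d  X: %d  M: %d\n",
              nrow(x), ncol(x), counts[1], counts[2], counts[3]))
  invisible(x)
}

#' Sample an interaction partner site
#'
#' Partner geometry is axial: the partner of `site` at range `r` is one of
#' the 4 sites at offset `+/-r` along the row or column axis, chosen
#' uniformly, with periodic wrap-around. This is the 2D extension of the
#' one-dimensional `i +/- h` interaction used by the models.
#'
#' @param lattice A `lattice` (only its dimensions matter).
#' @param site Integer `c(row, col)`, 1-based.
#' @param range_r Interaction range, a positive integer.
#' @return Integer `c(row, col)` of the sampled partner.
#' @export
sample_partner <- function(lattice, site, range_r) {
  stopifnot(range_r >= 1)
  nr <- nrow(lattice)
  nc <- ncol(lattice)
  dir <- floor(stats::runif(1) * 4)
  r <- site[1]
  c <- site[2]
  wrap1 <- function(i, n) ((i - 1) %% n) + 1L
  switch(as.character(dir),
         "0" = c(wrap1(r - range_r, nr), c),
         "1" = c(wrap1(r + range_r, nr), c),
         "2" = c(r, wrap1(c - range_r, nc)),
         c(r, wrap1(c + range_r, nc)))
}

#' Grow the domain by one column (or row)
#'
#' Appends one column on the right (the growing boundary). The new column is
#' all empty sites (`fill_mode = "empty"`, the default used throughout) or a
#' copy of the previously last column (`"copy"`). With periodic boundaries
#' the choice of side is immaterial up to relabeling. `axis = "row"` appends
#' a row at the bottom instead (trapezoidal growth).
#'
#' @param lattice A `lattice`.
#' @param fill_mode `"empty"` or `"copy"`.
#' @param axis `"col"` (default) or `"row"`.
#' @return The enlarged `lattice`.
#' @export
apply_growth <- function(lattice, fill_mode = "empty", axis = "col") {
  fill_mode <- match.arg(fill_mode, c("empty", "copy"))
  axis <- match.arg(axis, c("col", "row"))
  if (axis == "col") {
    new <- if (fill_mode == "empty") integer(nrow(lattice))
           else lattice[, ncol(lattice)]
    as_lattice(cbind(unclass(lattice), new, deparse.level = 0))
  } else {
    new <- if (fill_mode == "empty") integer(ncol(lattice))
           else lattice[nrow(lattice), ]
    as_lattice(rbind(unclass(lattice), new, deparse.level = 0))
  }
}

#' Specify in-silico ablation
#'
#' Ablation empties a centered rectangular block spanning
#' `floor(row_fraction * n_rows)` middle rows by
#' `floor(col_fraction * n_cols)` middle columns, the lattice analogue of
#' laser ablation of a patch of skin.
#'
#' @param trigger When to ablate, as a fraction of total growth completed in
#'   `[0, 1]` (1 = immediately after the last growth event).
#' @param row_fraction,col_fraction Fractions of rows/columns to empty, in
#'   `(0, 1]`.
#' @return An `ablation_spec` list.
#' @export
ablation_spec <- function(trigger = 0.5, row_fraction = 0.75,
                          col_fraction = 0.75) {
  stopifnot(trigger >= 0, trigger <= 1,
            row_fraction > 0, row_fraction <= 1,
            col_fraction > 0, col_fraction <= 1)
  structure(list(trigger = trigger, row_fraction = row_fraction,
                 col_fraction = col_fraction), class = "ablation_spec")
}

#' Ablate the center of a lattice
#'
#' Sets the central block defined by `spec` to empty sites. Block sizes are
#' `floor(fraction * extent)` and the block is centered by floor division:
#' offset `floor((extent - block) / 2)` from the first row/column.
#'
#' @param lattice A `lattice`.
#' @param spec An [ablation_spec()].
#' @return The ablated `lattice`.
#' @examples
#' apply_ablation(init_lattice(8, 8, "all_M"), ablation_spec())
#' @export
apply_ablation <- function(lattice, spec) {
  stopifnot(inherits(spec, "ablation_spec"))
  nr <- nrow(lattice)
  nc <- ncol(lattice)
  br <- floor(spec$row_fraction * nr)
  bc <- floor(spec$col_fraction * nc)
  r0 <- floor((nr - br) / 2)
  c0 <- floor((nc - bc) / 2)
  if (br >= 1 && bc >= 1) {
    lattice[(r0 + 1):(r0 + br), (c0 + 1):(c0 + bc)] <- 0L
  }
  lattice
}
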