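#' Read and write lattice snapshots as CSV
#'
#' The snapshot dialect is a plain comma-separated integer matrix, one
#' lattice row per line, codes 0 (S), 1 (X), 2 (M), LF newlines, no header
#' and no trailing separators. Reading validates every code and names the
#' offending row/column on failure, so `read_snapshot(write_snapshot(x))`
#' is the identity.
#'
#' @param lattice A `lattice`.
#' @param path File path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `lattice`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_snapshot(init_lattice(5, 5, "random", seed = 1), p)
#' read_snapshot(p)
#' @export
write_snapshot <- function(lattice, path) {
  lines <- apply(unclass(lattice), 1, paste, collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  grid <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(grid) <- NULL
  if (!is.numeric(grid) || any(is.na(grid)) ||
      any(grid != round(grid))) {
    bad <- which(is.na(grid) | grid != round(grid))[1]
    rc <- arrayInd(bad, dim(grid))
    stop("malformed snapshot: non-integer entry at row ", rc[1],
         ", col ", rc[2], call. = FALSE)
  }
  as_lattice(grid)
}

#' Render a lattice to an RGB image
#'
#' Colors follow the fixed convention: xanthophores yellow, melanophores
#' black, empty sites white, and (for growth animations) the not-yet-grown
#' margin of the final canvas royal blue. One pixel per lattice node.
#'
#' @param lattice A `lattice`.
#' @param final_size Canvas size `c(rows, cols)`, at least the current
#'   lattice size; defaults to the lattice itself.
#' @param path Optional PNG output path.
#' @return The RGB array (rows x cols x 3), invisibly when `path` is given.
#' @export
render_frame <- function(lattice, final_size = dim(lattice), path = NULL) {
  stopifnot(all(final_size >= dim(lattice)))
  cols <- list(S = c(1, 1, 1), X = c(1, 1, 0), M = c(0, 0, 0),
               margin = c(65, 105, 225) / 255)
  img <- array(0, c(final_size[1], final_size[2], 3))
  for (ch in 1:3) img[, , ch] <- cols$margin[ch]
  nr <- nrow(lattice); nc <- ncol(lattice)
  code <- unclass(lattice) + 1L
  pal <- rbind(cols$S, cols$X, cols$M)
  for (ch in 1:3) {
    img[seq_len(nr), seq_len(nc), ch] <- matrix(pal[code, ch], nr, nc)
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}

#' Render a simulation record as an ordered frame sequence
#'
#' Writes one PNG per stored snapshot, all on the canvas of the final
#' (largest) lattice so that growth appears as a shrinking blue margin,
#' numbered in iteration order for assembly into an animation.
#'
#' @param record A `simulation_record` with at least 2 snapshots.
#' @param dir Output directory (created if needed).
#' @param prefix Frame filename prefix.
#' @return Paths of the written frames, invisibly.
#' @export
render_animation <- function(record, dir, prefix = "frame") {
  n <- nrow(record$snapshots)
  if (n < 2) stop("record needs at least 2 snapshots", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  final_size <- dim(record$final)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    render_frame(record$snapshots$lattice[[i]], final_size, paths[i])
  }
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a lattice with the standard color convention
#'
#' @param object A `lattice`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lattice <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object)),
    col = as.vector(col(object)),
    state = factor(as.vector(unclass(object)), levels = 0:2,
                   labels = c("S", "X", "M")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(S = "white", X = "gold", M = "black"), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a mean-field state
#'
#' 2D states are shown as a raster of the chosen field; 1D states as
#' occupancy profiles of both fields along the ring.
#'
#' @param object A `mean_field_state`.
#' @param field `"x"` or `"m"` (2D only).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mean_field_state <- function(object, field = "x", ...) {
  if (is.matrix(object$x)) {
    f <- object[[field]]
    df <- tibble::tibble(row = as.vector(row(f)), col = as.vector(col(f)),
                         value = as.vector(f))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "gold",
                                   name = field) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_equal() +
      ggplot2::theme_void()
  } else {
    df <- tibble::tibble(node = seq_along(object$x),
                         x = object$x, m = object$m) |>
      tidyr::pivot_longer(c("x", "m"), names_to = "species")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$value,
                                     colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "occupancy")
  }
}

#' Plot a dispersion curve
#'
#' Real parts of the two eigenvalues against wavenumber; the band where
#' the leading eigenvalue is positive is the Turing-unstable band.
#'
#' @param object A `dispersion_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dispersion_curve <- function(object, ...) {
  df <- tibble::tibble(k = object$k,
                       omega1 = Re(object$omega1),
                       omega2 = Re(object$omega2)) |>
    tidyr::pivot_longer(c("omega1", "omega2"), names_to = "branch",
                        values_to = "re_omega")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$re_omega,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "wavenumber k", y = "Re(omega)")
}

#' @export
autoplot.simulation_record <- function(object, ...) {
  autoplot.lattice(object$final, ...)
}
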