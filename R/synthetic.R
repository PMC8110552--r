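#' Synthetic test fields
#'
#' Deterministic generators of reference fields for the spectral metrics:
#' single-mode stripes at a given angle, a hexagonal lattice of spots
#' (sum of three plane waves 60 degrees apart), or seeded i.i.d. noise.
#'
#' @param kind `"stripes"`, `"spots"` or `"noise"`.
#' @param wavelength Spatial period in lattice units; must be smaller than
#'   half the smallest field dimension (ignored for `"noise"`).
#' @param angle Direction of the wavevector in degrees from the column
#'   (horizontal) axis: `angle = 0` gives stripes that run vertically,
#'   `angle = 90` stripes that run horizontally.
#' @param size Field size, a scalar or `c(n_rows, n_cols)`.
#' @param seed Seed for `"noise"`.
#' @return A numeric matrix.
#' @examples
#' classify_pattern(make_synthetic_field("spots", 20, size = 120))
#' @export
make_synthetic_field <- function(kind, wavelength = NULL, angle = 0,
                                 size = 100, seed = 1L) {
  kind <- match.arg(kind, c("stripes", "spots", "noise"))
  if (length(size) == 1) size <- c(size, size)
  if (kind != "noise") {
    if (is.null(wavelength) || wavelength >= min(size) / 2) {
      stop("wavelength must be given and smaller than half the field size",
           call. = FALSE)
    }
  }
  rr <- matrix(seq_len(size[1]) - 1, size[1], size[2])
  cc <- matrix(seq_len(size[2]) - 1, size[1], size[2], byrow = TRUE)
  k <- 2 * pi / wavelength[1]
  plane <- function(deg) {
    a <- deg * pi / 180
    cos(k * (cos(a) * cc + sin(a) * rr))
  }
  switch(kind,
    stripes = plane(angle),
    spots = plane(angle) + plane(angle + 60) + plane(angle + 120),
    noise = {
      set.seed(seed)
      matrix(stats::runif(prod(size), -1, 1), size[1], size[2])
    })
}
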