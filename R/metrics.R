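#' Smoothed melanophore indicator field of a lattice
#'
#' Stripes in these models are defined by the melanophores, so spectral
#' metrics operate on the melanophore indicator (1 where the site holds an
#' M, 0 elsewhere) box-smoothed with a periodic moving average. The
#' conversion is deterministic.
#'
#' @param lattice A `lattice`.
#' @param smooth_width Odd box width of the periodic moving average.
#' @return A numeric matrix in `[0, 1]`.
#' @export
melanophore_field <- function(lattice, smooth_width = 3) {
  stopifnot(smooth_width >= 1, smooth_width %% 2 == 1)
  f <- (unclass(lattice) == 2L) * 1
  if (smooth_width == 1) return(f)
  half <- (smooth_width - 1) / 2
  acc <- 0
  for (dr in -half:half) acc <- acc + shift_per(f, dr, 1L)
  f <- acc / smooth_width
  acc <- 0
  for (dc in -half:half) acc <- acc + shift_per(f, dc, 2L)
  acc / smooth_width
}

as_field <- function(field) {
  if (inherits(field, "lattice")) melanophore_field(field)
  else as.matrix(field)
}

# 2D power spectrum with radial ring binning. Ring q holds Fourier
# components with |k| ~ q cycles per L pixels, L = min(nrow, ncol), so a
# single mode of wavelength lambda lands in ring q = L / lambda.
power_rings <- function(field) {
  f <- field - mean(field)
  P <- Mod(stats::fft(f))^2
  nr <- nrow(f); nc <- ncol(f)
  fy <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fx <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  kr <- sqrt(outer(fy^2, fx^2, `+`))
  L <- min(nr, nc)
  q <- round(kr * L)
  keep <- q >= 1 & kr <= 0.5
  rings <- tibble::tibble(q = q[keep], power = P[keep]) |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(power = mean(.data$power), n = dplyr::n()) |>
    dplyr::mutate(k = 2 * pi * .data$q / L, wavelength = L / .data$q)
  list(rings = rings, P = P, fy = fy, fx = fx, q = q, L = L)
}

#' Dominant pattern wavelength from the radial power spectrum
#'
#' Subtracts the field mean, computes the 2D discrete Fourier power
#' spectrum, radially averages it over rings of wavenumber magnitude, and
#' returns the wavelength of the peak ring. The peak is flagged
#' insignificant when its power is below `min_significance` times the
#' median ring power (flat spectrum); the wavelength is then undefined.
#' A `lattice` input is first converted with [melanophore_field()].
#'
#' @param field A 2D numeric field or a `lattice`.
#' @param min_significance Peak-to-median power ratio required.
#' @return A list with `wavelength` (lattice units; `NA` when not
#'   significant), `significant`, `peak_power`, `median_power`, and the
#'   ring `spectrum` tibble.
#' @examples
#' f <- make_synthetic_field("stripes", wavelength = 30, size = 120)
#' dominant_wavelength(f)$wavelength
#' @export
dominant_wavelength <- function(field, min_significance = 5) {
  field <- as_field(field)
  if (stats::sd(field) == 0) {
    return(list(wavelength = NA_real_, significant = FALSE,
                peak_power = NA_real_, median_power = NA_real_,
                spectrum = NULL))
  }
  pr <- power_rings(field)
  rings <- pr$rings
  i <- which.max(rings$power)
  med <- stats::median(rings$power)
  significant <- rings$power[i] >= min_significance * med
  list(wavelength = if (significant) rings$wavelength[i] else NA_real_,
       significant = significant,
       peak_power = rings$power[i], median_power = med,
       spectrum = rings)
}

#' Stripe orientation relative to the growth axis
#'
#' Spectral anisotropy index in `[-1, 1]`:
#' `(P_perp - P_par) / (P_perp + P_par)`, where `P_par` is the total
#' spectral power with wavevector within `half_width_deg` of the growth
#' axis and `P_perp` the power within `half_width_deg` of its normal
#' (zero frequency excluded). Stripes running parallel to the growth axis
#' — i.e. perpendicular to the moving boundary — vary only across the
#' axis, so their wavevector is normal to it and the index approaches +1;
#' stripes parallel to the boundary give -1; isotropic patterns give ~0.
#'
#' @param field A 2D numeric field or a `lattice` (non-constant).
#' @param growth_axis `"col"` if growth appends columns (the default used
#'   by [run_growing()]), `"row"` otherwise.
#' @param half_width_deg Angular half-width of each wedge.
#' @return A number in `[-1, 1]`.
#' @export
orientation_index <- function(field, growth_axis = "col",
                              half_width_deg = 22.5) {
  growth_axis <- match.arg(growth_axis, c("col", "row"))
  field <- as_field(field)
  if (stats::sd(field) == 0) {
    stop("orientation is undefined for a constant field", call. = FALSE)
  }
  f <- field - mean(field)
  P <- Mod(stats::fft(f))^2
  nr <- nrow(f); nc <- ncol(f)
  fy <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fx <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  ky <- matrix(fy, nr, nc)
  kx <- matrix(fx, nr, nc, byrow = TRUE)
  keep <- !(ky == 0 & kx == 0)
  # angle between the wavevector and the horizontal (column) axis, folded
  # to [0, 90] degrees
  ang <- atan2(abs(ky), abs(kx)) * 180 / pi
  to_col_axis <- ang
  to_row_axis <- 90 - ang
  P_col <- sum(P[keep & to_col_axis <= half_width_deg])
  P_row <- sum(P[keep & to_row_axis <= half_width_deg])
  if (growth_axis == "col") {
    (P_row - P_col) / (P_row + P_col)
  } else {
    (P_col - P_row) / (P_col + P_row)
  }
}

#' Pattern amplitude
#'
#' Range (max minus min) of the analyzed field; separates large-amplitude
#' from small-amplitude Turing patterns. A `lattice` input is converted
#' with [melanophore_field()].
#'
#' @param field A 2D numeric field or a `lattice`.
#' @return `max(field) - min(field)`.
#' @export
pattern_amplitude <- function(field) {
  field <- as_field(field)
  max(field) - min(field)
}

#' Coarse pattern classification
#'
#' `homogeneous` when the amplitude is below `amp_threshold`; otherwise the
#' angular distribution of spectral power on the dominant ring decides:
#' a strongly bimodal distribution (doubled-angle resultant length
#' `R2 >= stripe_threshold`) is `stripes`, an approximately isotropic one
#' (`R2 <= spot_threshold`, e.g. the six-fold ring of a hexagonal spot
#' lattice) is `spots`, anything else — including fields with no
#' significant spectral peak — is `irregular`.
#'
#' @param field A 2D numeric field or a `lattice`.
#' @param amp_threshold Amplitude below which the field is homogeneous.
#' @param stripe_threshold,spot_threshold Doubled-angle resultant cutoffs.
#' @return One of `"homogeneous"`, `"stripes"`, `"spots"`, `"irregular"`.
#' @export
classify_pattern <- function(field, amp_threshold = 0.05,
                             stripe_threshold = 0.7, spot_threshold = 0.35) {
  field <- as_field(field)
  if (pattern_amplitude(field) < amp_threshold) return("homogeneous")
  dw <- dominant_wavelength(field)
  if (!dw$significant) return("irregular")
  pr <- power_rings(field)
  q_peak <- pr$L / dw$wavelength
  nr <- nrow(field); nc <- ncol(field)
  ky <- matrix(pr$fy, nr, nc)
  kx <- matrix(pr$fx, nr, nc, byrow = TRUE)
  on_ring <- abs(pr$q - q_peak) <= 1 & pr$q >= 1
  P <- pr$P[on_ring]
  theta <- atan2(ky[on_ring], kx[on_ring])
  R2 <- Mod(sum(P * exp(2i * theta))) / sum(P)
  if (R2 >= stripe_threshold) "stripes"
  else if (R2 <= spot_threshold) "spots"
  else "irregular"
}

#' Pattern metrics for every snapshot of a simulation record
#'
#' Applies [dominant_wavelength()], [orientation_index()],
#' [pattern_amplitude()] and [classify_pattern()] to the melanophore field
#' of each stored snapshot.
#'
#' @param record A `simulation_record`.
#' @param growth_axis Passed to [orientation_index()].
#' @return A tibble with one row per snapshot: `iteration`, `wavelength`,
#'   `significant`, `orientation`, `amplitude`, `class`.
#' @export
analyze_snapshots <- function(record, growth_axis = "col") {
  purrr::map2_dfr(record$snapshots$iteration, record$snapshots$lattice,
                  function(it, lat) {
    f <- melanophore_field(lat)
    dw <- dominant_wavelength(f)
    ori <- tryCatch(orientation_index(f, growth_axis),
                    error = function(e) NA_real_)
    tibble::tibble(iteration = it,
                   wavelength = dw$wavelength,
                   significant = dw$significant,
                   orientation = ori,
                   amplitude = pattern_amplitude(f),
                   class = classify_pattern(f))
  })
}
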