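#' Parameter sets for the Survival and Promotion lattice models
#'
#' Rate constants for the two lattice models of melanophore/xanthophore
#' interaction. In the Survival model the simple death of melanophores is
#' replaced by three long-range channels: a melanophore dies at rate `d_M`
#' when the site a distance `h` away holds another melanophore or is empty,
#' and at the (much smaller) rate `d_MX` when that remote site holds a
#' xanthophore — remote xanthophores enhance melanophore survival. In the
#' Promotion model melanophores die at the simple rate `d_M` and remote
#' xanthophores instead promote melanophore birth at rate `l_X`.
#'
#' @param b_X,b_M Birth rates of xanthophores / melanophores at empty sites.
#' @param d_X Simple death rate of xanthophores.
#' @param d_M Survival model: long-range melanophore death rate applying when
#'   the remote site is a melanophore or empty. Promotion model: simple
#'   (partner-free) melanophore death rate.
#' @param d_MX Survival model only: melanophore death rate when a xanthophore
#'   sits a distance `h` away; the model intends `d_MX << d_M`, and a warning
#'   (not an error) is emitted when `d_MX > d_M`.
#' @param s_X Rate at which a xanthophore adjacent to a melanophore kills it
#'   (melanophore death next to X).
#' @param s_M Rate at which a melanophore adjacent to a xanthophore kills it
#'   (xanthophore death next to M).
#' @param s Convenience alias setting both `s_X` and `s_M`.
#' @param l_X Promotion model only: rate at which a xanthophore a distance
#'   `h` away promotes melanophore birth at an empty site.
#' @param h Long-range interaction distance in lattice units; positive
#'   integer, roughly half the emerging pattern wavelength.
#'
#' @return A list of rates with class `"survival_params"` or
#'   `"promotion_params"`.
#' @examples
#' p <- survival_params(b_X = 1, b_M = 7, d_M = 9, s = 1, h = 15)
#' build_survival_processes(p)
#' @export
survival_params <- function(b_X = 1, b_M = 1, d_X = 0, d_M = 1, d_MX = 0,
                            s_X = 1, s_M = 1, h = 1, s = NULL) {
  if (!is.null(s)) {
    check_rate(s, "s")
    s_X <- s
    s_M <- s
  }
  rates <- list(b_X = b_X, b_M = b_M, d_X = d_X, d_M = d_M, d_MX = d_MX,
                s_X = s_X, s_M = s_M)
  for (nm in names(rates)) check_rate(rates[[nm]], nm)
  check_h(h)
  if (d_MX > d_M) {
    warning("d_MX > d_M: the survival feedback is meant to *reduce* the ",
            "long-range death rate (d_MX << d_M)", call. = FALSE)
  }
  structure(c(rates, list(h = as.integer(h))), class = "survival_params")
}

#' @rdname survival_params
#' @export
promotion_params <- function(b_X = 1, b_M = 0, d_X = 0, d_M = 0,
                             s_X = 1, s_M = 1, l_X = 2.5, h = 1, s = NULL) {
  if (!is.null(s)) {
    check_rate(s, "s")
    s_X <- s
    s_M <- s
  }
  rates <- list(b_X = b_X, b_M = b_M, d_X = d_X, d_M = d_M,
                s_X = s_X, s_M = s_M, l_X = l_X)
  for (nm in names(rates)) check_rate(rates[[nm]], nm)
  check_h(h)
  structure(c(rates, list(h = as.integer(h))), class = "promotion_params")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("rate `", name, "` must be a single finite non-negative number",
         call. = FALSE)
  }
  invisible(x)
}

check_h <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) ||
      h < 1 || h != round(h)) {
    stop("`h` must be a positive integer (lattice units)", call. = FALSE)
  }
  invisible(h)
}

#' @export
print.survival_params <- function(x, ...) {
  cat("Survival model parameters\n")
  print_param_fields(x)
  invisible(x)
}

#' @export
print.promotion_params <- function(x, ...) {
  cat("Promotion model parameters\n")
  print_param_fields(x)
  invisible(x)
}

print_param_fields <- function(x) {
  cat(paste0("  ", names(x), " = ", unlist(x), collapse = "\n"), "\n")
}

#' Read or write model parameters as a flat key=value config file
#'
#' The config dialect is one `key=value` (or `key,value`) pair per line,
#' with keys named exactly `b_X, b_M, d_X, d_M, d_MX, s_X, s_M, s, l_X, h`
#' plus an optional `model` key (`survival` or `promotion`). Lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @param model `"survival"` or `"promotion"`; overrides any `model` key.
#' @return `read_params()` returns a parameter object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, model = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[=,]")
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- trimws(vapply(parts, `[`, "", 2L))
  names(vals) <- keys
  if (is.null(model)) model <- unname(vals["model"])
  if (is.na(model) || is.null(model)) {
    stop("config must name the model (key `model`) or pass `model=`",
         call. = FALSE)
  }
  vals <- vals[names(vals) != "model"]
  num <- as.numeric(vals)
  names(num) <- names(vals)
  ctor <- switch(model,
                 survival = survival_params,
                 promotion = promotion_params,
                 stop("unknown model: ", model, call. = FALSE))
  allowed <- names(formals(ctor))
  bad <- setdiff(names(num), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(ctor, as.list(num))
}

#' @rdname read_params
#' @param params A `survival_params` or `promotion_params` object.
#' @export
write_params <- function(params, path) {
  model <- if (inherits(params, "survival_params")) "survival" else "promotion"
  lines <- c(paste0("model,", model),
             paste0(names(params), ",", vapply(params, format, "")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
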