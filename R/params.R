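#' Model parameters for the microcolony simulator
#'
#' Bundles every physical constant of the mechanical model with its units.
#' All defaults can be overridden either by arguments or through a flat
#' key/value config file ([read_params_config()]).
#'
#' Units are SI-derived throughout: lengths in \eqn{\mu m}, forces in pN,
#' times in min, energies in \eqn{pN\,\mu m}, pressures in Pa
#' (numerically equal to \eqn{pN/\mu m^2}).
#'
#' @param g Elongation rate (1/min).  Cells elongate exponentially,
#'   \eqn{\dot d_c = g d_c}; default `log(2)/25` (25 min doubling time).
#' @param d_L Division length threshold (\eqn{\mu m}).
#' @param division_rate Stochastic division rate once `d_c >= d_L` (1/min).
#' @param forced_division_factor Division is forced once
#'   `d_c > forced_division_factor * d_L`; default 1.30.
#' @param k_rep Cell-cell elastic repulsion constant (pN/\eqn{\mu m}).
#' @param r_0 Repulsion distance = cell width (\eqn{\mu m}).
#' @param V_0 Yukawa potential depth (pN \eqn{\mu m}); `V_0 = 0` disables the
#'   attractive tail (and the printed discontinuity of the force law at `r_0`).
#' @param r_1 Attraction range (\eqn{\mu m}).
#' @param k_on Link creation rate per ball (1/min).
#' @param n_l Maximum number of links per ball (integer).
#' @param k_off Base link detachment rate (1/min).
#' @param F_link Link rupture force (pN).
#' @param L_0 Link contour length (\eqn{\mu m}).
#' @param L_p Link persistence length (\eqn{\mu m}).  Default 5e-4 (0.5 nm),
#'   the flexible-polymer scale of adhesins and polysaccharides.
#' @param kT Thermal energy (pN \eqn{\mu m}); default 4.24e-3 (307 K).
#' @param eta Effective viscosity (pN min/\eqn{\mu m^2}), chosen so mechanical
#'   relaxation is much faster than the doubling time.
#' @param dt Integration time step (min).
#' @param E_gel Substrate Young modulus (Pa).
#' @param nu_gel Substrate Poisson ratio (dimensionless, in (0, 0.5]).
#' @param A_0 Mean post-division cell footprint area (\eqn{\mu m^2}); if `NULL`
#'   computed from the geometry of a cell of length `d_L/2` and width `r_0`
#'   (rectangle plus end caps).
#' @param lattice Substrate force-grid pitch (\eqn{\mu m}); default 0.510.
#'
#' @return An object of class `"model_params"` (named list).
#' @examples
#' p <- model_params()
#' p$F_link
#' @export
model_params <- function(g = log(2) / 25,
                         d_L = 4,
                         division_rate = 0.5,
                         forced_division_factor = 1.30,
                         k_rep = 1e4,
                         r_0 = 1,
                         V_0 = 0.1,
                         r_1 = 0.1,
                         k_on = 1,
                         n_l = 10L,
                         k_off = 0.01,
                         F_link = 4.25,
                         L_0 = 0.3,
                         L_p = 5e-4,
                         kT = 4.24e-3,
                         eta = 100,
                         dt = 0.005,
                         E_gel = 15000,
                         nu_gel = 0.45,
                         A_0 = NULL,
                         lattice = 0.510) {
  if (is.null(A_0)) {
    # footprint of a freshly divided cell: pole-to-pole axis d_L/2, width r_0,
    # half-disc caps beyond each pole (matches the raster mask geometry)
    A_0 <- (d_L / 2) * r_0 + pi * (r_0 / 2)^2
  }
  p <- list(
    g = g, d_L = d_L, division_rate = division_rate,
    forced_division_factor = forced_division_factor,
    k_rep = k_rep, r_0 = r_0, V_0 = V_0, r_1 = r_1,
    k_on = k_on, n_l = as.integer(n_l), k_off = k_off,
    F_link = F_link, L_0 = L_0, L_p = L_p, kT = kT,
    eta = eta, dt = dt, E_gel = E_gel, nu_gel = nu_gel,
    A_0 = A_0, lattice = lattice
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  pos <- c(
    "g", "d_L", "division_rate", "k_rep", "r_0", "r_1", "k_on",
    "k_off", "F_link", "L_0", "L_p", "kT", "eta", "dt", "E_gel",
    "A_0", "lattice"
  )
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !(p[[nm]] > 0)) {
      stop("parameter '", nm, "' must be a single strictly positive number")
    }
  }
  if (!(p$V_0 >= 0)) stop("parameter 'V_0' must be >= 0")
  if (!(p$forced_division_factor > 1)) {
    stop("'forced_division_factor' must exceed 1")
  }
  if (!(p$nu_gel > 0 && p$nu_gel <= 0.5)) {
    stop("'nu_gel' must lie in (0, 0.5]")
  }
  if (p$n_l < 1L) stop("'n_l' must be a positive integer")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]], digits = 10)))
  }
  invisible(x)
}

#' Read / write a flat key=value parameter config file
#'
#' One `key = value` pair per line; `#` starts a comment; every key is
#' optional and falls back to the [model_params()] default.  Values are in
#' the SI-derived units documented in [model_params()].
#'
#' @param path File path.
#' @return `read_params_config()` returns a `model_params` object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(model_params)
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) stop("unknown parameter key: '", key, "'")
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    overrides[[key]] <- val
  }
  do.call(model_params, overrides)
}

#' @param params A `model_params` object.
#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  lines <- c(
    "# rodcolony model parameters (um, pN, min, Pa)",
    sprintf("%s = %.17g", names(params), as.numeric(unlist(params)))
  )
  writeLines(lines, path)
  invisible(path)
}
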