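#' Pairwise ball-ball interaction force between two cells
#'
#' Force law derived from a Yukawa-like potential, evaluated between two
#' balls of distinct bacteria at center distance `r_bb`:
#' linear elastic repulsion \eqn{k_{rep}(r_0 - r)} for \eqn{r < r_0}, and an
#' attractive tail
#' \eqn{-V_0 (1/r + 1/r_1)(1/r)\exp[-(r - r_0)/r_1]} for \eqn{r \ge r_0}.
#' The law is implemented exactly as stated, including its discontinuity at
#' \eqn{r = r_0}; setting `V_0 = 0` removes both the attraction and the
#' discontinuity.
#'
#' The returned signed magnitude acts along the unit vector from the partner
#' ball toward the ball under consideration (positive = repulsive); the force
#' on the partner is the exact negation.
#'
#' @param r_bb Ball center distance(s), \eqn{\mu m}; strictly positive.
#' @param params A [model_params()] object.
#' @return Signed force magnitude(s) in pN.
#' @examples
#' p <- model_params()
#' cell_cell_force(p$r_0 / 2, p)   # repulsive branch
#' cell_cell_force(p$r_0 + p$r_1, p)  # attractive tail
#' @export
cell_cell_force <- function(r_bb, params = model_params()) {
  if (any(r_bb <= 0)) {
    stop("degenerate geometry: overlapping ball centers (r_bb <= 0)")
  }
  ifelse(
    r_bb < params$r_0,
    params$k_rep * (params$r_0 - r_bb),
    -params$V_0 * (1 / r_bb + 1 / params$r_1) * (1 / r_bb) *
      exp(-(r_bb - params$r_0) / params$r_1)
  )
}

#' Worm-like-chain force of an adhesive link
#'
#' Restoring force of a link stretched to extension `L`:
#' \deqn{F(L) = -\frac{kT}{L_p}\left(\frac{L}{L_0} +
#'   \frac{1}{4}\left(1 - \frac{L}{L_0}\right)^{-2} - \frac{1}{4}\right)}
#' Negative values denote tension resisting the extension; in the plane the
#' restoring pull on the cell acts along attachment \eqn{\to} anchor.
#'
#' @param L Extension(s), \eqn{\mu m}, with `0 <= L < L_0`.  Callers must
#'   rupture links before they reach the contour length.
#' @param params A [model_params()] object.
#' @return Signed force(s) in pN (<= 0).
#' @seealso [wlc_link_energy()] for the stored elastic energy.
#' @export
wlc_link_force <- function(L, params = model_params()) {
  if (any(L < 0)) stop("link extension must be >= 0")
  if (any(L >= params$L_0)) {
    stop("link extension reached the contour length L_0; rupture it first")
  }
  x <- L / params$L_0
  -(params$kT / params$L_p) * (x + 0.25 * (1 - x)^-2 - 0.25)
}

#' Elastic energy stored in a worm-like-chain link
#'
#' Closed antiderivative of the WLC force magnitude from 0 to `L`:
#' \deqn{E(L) = \frac{kT}{L_p}\left[\frac{L^2}{2 L_0} +
#'   \frac{L_0}{4}\left(\frac{1}{1 - L/L_0} - 1\right) - \frac{L}{4}\right]}
#'
#' @inheritParams wlc_link_force
#' @return Energy(ies) in pN \eqn{\mu m} (>= 0).
#' @export
wlc_link_energy <- function(L, params = model_params()) {
  if (any(L < 0)) stop("link extension must be >= 0")
  if (any(L >= params$L_0)) {
    stop("link extension reached the contour length L_0; rupture it first")
  }
  x <- L / params$L_0
  (params$kT / params$L_p) *
    (L^2 / (2 * params$L_0) + (params$L_0 / 4) * (1 / (1 - x) - 1) - L / 4)
}

#' Tension-dependent link detachment rate
#'
#' Links detach at rate \eqn{k_{off}(1 + \mathrm{arctanh}(F/F_{link}))} for
#' tensions below the rupture force and with certainty (`Inf`) at or above
#' it.  The per-step rupture probability is `1 - exp(-rate * dt)`, which is 1
#' when the rate is infinite.
#'
#' @param F_abs Link tension magnitude(s), pN (>= 0).
#' @param params A [model_params()] object.
#' @return Detachment rate(s), 1/min; `Inf` means certain rupture.
#' @export
link_detach_rate <- function(F_abs, params = model_params()) {
  if (any(F_abs < 0)) stop("link tension magnitude must be >= 0")
  ifelse(F_abs >= params$F_link, Inf,
         params$k_off * (1 + atanh(F_abs / params$F_link)))
}

#' Slender-body friction coefficients of a cell
#'
#' Translational and rotational friction of a cylinder of length `d_c` and
#' aspect ratio \eqn{p = d_c/r_0} in a viscous fluid:
#' \deqn{\nu_t = \frac{3\pi\eta d_c}{\ln p + C_t(p)},\qquad
#'   \nu_r = \frac{\pi\eta d_c^3}{3(\ln p + C_r(p))}}
#' with end corrections \eqn{C_t = 0.312 + 0.565/p - 0.1/p^2} and
#' \eqn{C_r = -0.662 + 0.917/p - 0.05/p^2}.  Valid where the corrected
#' logarithms are positive (satisfied for all aspect ratios the simulator
#' produces, \eqn{p \gtrsim 1}).
#'
#' @param d_c Cell length(s), \eqn{\mu m}.
#' @param params A [model_params()] object.
#' @return A list with `nu_t` (pN min/\eqn{\mu m}) and `nu_r`
#'   (pN min \eqn{\mu m}).
#' @export
friction_coefficients <- function(d_c, params = model_params()) {
  if (any(d_c <= 0)) stop("cell length d_c must be > 0")
  p <- d_c / params$r_0
  C_t <- 0.312 + 0.565 / p - 0.1 / p^2
  C_r <- -0.662 + 0.917 / p - 0.05 / p^2
  den_t <- log(p) + C_t
  den_r <- log(p) + C_r
  if (any(den_t <= 0) || any(den_r <= 0)) {
    stop("friction denominator non-positive: aspect ratio p = d_c/r_0 ",
         "outside the validity range of the slender-body corrections")
  }
  list(
    nu_t = 3 * pi * params$eta * d_c / den_t,
    nu_r = pi * params$eta * d_c^3 / (3 * den_r)
  )
}
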