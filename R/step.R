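#' Net forces, torques and link tensions for a world state
#'
#' Evaluates, for the current configuration, the sum over each cell's six
#' balls of all ball-ball interaction forces with neighboring cells and of
#' all worm-like-chain link forces, together with torques about the centers
#' of mass, per-link force contributions, link extensions/tensions and the
#' cell-cell repulsion energy.
#'
#' @param world A [world_state()].
#' @param params A [model_params()] object.
#' @return A list with per-cell `fx`, `fy` (pN), `torque` (pN \eqn{\mu m}),
#'   `e_rep_cell`, scalar `e_rep_total` (pN \eqn{\mu m}), and per-link
#'   `link_fx`, `link_fy`, `link_torque`, `link_ext`, `link_tension`
#'   (tension `Inf` flags a link past its contour length, pending rupture).
#' @export
compute_colony_forces <- function(world, params = model_params()) {
  cl <- world$cells
  lk <- world$links
  colony_forces_cpp(
    cl$cm_x, cl$cm_y, cl$theta, cl$d_c,
    match(lk$cell_id, cl$id), lk$frac, lk$lat,
    lk$anchor_x, lk$anchor_y, lk$rigid,
    params$k_rep, params$r_0, params$V_0, params$r_1,
    params$kT, params$L_p, params$L_0
  )
}

# Overdamped pose update given kernel forces; shared by integrate_step and
# the fused loop of run_simulation.  Errors on per-step displacements above
# r_0/2 (stability guard).
pose_update <- function(cells, fx, fy, torque, params) {
  fr <- friction_coefficients(cells$d_c, params)
  dx <- params$dt * fx / fr$nu_t
  dy <- params$dt * fy / fr$nu_t
  if (length(dx) && max(dx^2 + dy^2) > (params$r_0 / 2)^2) {
    stop("integration unstable: a cell moved more than r_0/2 in one step; ",
         "reduce dt")
  }
  cells$cm_x <- cells$cm_x + dx
  cells$cm_y <- cells$cm_y + dy
  cells$theta <- (cells$theta + params$dt * torque / fr$nu_r) %% (2 * pi)
  cells
}

# Re-impose rigid fixture pins: translate each pinned cell so the pinned
# material point coincides with its anchor (stiff, unbreakable limit).
# With several rigid pins on one cell the mean correction is applied.
apply_rigid_pins <- function(world) {
  lk <- world$links
  if (!nrow(lk) || !any(lk$rigid)) return(world)
  rp <- lk[lk$rigid, , drop = FALSE]
  att <- link_attachments(world$cells, rp)
  sx <- tapply(rp$anchor_x - att[, 1], rp$cell_id, mean)
  sy <- tapply(rp$anchor_y - att[, 2], rp$cell_id, mean)
  idx <- match(as.integer(names(sx)), world$cells$id)
  world$cells$cm_x[idx] <- world$cells$cm_x[idx] + as.numeric(sx)
  world$cells$cm_y[idx] <- world$cells$cm_y[idx] + as.numeric(sy)
  world
}

#' One overdamped integration step
#'
#' Advances every cell pose by one explicit Euler step of the overdamped
#' equations of motion: translation \eqn{\Delta x = \Delta t\, F/\nu_t} and
#' rotation \eqn{\Delta\theta = \Delta t\, \tau/\nu_r}, with friction from
#' [friction_coefficients()].  Internal pair forces are exactly antisymmetric
#' and links act only on their own cell.  The step does not create, rupture,
#' grow or divide anything; see [run_simulation()] for the full event loop.
#'
#' @inheritParams compute_colony_forces
#' @return The updated [world_state()] (time advanced by `dt`).
#' @export
integrate_step <- function(world, params = model_params()) {
  kf <- compute_colony_forces(world, params)
  world$cells <- pose_update(world$cells, kf$fx, kf$fy, kf$torque, params)
  world <- apply_rigid_pins(world)
  world$time <- world$time + params$dt
  world
}
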