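#' Simulation run configuration
#'
#' @param params A [model_params()] object.
#' @param mode Link placement mode, `"polar"` or `"uniform"`.
#' @param seed Integer RNG seed; together with the config it determines every
#'   output bit.
#' @param t_end Stop after this simulated time (min), or
#' @param n_cells_stop stop once the colony reaches this many cells.
#'   Exactly one stop criterion must be given.
#' @param frame_interval Frame cadence (min); default 3, the time-lapse
#'   imaging interval.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(params = model_params(),
                       mode = c("polar", "uniform"),
                       seed = 1L, t_end = NULL, n_cells_stop = NULL,
                       frame_interval = 3) {
  mode <- match.arg(mode)
  if (is.null(t_end) == is.null(n_cells_stop)) {
    stop("give exactly one stop criterion: t_end or n_cells_stop")
  }
  stopifnot(inherits(params, "model_params"), frame_interval > 0)
  cfg <- list(params = params, mode = mode, seed = as.integer(seed),
              t_end = t_end, n_cells_stop = n_cells_stop,
              frame_interval = frame_interval)
  class(cfg) <- "run_config"
  cfg
}

# Footprint area of the colony (sum of spherocylinder footprints; overlaps
# between neighbors are ignored, which is adequate for the near-contact
# packing the repulsion enforces).
colony_area <- function(cells, params) {
  sum(cells$d_c * params$r_0 + pi * (params$r_0 / 2)^2)
}

make_frame <- function(world, params) {
  lt <- link_tensions(world, params)
  links <- world$links
  links$extension <- lt$extension
  links$tension <- lt$tension
  grid <- substrate_force_grid(world, params)
  e_adh <- sum(wlc_link_energy(
    lt$extension[!links$rigid & lt$extension < params$L_0], params
  ))
  list(
    time = world$time, cells = world$cells, links = links,
    N_cells = nrow(world$cells), E_adh = e_adh,
    E_rep = compute_colony_forces(world, params)$e_rep_total,
    F_max = grid$F_max, F_colo = grid$F_colo,
    area = colony_area(world$cells, params)
  )
}

#' Run a microcolony simulation
#'
#' Initializes a single cell of length `d_L/2` at the origin with a random
#' orientation and iterates the fixed event order
#' link creation -> forces -> link rupture -> overdamped integration ->
#' elongation -> division, sampling every stochastic event as a Bernoulli
#' trial with probability `1 - exp(-rate * dt)` from one seeded RNG stream.
#' Frames are recorded every `frame_interval` minutes.  Identical
#' `(config, seed)` give identical trajectories.
#'
#' @param config A [run_config()].
#' @param world Optional initial [world_state()] (e.g. a fixture); when
#'   given, the founder-initialization step is skipped.
#' @return An object of class `"colony_trajectory"`: list with `config` and
#'   `frames` (each frame holds time, the cell and link tables, `N_cells`,
#'   `E_adh`, `E_rep`, `F_max`, `F_colo`, `area`).
#' @export
run_simulation <- function(config, world = NULL) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  set.seed(config$seed)
  if (is.null(world)) {
    world <- world_state(new_cell(1L, 0, 0, stats::runif(1, 0, 2 * pi),
                                  p$d_L / 2, 0))
  }
  frames <- list()
  next_frame <- world$time
  eps <- 1e-9
  repeat {
    if (world$time >= next_frame - eps) {
      frames[[length(frames) + 1L]] <- make_frame(world, p)
      next_frame <- next_frame + config$frame_interval
    }
    stop_now <- (!is.null(config$t_end) && world$time >= config$t_end - eps) ||
      (!is.null(config$n_cells_stop) &&
         nrow(world$cells) >= config$n_cells_stop)
    if (stop_now) break

    world <- spawn_links(world, p, config$mode)
    kf <- compute_colony_forces(world, p)
    fx <- kf$fx; fy <- kf$fy; tq <- kf$torque
    if (nrow(world$links)) {
      gone <- rupture_draw(world$links, kf$link_ext, kf$link_tension, p)
      if (any(gone)) {
        # remove ruptured links and their force/torque contributions
        idx <- match(world$links$cell_id[gone], world$cells$id)
        for (k in seq_along(idx)) {
          g <- which(gone)[k]; ci <- idx[k]
          fx[ci] <- fx[ci] - kf$link_fx[g]
          fy[ci] <- fy[ci] - kf$link_fy[g]
          tq[ci] <- tq[ci] - kf$link_torque[g]
        }
        world$links <- world$links[!gone, , drop = FALSE]
        rownames(world$links) <- NULL
      }
    }
    world$cells <- pose_update(world$cells, fx, fy, tq, p)
    world <- apply_rigid_pins(world)
    world$time <- world$time + p$dt
    world$cells$d_c <- world$cells$d_c * exp(p$g * p$dt)
    world <- apply_rigid_pins(world)
    world <- attempt_divisions(world, p)
  }
  # final frame if the loop broke between frame times
  if (!length(frames) || frames[[length(frames)]]$time < world$time - eps) {
    frames[[length(frames) + 1L]] <- make_frame(world, p)
  }
  traj <- list(config = config, frames = frames, final = world)
  class(traj) <- "colony_trajectory"
  traj
}

#' @export
print.colony_trajectory <- function(x, ...) {
  last <- x$frames[[length(x$frames)]]
  cat(sprintf(
    "<colony_trajectory> %d frames, %.1f min, final N = %d cells (%s mode, seed %d)\n",
    length(x$frames), last$time, last$N_cells, x$config$mode, x$config$seed
  ))
  invisible(x)
}

#' Per-frame observable table of a trajectory
#'
#' `youngest_age` is the time since the most recent division anywhere in the
#' colony; frames with a small value are still relaxing the mechanical
#' transient of septation and are excluded from quasi-static energy fits
#' (see [fit_energy_scalings()]).
#'
#' @param traj A [run_simulation()] trajectory.
#' @return A `data.frame` with one row per frame: `time`, `N_cells`,
#'   `E_adh`, `E_rep`, `F_max`, `F_colo`, `area`, `youngest_age`.
#' @export
trajectory_frames <- function(traj) {
  stopifnot(inherits(traj, "colony_trajectory"))
  do.call(rbind, lapply(traj$frames, function(f) {
    data.frame(time = f$time, N_cells = f$N_cells, E_adh = f$E_adh,
               E_rep = f$E_rep, F_max = f$F_max, F_colo = f$F_colo,
               area = f$area,
               youngest_age = f$time - max(f$cells$birth_time))
  }))
}

#' Deterministic toy states for oracle testing
#'
#' Hand-specified worlds used by the test-suite and documentation:
#' \describe{
#'   \item{`single_free`}{one cell of length `d_L/2` at the origin.}
#'   \item{`single_oldpole_pinned`}{one cell with an unbreakable
#'     zero-compliance pin at its old pole.}
#'   \item{`pair_overlap`}{two collinear cells with exactly one overlapping
#'     ball pair.}
#'   \item{`chain8`}{eight collinear non-overlapping cells.}
#'   \item{`handforce`}{one cell with a single old-pole link pre-stretched
#'     to a 3 pN tension.}
#' }
#'
#' @param name Fixture name.
#' @param params A [model_params()] object.
#' @return A [world_state()].
#' @export
make_fixture <- function(name = c("single_free", "single_oldpole_pinned",
                                  "pair_overlap", "chain8", "handforce"),
                         params = model_params()) {
  name <- match.arg(name)
  p <- params
  half <- p$d_L / 2
  if (name == "single_free") {
    return(world_state(new_cell(1L, d_c = half)))
  }
  if (name == "single_oldpole_pinned") {
    w <- world_state(new_cell(1L, d_c = half))
    w$links <- data.frame(
      cell_id = 1L, ball_index = 1L, frac = -0.5, lat = 0,
      anchor_x = -half / 2, anchor_y = 0, created_at = 0,
      pole_tag = "old", rigid = TRUE
    )
    return(w)
  }
  if (name == "pair_overlap") {
    # end-to-end: only the facing pole balls overlap (gap 0.9 r_0)
    cells <- rbind(
      new_cell(1L, 0, 0, 0, p$d_L),
      new_cell(2L, p$d_L + 0.9 * p$r_0, 0, 0, p$d_L)
    )
    return(world_state(cells))
  }
  if (name == "chain8") {
    # facing pole balls sit just beyond contact distance (no overlap)
    spacing <- half + p$r_0 + 0.01
    cells <- do.call(rbind, lapply(1:8, function(i) {
      new_cell(i, (i - 1) * spacing, 0, 0, half)
    }))
    return(world_state(cells))
  }
  # handforce: solve the WLC extension carrying 3 pN and offset the anchor
  target <- 3
  Lstar <- stats::uniroot(
    function(L) abs(wlc_link_force(L, p)) - target,
    c(1e-9, p$L_0 * (1 - 1e-9)), tol = 1e-14
  )$root
  w <- world_state(new_cell(1L, d_c = half))
  w$links <- data.frame(
    cell_id = 1L, ball_index = 1L, frac = -0.5, lat = 0,
    anchor_x = -half / 2 - Lstar, anchor_y = 0, created_at = 0,
    pole_tag = "old", rigid = FALSE
  )
  w
}

#' Simulate one isolated cell over a full cell cycle
#'
#' Runs a single cell from birth (length `d_L/2`) to its first division with
#' adhesive-link dynamics in the requested placement mode and returns the
#' founder's track, its asymmetry parameter and the trajectory.
#'
#' @param params A [model_params()] object.
#' @param mode `"polar"` or `"uniform"`.
#' @param seed RNG seed.
#' @param frame_interval Frame cadence (min).
#' @return A list with `A_cell`, `track` (per-frame pose table of the
#'   founder) and `trajectory`.
#' @export
simulate_isolated_cell <- function(params = model_params(),
                                   mode = c("polar", "uniform"),
                                   seed = 1L, frame_interval = 1) {
  mode <- match.arg(mode)
  cfg <- run_config(params = params, mode = mode, seed = seed,
                    n_cells_stop = 2L, frame_interval = frame_interval)
  traj <- run_simulation(cfg)
  track <- do.call(rbind, lapply(traj$frames, function(f) {
    row <- f$cells[f$cells$id == 1L, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    data.frame(time = f$time, cm_x = row$cm_x, cm_y = row$cm_y,
               theta = row$theta, d_c = row$d_c)
  }))
  list(A_cell = cell_asymmetry(track), track = track, trajectory = traj)
}

#' Sweep simulations over rupture forces and seeds
#'
#' Runs polar- (or uniform-) mode colonies to `n_cells_stop` cells for every
#' combination of `F_link` value and seed, and returns the per-frame summary
#' table expected by [fit_energy_scalings()], with each run's focus force
#' measured by [foci_force()].
#'
#' @param F_links Rupture-force values (pN) to sweep.
#' @param seeds Seeds per rupture force.
#' @param params Base [model_params()]; `F_link` is overridden per run.
#' @param mode Placement mode.
#' @param n_cells_stop Colony size at which each run stops.
#' @return A list with `frames` (stacked [trajectory_frames()] rows plus
#'   `run`, `F_link`, `F_foci`) and `runs` (one row per run: `run`,
#'   `F_link`, `seed`, `F_foci`, `aspect_ratio`).
#' @export
run_sweep <- function(F_links, seeds, params = model_params(),
                      mode = "polar", n_cells_stop = 30) {
  frames <- list(); runs <- list()
  for (fl in F_links) {
    p <- params
    p$F_link <- fl
    validate_params(p)
    for (s in seeds) {
      cfg <- run_config(params = p, mode = mode, seed = s,
                        n_cells_stop = n_cells_stop)
      traj <- run_simulation(cfg)
      fr <- trajectory_frames(traj)
      ff <- foci_force(fr)
      run_id <- sprintf("F%.3g_s%d", fl, s)
      fr$run <- run_id; fr$F_link <- fl; fr$F_foci <- ff
      frames[[run_id]] <- fr
      runs[[run_id]] <- data.frame(
        run = run_id, F_link = fl, seed = s, F_foci = ff,
        aspect_ratio = aspect_ratio(traj_last_world(traj), params = p)
      )
    }
  }
  list(frames = do.call(rbind, frames), runs = do.call(rbind, runs))
}

# Reconstruct a world_state from the last frame of a trajectory.
traj_last_world <- function(traj) {
  f <- traj$frames[[length(traj$frames)]]
  lk <- f$links
  lk$extension <- NULL; lk$tension <- NULL
  w <- world_state(f$cells, lk, f$time)
  w
}
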