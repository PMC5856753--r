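#' Exponential cell elongation over one time step
#'
#' Every cell length is updated as \eqn{d_c \leftarrow d_c e^{g\,dt}}.
#' Isolated bacteria elongate symmetrically about their center of mass, so
#' elongation itself leaves `cm` unchanged; link attachment points, stored as
#' body-frame fractions of `d_c`, stretch with the cell.  Cells pinned by a
#' rigid fixture link are re-positioned so the pinned material point stays on
#' its anchor (the pole stays put and the CM advances).
#'
#' @param world A [world_state()].
#' @param params A [model_params()] object.
#' @return The updated world (time unchanged; [run_simulation()] owns the
#'   clock).
#' @export
elongate_cells <- function(world, params = model_params()) {
  world$cells$d_c <- world$cells$d_c * exp(params$g * params$dt)
  apply_rigid_pins(world)
}

ball_from_frac <- function(frac) {
  pmin(pmax(floor((frac + 0.5) * 6) + 1, 1L), 6L)
}

pole_tag_from_ball <- function(ball) {
  ifelse(ball == 1L, "old", ifelse(ball == 6L, "new", "body"))
}

#' Stochastic and forced cell division
#'
#' Cells that have reached the division length `d_L` divide with per-step
#' probability `1 - exp(-division_rate * dt)`; division is forced in the same
#' step once the length exceeds `forced_division_factor * d_L` (30% beyond
#' the threshold by default).  Each division splits the mother at the exact
#' midpoint into two daughters of length `d_c/2` on the same axis.  Each
#' daughter keeps the mother pole on its side as its old pole; the poles
#' born at the septum are new and carry no adhesive links, which is how
#' asymmetric adhesion arises in this model.  Axis orientation is re-set per
#' daughter to point old pole -> new pole, links are reassigned to the
#' daughter whose body contains their attachment point, and the division is
#' appended to the event log.
#'
#' @inheritParams elongate_cells
#' @return The updated world.
#' @export
attempt_divisions <- function(world, params = model_params()) {
  cells <- world$cells
  if (!nrow(cells)) return(world)
  eligible <- which(cells$d_c >= params$d_L)
  divide <- logical(nrow(cells))
  if (length(eligible)) {
    p <- 1 - exp(-params$division_rate * params$dt)
    divide[eligible] <- stats::runif(length(eligible)) < p
  }
  divide[cells$d_c > params$forced_division_factor * params$d_L] <- TRUE
  if (!any(divide)) return(world)

  next_id <- max(cells$id) + 1L
  lk <- world$links
  keep_cells <- cells[!divide, , drop = FALSE]
  new_rows <- list()
  # Daughters are born with their facing (new-pole) balls at the steric
  # contact distance r_0: the cap surfaces are tangent at the septum plane.
  # Coincident septum balls would have no defined force direction and would
  # inject ~0.5*k_rep*r_0^2 of spurious elastic energy per division.
  eps <- params$r_0 / 2
  for (i in which(divide)) {
    mo <- cells[i, ]
    u <- c(cos(mo$theta), sin(mo$theta))
    half <- mo$d_c / 2
    off <- half / 2 + eps
    idA <- next_id; idB <- next_id + 1L; next_id <- next_id + 2L
    # daughter A keeps the mother's old pole (axis direction unchanged)
    dA <- new_cell(idA, mo$cm_x - off * u[1], mo$cm_y - off * u[2],
                   mo$theta, half, world$time,
                   mo$old_pole_generation + 1L, mo$id)
    # daughter B keeps the mother's new pole; its axis flips so it still
    # points old -> new (generation restarts at 1 for a first-generation pole)
    dB <- new_cell(idB, mo$cm_x + off * u[1], mo$cm_y + off * u[2],
                   mo$theta + pi, half, world$time, 1L, mo$id)
    new_rows[[length(new_rows) + 1L]] <- dA
    new_rows[[length(new_rows) + 1L]] <- dB
    nA <- 0L; nB <- 0L
    if (nrow(lk)) {
      mine <- lk$cell_id == mo$id
      if (any(mine)) {
        toA <- mine & lk$frac < 0
        toB <- mine & lk$frac >= 0
        nA <- sum(toA); nB <- sum(toB)
        # attachment world points are preserved: new fraction measured from
        # the daughter center (offset by eps along the mother axis)
        lk$cell_id[toA] <- idA
        lk$frac[toA] <- 2 * lk$frac[toA] + 0.5 + 2 * eps / mo$d_c
        lk$cell_id[toB] <- idB
        lk$frac[toB] <- -2 * lk$frac[toB] + 0.5 + 2 * eps / mo$d_c
        lk$lat[toB] <- -lk$lat[toB]
        # attachments mapping onto the regenerated cap (possible for links
        # just inside the septum) are projected back onto the body span
        lk$frac[mine] <- pmin(pmax(lk$frac[mine], -0.5), 0.5)
        # pole adhesin patches keep their pole identity: the mother's old
        # pole is A's old pole, the mother's new pole becomes B's old pole;
        # body links are reclassified from their new axial fraction
        was_pole <- lk$pole_tag %in% c("old", "new")
        lk$ball_index[mine & !was_pole] <-
          ball_from_frac(lk$frac[mine & !was_pole])
        lk$pole_tag[mine & !was_pole] <-
          pole_tag_from_ball(lk$ball_index[mine & !was_pole])
        lk$ball_index[mine & was_pole] <- 1L
        lk$pole_tag[mine & was_pole] <- "old"
      }
    }
    world$events[[length(world$events) + 1L]] <- list(
      type = "division", time = world$time, mother_id = mo$id,
      daughter_ids = c(idA, idB), septum = c(mo$cm_x, mo$cm_y),
      inherited_link_counts = c(nA, nB)
    )
  }
  world$cells <- rbind(keep_cells, do.call(rbind, new_rows))
  world$links <- lk
  world
}

#' Create adhesive links (polar or uniform placement)
#'
#' For each eligible ball whose current link count is below the saturation
#' density `n_l`, a link is created with per-step probability
#' `1 - exp(-k_on * dt)`.  In `"polar"` mode only the two pole balls (1 and 6)
#' are eligible and the attachment point is drawn uniformly in a disk of
#' diameter `r_0` centered on the pole; in `"uniform"` mode all six balls are
#' eligible and the attachment is drawn uniformly along that ball's axial
#' segment.  The substrate anchor is set directly beneath the attachment
#' point, i.e. the link is born at zero extension.
#'
#' @inheritParams elongate_cells
#' @param mode `"polar"` or `"uniform"` placement.
#' @return The updated world.
#' @export
spawn_links <- function(world, params = model_params(),
                        mode = c("polar", "uniform")) {
  mode <- match.arg(mode)
  cells <- world$cells
  n <- nrow(cells)
  if (!n) return(world)
  balls <- if (mode == "polar") c(1L, 6L) else 1:6
  # per-(cell, ball) live-link counts, keyed as (cell row - 1) * 6 + ball
  counts <- integer(n * 6)
  if (nrow(world$links)) {
    idx <- match(world$links$cell_id, cells$id)
    counts <- tabulate((idx - 1L) * 6L + world$links$ball_index, nbins = n * 6)
  }
  cand_cell <- rep(seq_len(n), times = length(balls))
  cand_ball <- rep(balls, each = n)
  open <- counts[(cand_cell - 1L) * 6L + cand_ball] < params$n_l
  cand_cell <- cand_cell[open]; cand_ball <- cand_ball[open]
  if (!length(cand_cell)) return(world)
  hit <- stats::runif(length(cand_cell)) < 1 - exp(-params$k_on * params$dt)
  if (!any(hit)) return(world)
  cc <- cand_cell[hit]; cb <- cand_ball[hit]
  k <- length(cc)
  d_c <- cells$d_c[cc]
  if (mode == "polar") {
    # uniform in a disk of diameter r_0 on the pole, with the axial
    # component folded onto the body side so the material point stays on
    # the stretching sidewall parameterization (|frac| <= 1/2)
    rad <- (params$r_0 / 2) * sqrt(stats::runif(k))
    phi <- 2 * pi * stats::runif(k)
    frac <- ifelse(cb == 1L, -0.5 + abs(rad * cos(phi)) / d_c,
                   0.5 - abs(rad * cos(phi)) / d_c)
    lat <- rad * sin(phi)
  } else {
    frac <- (cb - stats::runif(k)) / 6 - 0.5
    lat <- numeric(k)
  }
  newl <- data.frame(
    cell_id = cells$id[cc], ball_index = cb, frac = frac, lat = lat,
    anchor_x = 0, anchor_y = 0, created_at = world$time,
    pole_tag = pole_tag_from_ball(cb), rigid = FALSE
  )
  att <- link_attachments(cells, newl)
  newl$anchor_x <- att[, 1]
  newl$anchor_y <- att[, 2]
  world$links <- rbind(world$links, newl)
  world
}

# Rupture decision given precomputed extensions/tensions (shared by
# rupture_links and the fused run_simulation loop).  Returns a logical
# rupture mask.
rupture_draw <- function(links, ext, tension, params) {
  n <- nrow(links)
  if (!n) return(logical(0))
  rate <- link_detach_rate(pmin(tension, params$F_link), params)
  rate[tension >= params$F_link | ext >= params$L_0] <- Inf
  rate[links$rigid] <- 0
  p <- 1 - exp(-rate * params$dt)
  stats::runif(n) < p
}

#' Stochastic link rupture
#'
#' Each link ruptures with per-step probability `1 - exp(-rate * dt)` where
#' the rate follows [link_detach_rate()] at the link's current tension.
#' Links at or above the rupture force `F_link`, or stretched to the contour
#' length `L_0`, rupture with certainty.  Ruptured links are deleted
#' permanently (detached adhesive bonds are lost); rigid fixture pins never
#' rupture.
#'
#' @inheritParams elongate_cells
#' @return The updated world, with rupture counts appended to the event log.
#' @export
rupture_links <- function(world, params = model_params()) {
  if (!nrow(world$links)) return(world)
  lt <- link_tensions(world, params)
  gone <- rupture_draw(world$links, lt$extension, lt$tension, params)
  if (any(gone)) {
    world$events[[length(world$events) + 1L]] <- list(
      type = "rupture", time = world$time, n = sum(gone),
      cell_ids = world$links$cell_id[gone]
    )
    world$links <- world$links[!gone, , drop = FALSE]
    rownames(world$links) <- NULL
  }
  world
}
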