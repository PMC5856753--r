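#' Construct a colony world state
#'
#' A `world_state` holds the whole colony at one instant: a cell table, an
#' adhesive-link table, the simulation clock and an event log.  It is the
#' object every simulation and measurement operation consumes and returns.
#'
#' Cell table columns: `id`, `cm_x`, `cm_y` (\eqn{\mu m}), `theta` (rad, axis
#' unit vector points from the old pole toward the new pole), `d_c`
#' (pole-to-pole length, \eqn{\mu m}), `birth_time` (min),
#' `old_pole_generation` (divisions the old pole has survived), `parent_id`.
#'
#' Link table columns: `cell_id`, `ball_index` (1..6, ball 1 sits at the old
#' pole), `frac` (axial body-frame attachment as a signed fraction of `d_c`,
#' so the attachment advects with rigid-body motion and stretches with
#' elongation), `lat` (lateral body-frame offset, \eqn{\mu m}), `anchor_x`,
#' `anchor_y` (fixed substrate point), `created_at` (min), `pole_tag`
#' (`"old"`, `"new"` or `"body"`), `rigid` (logical; a rigid link is an
#' unbreakable zero-compliance pin used by fixtures).
#'
#' @param cells Cell `data.frame` (see Details); `empty_cells()` gives the
#'   column skeleton.
#' @param links Link `data.frame`; `empty_links()` gives the skeleton.
#' @param time Simulation clock (min).
#' @return An object of class `"world_state"`.
#' @export
world_state <- function(cells = empty_cells(), links = empty_links(),
                        time = 0) {
  w <- list(time = time, cells = cells, links = links,
            events = list())
  class(w) <- "world_state"
  w
}

#' @rdname world_state
#' @export
empty_cells <- function() {
  data.frame(
    id = integer(), cm_x = numeric(), cm_y = numeric(), theta = numeric(),
    d_c = numeric(), birth_time = numeric(), old_pole_generation = integer(),
    parent_id = integer()
  )
}

#' @rdname world_state
#' @export
empty_links <- function() {
  data.frame(
    cell_id = integer(), ball_index = integer(), frac = numeric(),
    lat = numeric(), anchor_x = numeric(), anchor_y = numeric(),
    created_at = numeric(), pole_tag = character(), rigid = logical()
  )
}

#' @rdname world_state
#' @param id,cm_x,cm_y,theta,d_c,birth_time,old_pole_generation,parent_id
#'   Scalar cell fields, see Details.
#' @export
new_cell <- function(id, cm_x = 0, cm_y = 0, theta = 0, d_c = 2,
                     birth_time = 0, old_pole_generation = 1L,
                     parent_id = NA_integer_) {
  data.frame(
    id = as.integer(id), cm_x = cm_x, cm_y = cm_y,
    theta = theta %% (2 * pi), d_c = d_c, birth_time = birth_time,
    old_pole_generation = as.integer(old_pole_generation),
    parent_id = as.integer(parent_id)
  )
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf(
    "<world_state> t = %.3f min, %d cells, %d links, %d logged events\n",
    x$time, nrow(x$cells), nrow(x$links), length(x$events)
  ))
  invisible(x)
}

#' Ball centers of a spherocylinder cell
#'
#' Each bacterium is discretized as 6 adjacent balls equally spaced along its
#' length.  Ball 1 sits at the old pole, ball 6 at the new pole; ball centers
#' lie at axial coordinates \eqn{d_c (k-1)/5 - d_c/2} relative to the center
#' of mass.
#'
#' @param cell One-row cell `data.frame` (see [world_state()]).
#' @param params A [model_params()] object (reserved; the positions depend on
#'   geometry only).
#' @return A 6 x 2 matrix of ball centers (\eqn{\mu m}).
#' @examples
#' ball_positions(new_cell(1, d_c = 5))
#' @export
ball_positions <- function(cell, params = model_params()) {
  stopifnot(nrow(cell) == 1L)
  if (!(cell$d_c > 0)) stop("cell length d_c must be > 0")
  s <- cell$d_c * ((seq_len(6) - 1) / 5 - 0.5)
  u <- c(cos(cell$theta), sin(cell$theta))
  cbind(cell$cm_x + s * u[1], cell$cm_y + s * u[2])
}

# World-frame attachment points of links given the cell table.
# Returns a matrix with columns ax, ay (attachment) for each link row.
link_attachments <- function(cells, links) {
  if (nrow(links) == 0L) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("ax", "ay"))))
  }
  idx <- match(links$cell_id, cells$id)
  if (anyNA(idx)) stop("link references a cell id not present in the world")
  th <- cells$theta[idx]
  ux <- cos(th); uy <- sin(th)
  s <- links$frac * cells$d_c[idx]
  ax <- cells$cm_x[idx] + s * ux - links$lat * uy
  ay <- cells$cm_y[idx] + s * uy + links$lat * ux
  cbind(ax = ax, ay = ay)
}

#' Link extensions and WLC tensions for every live link
#'
#' Extension is the planar distance between the fixed substrate anchor and
#' the current world-frame attachment point on the cell body; tension is the
#' worm-like-chain force magnitude at that extension.  Links at or beyond the
#' contour length `L_0` (which must rupture) are reported with tension `Inf`.
#' Rigid fixture pins are reported with extension and tension 0.
#'
#' @param world A [world_state()].
#' @param params A [model_params()] object.
#' @return A `data.frame` with columns `extension` (\eqn{\mu m}) and
#'   `tension` (pN, magnitude).
#' @export
link_tensions <- function(world, params = model_params()) {
  lk <- world$links
  if (nrow(lk) == 0L) {
    return(data.frame(extension = numeric(), tension = numeric()))
  }
  att <- link_attachments(world$cells, lk)
  ext <- sqrt((att[, 1] - lk$anchor_x)^2 + (att[, 2] - lk$anchor_y)^2)
  tension <- numeric(nrow(lk))
  live <- !lk$rigid & ext < params$L_0
  tension[live] <- abs(wlc_link_force(ext[live], params))
  tension[!lk$rigid & ext >= params$L_0] <- Inf
  ext[lk$rigid] <- 0
  data.frame(extension = ext, tension = tension)
}
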