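#' Colony aspect ratio from the moment-equivalent ellipse
#'
#' Rasterizes the union of all spherocylinder footprints (width `r_0`) to a
#' binary mask and fits the ellipse with the same normalized second central
#' moments; returns the ratio of the small to the large ellipse axis,
#' \eqn{b/a \in (0, 1]}.  Close to 0 for a linear chain of bacteria, close
#' to 1 for a circular microcolony.
#'
#' @param world A [world_state()] with at least one cell.
#' @param raster_pitch Mask pixel size (\eqn{\mu m}); the default 0.05 keeps
#'   the ellipse-fit error below 1e-3 at colony scale.
#' @param params A [model_params()] object (supplies the cell width).
#' @return The aspect ratio `b/a`.
#' @export
aspect_ratio <- function(world, raster_pitch = 0.05,
                         params = model_params()) {
  cells <- world$cells
  if (!nrow(cells)) stop("empty colony: no cells to rasterize")
  half_w <- params$r_0 / 2
  x1 <- cells$cm_x - cells$d_c / 2 * cos(cells$theta)
  y1 <- cells$cm_y - cells$d_c / 2 * sin(cells$theta)
  x2 <- cells$cm_x + cells$d_c / 2 * cos(cells$theta)
  y2 <- cells$cm_y + cells$d_c / 2 * sin(cells$theta)
  gx <- seq(min(x1, x2) - half_w - raster_pitch,
            max(x1, x2) + half_w + raster_pitch, by = raster_pitch)
  gy <- seq(min(y1, y2) - half_w - raster_pitch,
            max(y1, y2) + half_w + raster_pitch, by = raster_pitch)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  mask <- logical(length(px))
  for (i in seq_len(nrow(cells))) {
    vx <- x2[i] - x1[i]; vy <- y2[i] - y1[i]
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) pmin(pmax(((px - x1[i]) * vx + (py - y1[i]) * vy) /
                                   len2, 0), 1) else 0
    dx <- px - (x1[i] + t * vx)
    dy <- py - (y1[i] + t * vy)
    mask <- mask | (dx * dx + dy * dy <= half_w * half_w)
  }
  if (!any(mask)) stop("empty mask: raster pitch too coarse for the colony")
  mx <- px[mask]; my <- py[mask]
  cxx <- stats::var(mx); cyy <- stats::var(my)
  cxy <- stats::cov(mx, my)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  sqrt(max(ev[2], 0) / ev[1])
}

#' Substrate force grid and total colony force
#'
#' Deposits each live link's planar tension vector (the pull the link exerts
#' on the substrate, applied at its fixed anchor) onto a square lattice of
#' pitch `pitch` (default 510 nm, the traction-microscopy lattice).  The
#' value of a lattice cell is the magnitude of the vector sum of its
#' deposits; `F_colo` is the sum of those magnitudes over the lattice under
#' the colony and `F_max` their maximum, used for the focus-force plateau.
#'
#' @param world A [world_state()].
#' @param params A [model_params()] object.
#' @param pitch Lattice pitch (\eqn{\mu m}); defaults to `params$lattice`.
#' @return An object of class `"force_grid"`: a list with `table`
#'   (`data.frame` of occupied lattice cells: `ix`, `iy`, `fx`, `fy`,
#'   `mag`), `pitch`, `F_colo`, `F_max` and `time`.
#' @export
substrate_force_grid <- function(world, params = model_params(),
                                 pitch = params$lattice) {
  stopifnot(pitch > 0)
  lk <- world$links
  empty <- list(
    table = data.frame(ix = integer(), iy = integer(), fx = numeric(),
                       fy = numeric(), mag = numeric()),
    pitch = pitch, F_colo = 0, F_max = 0, time = world$time
  )
  class(empty) <- "force_grid"
  if (!nrow(lk)) return(empty)
  lt <- link_tensions(world, params)
  use <- !lk$rigid & is.finite(lt$tension) & lt$tension > 0 &
    lt$extension > 0
  if (!any(use)) return(empty)
  lk <- lk[use, , drop = FALSE]
  att <- link_attachments(world$cells, lk)
  ext <- lt$extension[use]; ten <- lt$tension[use]
  # pull on the substrate points from the anchor toward the attachment
  fx <- ten * (att[, 1] - lk$anchor_x) / ext
  fy <- ten * (att[, 2] - lk$anchor_y) / ext
  ix <- floor(lk$anchor_x / pitch)
  iy <- floor(lk$anchor_y / pitch)
  key <- paste(ix, iy)
  sfx <- rowsum(fx, key); sfy <- rowsum(fy, key)
  first <- !duplicated(key)
  ord <- match(rownames(sfx), key[first])
  tab <- data.frame(
    ix = ix[first][ord], iy = iy[first][ord],
    fx = as.numeric(sfx), fy = as.numeric(sfy)
  )
  tab$mag <- sqrt(tab$fx^2 + tab$fy^2)
  out <- list(table = tab, pitch = pitch, F_colo = sum(tab$mag),
              F_max = max(tab$mag), time = world$time)
  class(out) <- "force_grid"
  out
}

#' @export
print.force_grid <- function(x, ...) {
  cat(sprintf(
    "<force_grid> pitch %.3f um, %d occupied cells, F_colo = %.3f pN, F_max = %.3f pN\n",
    x$pitch, nrow(x$table), x$F_colo, x$F_max
  ))
  invisible(x)
}

#' Adhesion-focus force from a growth series
#'
#' The maximal lattice force `F_max` rises early during colony growth and
#' saturates once the colony exceeds about eight bacteria (one cell fully
#' surrounded by neighbors).  The focus force `F_foci` is the plateau value,
#' estimated as the median of `F_max` over frames with at least `N_plateau`
#' cells (robust to rupture spikes).
#'
#' @param series A `data.frame` with columns `N_cells` and `F_max`, one row
#'   per frame ([trajectory_frames()] provides it).
#' @param N_plateau Plateau gate (cells), default 8.
#' @return `F_foci` in pN.
#' @export
foci_force <- function(series, N_plateau = 8) {
  stopifnot(all(c("N_cells", "F_max") %in% names(series)))
  keep <- series$N_cells >= N_plateau
  if (!any(keep)) {
    stop("no frames with N_cells >= ", N_plateau,
         ": run the simulation longer to reach the force plateau")
  }
  stats::median(series$F_max[keep])
}

#' Global adhesive stress under the colony
#'
#' Slope of the ordinary-least-squares fit of the total substrate force
#' `F_colo` against the change in colony area, in \eqn{pN/\mu m^2}
#' (numerically equal to Pa).
#'
#' @param series A `data.frame` with columns `F_colo` (pN) and `area`
#'   (\eqn{\mu m^2}), one row per frame.
#' @return `sigma_colo` in Pa.
#' @export
global_stress_sigma <- function(series) {
  stopifnot(all(c("F_colo", "area") %in% names(series)))
  if (nrow(series) < 5) stop("need at least 5 frames to fit sigma_colo")
  dA <- series$area - series$area[1]
  if (any(diff(series$area) < 0) || max(dA) <= 0) {
    stop("degenerate or non-monotone area series: cannot fit sigma_colo")
  }
  unname(stats::coef(stats::lm(series$F_colo ~ dA))[2])
}

#' Single-cell adhesion asymmetry A_cell
#'
#' Projects the cumulative center-of-mass displacement of one cell onto its
#' axis (oriented from the old pole toward the new pole) and regresses it
#' through the origin against the cell's elongation:
#' \eqn{\Delta X = A_{cell}\,\Delta L}.  `A_cell` is 0 for uniform adhesion
#' and +0.5 (resp. -0.5) for a cell anchored rigidly at its old (resp. new)
#' pole; positive values mean stronger old-pole adhesion.
#'
#' @param track A `data.frame` with one row per frame of a single cell cycle
#'   and columns `cm_x`, `cm_y`, `theta`, `d_c` (time-ordered).
#' @return The slope `A_cell`.
#' @export
cell_asymmetry <- function(track) {
  stopifnot(all(c("cm_x", "cm_y", "theta", "d_c") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least two frames")
  dL <- track$d_c - track$d_c[1]
  if (max(abs(dL)) < 1e-12) stop("no elongation in track: A_cell undefined")
  dX <- (track$cm_x - track$cm_x[1]) * cos(track$theta) +
    (track$cm_y - track$cm_y[1]) * sin(track$theta)
  sum(dX * dL) / sum(dL * dL)
}

#' Population mean of |A_cell| via a folded-normal fit
#'
#' Before a division has been observed, pole identities are unknown and only
#' \eqn{|A_{cell}|} can be measured.  The population average
#' \eqn{|\langle A_{cell}\rangle|} is recovered by fitting the empirical
#' cumulative distribution of \eqn{|A_{cell}|} with a folded normal
#' distribution (least-squares distance between CDFs) and reporting
#' \eqn{|\mu|}; a bootstrap confidence interval is attached.
#'
#' @param samples Numeric vector of \eqn{|A_{cell}|} values (n >= 20).
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param conf Confidence level (default 0.95).
#' @return A list with `mu_abs`, `sigma`, `ci` (length-2) and `converged`.
#' @export
folded_normal_mean <- function(samples, n_boot = 200, conf = 0.95) {
  if (length(samples) < 20) stop("need at least 20 samples")
  if (any(samples < 0)) stop("samples must be absolute values (>= 0)")
  fit_one <- function(x) {
    xs <- sort(x)
    n <- length(xs)
    emp <- (seq_len(n) - 0.5) / n
    if (stats::sd(xs) < 1e-12) return(c(mu = xs[1], sigma = 0))
    obj <- function(par) {
      mu <- par[1]; s <- abs(par[2])
      if (s < 1e-10) return(1e10)
      cdf <- stats::pnorm((xs - mu) / s) + stats::pnorm((xs + mu) / s) - 1
      sum((cdf - emp)^2)
    }
    fit <- stats::optim(c(mean(xs), stats::sd(xs)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$convergence != 0) {
      stop("folded-normal CDF fit did not converge (code ",
           fit$convergence, ", objective ", signif(fit$value, 4), ")")
    }
    c(mu = abs(fit$par[1]), sigma = abs(fit$par[2]))
  }
  est <- fit_one(samples)
  boot <- replicate(n_boot, {
    fit_one(sample(samples, replace = TRUE))[["mu"]]
  })
  alpha <- (1 - conf) / 2
  list(
    mu_abs = unname(est[["mu"]]), sigma = unname(est[["sigma"]]),
    ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    converged = TRUE
  )
}

#' Colony-scale adhesion asymmetry A_colo
#'
#' Compares maximal (not average, since most poles slide) substrate forces
#' at old vs new poles across the colony on the traction lattice:
#' \deqn{A_{colo} = \frac{\max\{F_{oldpole}\}_{cells} -
#'   \max\{F_{newpole}\}_{cells}}{F_{foci}}}
#' Per cell and pole tag, link tension vectors are deposited on the lattice
#' and the per-cell pole force is the maximal resulting lattice magnitude.
#'
#' @param world A [world_state()].
#' @param F_foci Focus force used for normalization (pN, > 0); from
#'   [foci_force()].
#' @param params A [model_params()] object.
#' @param pitch Lattice pitch (\eqn{\mu m}).
#' @return `A_colo` (dimensionless).
#' @export
colony_asymmetry <- function(world, F_foci, params = model_params(),
                             pitch = params$lattice) {
  if (!is.finite(F_foci) || F_foci <= 0) {
    stop("A_colo undefined: F_foci must be > 0")
  }
  lk <- world$links
  pole_max <- function(tag) {
    if (!nrow(lk)) return(0)
    lt <- link_tensions(world, params)
    use <- !lk$rigid & lk$pole_tag == tag & is.finite(lt$tension) &
      lt$tension > 0 & lt$extension > 0
    if (!any(use)) return(0)
    sub <- lk[use, , drop = FALSE]
    att <- link_attachments(world$cells, sub)
    fx <- lt$tension[use] * (att[, 1] - sub$anchor_x) / lt$extension[use]
    fy <- lt$tension[use] * (att[, 2] - sub$anchor_y) / lt$extension[use]
    key <- paste(sub$cell_id, floor(sub$anchor_x / pitch),
                 floor(sub$anchor_y / pitch))
    max(sqrt(rowsum(fx, key)^2 + rowsum(fy, key)^2))
  }
  (pole_max("old") - pole_max("new")) / F_foci
}

#' Nematic orientational order of the colony
#'
#' Head-tail-symmetric alignment statistic of the rod orientations:
#' \deqn{S(\ell) = \langle \cos 2(\theta_i - \theta_j) \rangle} over cell
#' pairs whose centers are closer than `length_scale`; 1 means perfectly
#' aligned, 0 random.  `length_scale = Inf` gives the global order.
#'
#' @param world A [world_state()] with at least two cells.
#' @param length_scale Pair-distance cutoff \eqn{\ell} (\eqn{\mu m}).
#' @return `S` in `[-1, 1]` (`NA` when no pair falls within the scale).
#' @export
nematic_order <- function(world, length_scale = Inf) {
  cells <- world$cells
  if (nrow(cells) < 2) stop("need at least two cells for orientational order")
  i <- rep(seq_len(nrow(cells)), times = nrow(cells))
  j <- rep(seq_len(nrow(cells)), each = nrow(cells))
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  d2 <- (cells$cm_x[i] - cells$cm_x[j])^2 + (cells$cm_y[i] - cells$cm_y[j])^2
  within <- d2 <= length_scale^2
  if (!any(within)) return(NA_real_)
  mean(cos(2 * (cells$theta[i][within] - cells$theta[j][within])))
}
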