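#' Elastic energy stored in adhesive links
#'
#' Sums, per cell and over the colony, the worm-like-chain stretching energy
#' \eqn{\int_0^L |F(L')| dL'} of every live link, evaluated with the closed
#' antiderivative ([wlc_link_energy()]).  Rigid fixture pins store no energy.
#'
#' @param world A [world_state()].
#' @param params A [model_params()] object.
#' @return A list with `total` (pN \eqn{\mu m}) and `per_cell` (named by cell
#'   id).
#' @export
adhesion_energy <- function(world, params = model_params()) {
  per_cell <- stats::setNames(numeric(nrow(world$cells)),
                              as.character(world$cells$id))
  lk <- world$links
  if (nrow(lk)) {
    lt <- link_tensions(world, params)
    live <- !lk$rigid
    if (any(lt$extension[live] >= params$L_0)) {
      stop("a link extension is at or past L_0; rupture before computing ",
           "the adhesion energy")
    }
    e <- numeric(nrow(lk))
    e[live] <- wlc_link_energy(lt$extension[live], params)
    agg <- tapply(e, lk$cell_id, sum)
    per_cell[names(agg)] <- agg
  }
  list(total = sum(per_cell), per_cell = per_cell)
}

#' Steric repulsion energy between cells
#'
#' Elastic energy of overlapping ball pairs between distinct cells,
#' \eqn{\frac12 k_{rep}(r_0 - r)^2} per unordered overlapping pair (only
#' overlaps contribute; the attractive tail stores nothing by definition).
#' Each pair is counted once in the total and split equally between the two
#' cells, so that minus the gradient of the total with respect to a ball
#' position reproduces the repulsive force branch of [cell_cell_force()].
#'
#' @inheritParams adhesion_energy
#' @return A list with `total` (pN \eqn{\mu m}) and `per_cell` (named by cell
#'   id).
#' @export
repulsion_energy <- function(world, params = model_params()) {
  kf <- compute_colony_forces(world, params)
  list(
    total = kf$e_rep_total,
    per_cell = stats::setNames(kf$e_rep_cell, as.character(world$cells$id))
  )
}

#' Hertz energy of gel indentation
#'
#' Energy required to indent the soft confining gel by `z` with a spherical
#' cap of radius `r_0/2` (Hertz contact):
#' \deqn{E_g(z) = \int_0^z \frac{4}{3}\frac{E}{1-\nu^2}
#'   \left(\frac{r_0}{2}\right)^{1/2} z'^{3/2} dz'
#'   = \frac{8}{15}\frac{E}{1-\nu^2}\left(\frac{r_0}{2}\right)^{1/2} z^{5/2}}
#' The Young modulus is given in Pa, which is numerically identical to
#' \eqn{pN/\mu m^2}, so no unit conversion factor is required; the result is
#' in pN \eqn{\mu m}.
#'
#' @param z Indentation depth(s), \eqn{\mu m} (>= 0).
#' @param params A [model_params()] object supplying `E_gel` (Pa), `nu_gel`
#'   and `r_0`.
#' @param E_gel,nu_gel Optional overrides of the gel modulus / Poisson ratio.
#' @return Energy(ies) in pN \eqn{\mu m}.
#' @export
hertz_indentation_energy <- function(z, params = model_params(),
                                     E_gel = params$E_gel,
                                     nu_gel = params$nu_gel) {
  if (any(z < 0)) stop("indentation z must be >= 0")
  (8 / 15) * (E_gel / (1 - nu_gel^2)) * sqrt(params$r_0 / 2) * z^(5 / 2)
}

#' Fit the adhesion / repulsion energy scalings from simulation summaries
#'
#' During monolayer growth the adhesive and repulsive energies scale as
#' \eqn{E_{adh} = \alpha F_{foci}^2 N_{cells}} and
#' \eqn{E_{rep} = (\beta_0 + \beta_1 F_{foci}) N_{cells}^2}
#' (with area and cell number interchangeable through
#' \eqn{N_{cells} = A/A_0}).  This fits both laws by least squares on frame
#' records from simulation sweeps at several rupture forces, and also
#' reports the free power-law exponents used for model checking: the
#' exponent of \eqn{F_{foci}} in \eqn{E_{adh}/N_{cells}} (across runs) and
#' the exponent of \eqn{N_{cells}} in \eqn{E_{rep}} (within runs, averaged).
#'
#' @param frames A `data.frame` with one row per recorded frame and columns
#'   `run` (run identifier), `F_foci` (the run's measured focus force, pN),
#'   `N_cells`, `E_adh`, `E_rep` (pN \eqn{\mu m}).  [sweep_summary()]
#'   produces this format.
#' @param N_min,N_max Frame window (cell counts) used for the fits; defaults
#'   8 (the focus-force plateau onset) to `Inf`.
#' @param settle Minimum time (min) since the last division for a frame to
#'   count as quasi-static; frames younger than this are still relaxing the
#'   septation transient and are dropped when the `youngest_age` column is
#'   present.  Default 1 min, about ten mechanical relaxation times of an
#'   overlapping ball pair at the default parameters.
#' @return An object of class `"scaling_fit"`: coefficients `alpha`,
#'   `beta0`, `beta1` with standard errors, free exponents `exponent_adh`
#'   and `exponent_rep`, fit diagnostics and the design actually used.
#' @export
fit_energy_scalings <- function(frames, N_min = 8, N_max = Inf, settle = 1) {
  req <- c("run", "F_foci", "N_cells", "E_adh", "E_rep")
  if (!all(req %in% names(frames))) {
    stop("frames must have columns: ", paste(req, collapse = ", "))
  }
  fr <- frames[frames$N_cells >= N_min & frames$N_cells <= N_max &
                 frames$F_foci > 0, , drop = FALSE]
  if ("youngest_age" %in% names(fr)) {
    fr <- fr[fr$youngest_age >= settle, , drop = FALSE]
  }
  if (!nrow(fr)) stop("no frames in the requested N_cells window")
  runs <- unique(fr$run)
  n_forces <- length(unique(signif(fr$F_foci, 6)))

  fit_a <- stats::lm(E_adh ~ 0 + I(F_foci^2 * N_cells), data = fr)
  alpha <- unname(stats::coef(fit_a)[1])
  alpha_se <- unname(sqrt(diag(stats::vcov(fit_a)))[1])

  if (n_forces < 2) {
    stop("degenerate design: at least two distinct F_foci values are ",
         "required to separate beta0 and beta1")
  }
  fit_b <- stats::lm(E_rep ~ 0 + I(N_cells^2) + I(F_foci * N_cells^2),
                     data = fr)
  beta <- unname(stats::coef(fit_b))
  beta_se <- unname(sqrt(diag(stats::vcov(fit_b))))

  # free exponents: E_adh/N vs F_foci across run medians; E_rep vs N per run
  per_run <- do.call(rbind, lapply(runs, function(r) {
    g <- fr[fr$run == r, , drop = FALSE]
    data.frame(
      run = r, F_foci = g$F_foci[1],
      med_eadh_per_cell = stats::median(g$E_adh / g$N_cells),
      slope_rep = if (length(unique(g$N_cells)) >= 2 && all(g$E_rep > 0)) {
        unname(stats::coef(stats::lm(log(E_rep) ~ log(N_cells), data = g))[2])
      } else NA_real_
    )
  }))
  exponent_adh <- if (n_forces >= 2) {
    unname(stats::coef(stats::lm(
      log(med_eadh_per_cell) ~ log(F_foci), data = per_run
    ))[2])
  } else NA_real_
  exponent_rep <- mean(per_run$slope_rep, na.rm = TRUE)

  out <- list(
    alpha = alpha, alpha_se = alpha_se,
    beta0 = beta[1], beta0_se = beta_se[1],
    beta1 = beta[2], beta1_se = beta_se[2],
    exponent_adh = exponent_adh, exponent_rep = exponent_rep,
    r2_adh = summary(fit_a)$r.squared, r2_rep = summary(fit_b)$r.squared,
    n_frames = nrow(fr), n_runs = length(runs), n_forces = n_forces,
    per_run = per_run
  )
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit>\n")
  cat(sprintf("  E_adh = alpha F_foci^2 N : alpha = %.4g (se %.2g), R2 = %.3f\n",
              x$alpha, x$alpha_se, x$r2_adh))
  cat(sprintf("  E_rep = (b0 + b1 F) N^2  : b0 = %.4g (se %.2g), b1 = %.4g (se %.2g), R2 = %.3f\n",
              x$beta0, x$beta0_se, x$beta1, x$beta1_se, x$r2_rep))
  cat(sprintf("  free exponents: F_foci in E_adh/N = %.3f; N in E_rep = %.3f\n",
              x$exponent_adh, x$exponent_rep))
  cat(sprintf("  design: %d runs, %d distinct forces, %d frames\n",
              x$n_runs, x$n_forces, x$n_frames))
  invisible(x)
}

#' Construct a scaling-fit object from known coefficients
#'
#' Convenience constructor used when the scaling coefficients are supplied
#' (e.g. from a previous [fit_energy_scalings()]) rather than refitted.
#'
#' @param alpha,beta0,beta1 Scaling coefficients (see
#'   [fit_energy_scalings()]).
#' @return A `"scaling_fit"` object with `NA` diagnostics.
#' @export
scaling_fit <- function(alpha, beta0, beta1) {
  out <- list(
    alpha = alpha, alpha_se = NA_real_, beta0 = beta0, beta0_se = NA_real_,
    beta1 = beta1, beta1_se = NA_real_, exponent_adh = NA_real_,
    exponent_rep = NA_real_, r2_adh = NA_real_, r2_rep = NA_real_,
    n_frames = 0L, n_runs = 0L, n_forces = 0L, per_run = NULL
  )
  class(out) <- "scaling_fit"
  out
}

#' Parameters of the 2D-to-3D transition theory
#'
#' Bundles the constants of the monolayer-to-multilayer energy balance: the
#' critical gel indentation `z`, the link-work coefficient `gamma` (the work
#' to extend the adhesive links vertically is \eqn{W = \gamma z F_{foci}}),
#' the gel elasticity and the cell footprint.  The surface saving when one
#' bacterium leaves the plane is \eqn{\delta A = z r_0}, always computed,
#' never set independently.
#'
#' @param z Critical indentation (\eqn{\mu m}, > 0); default 0.1.
#' @param gamma Dimensionless link-work coefficient; default 1.
#' @param params A [model_params()] supplying defaults for the remaining
#'   fields.
#' @param E_gel,nu_gel,A_0,r_0 Optional overrides.
#' @return An object of class `"transition_params"`.
#' @export
transition_params <- function(z = 0.1, gamma = 1, params = model_params(),
                              E_gel = params$E_gel, nu_gel = params$nu_gel,
                              A_0 = params$A_0, r_0 = params$r_0) {
  if (!(z > 0)) stop("critical indentation z must be > 0")
  tp <- list(z = z, gamma = gamma, E_gel = E_gel, nu_gel = nu_gel,
             A_0 = A_0, r_0 = r_0, delta_A = z * r_0)
  class(tp) <- "transition_params"
  tp
}

tp_hertz <- function(tp, E_gel) {
  (8 / 15) * (E_gel / (1 - tp$nu_gel^2)) * sqrt(tp$r_0 / 2) * tp$z^(5 / 2)
}

#' Closed-form colony size at the monolayer-to-multilayer transition
#'
#' Number of bacteria at second-layer onset, obtained by balancing the
#' in-plane energy increase of monolayer growth against the cost for one
#' bacterium to indent the gel and stretch its links vertically:
#' \deqn{N_{2D/3D}(E, F) = \frac{E_g(E, z) + \gamma z F - \alpha F^2 z r_0}
#'   {A_0 (2 z r_0 + A_0)(\beta_0 + \beta_1 F)}}
#'
#' @param E_gel Young modulus of the soft gel (Pa).
#' @param F_foci Force at adhesion foci (pN).
#' @param tp A [transition_params()] object.
#' @param sf A [scaling_fit()] / [fit_energy_scalings()] object.
#' @return A list with `N` (real-valued), `N_cells` (its ceiling) and
#'   `immediate` (`TRUE` when the numerator is non-positive, i.e. the
#'   transition happens immediately, N <= 0).
#' @export
predict_transition_size <- function(E_gel, F_foci, tp, sf) {
  stopifnot(inherits(tp, "transition_params"), inherits(sf, "scaling_fit"))
  den <- tp$A_0 * (2 * tp$z * tp$r_0 + tp$A_0) * (sf$beta0 + sf$beta1 * F_foci)
  if (any(den <= 0)) stop("non-positive denominator: check beta coefficients")
  num <- tp_hertz(tp, E_gel) + tp$gamma * tp$z * F_foci -
    sf$alpha * F_foci^2 * tp$z * tp$r_0
  N <- num / den
  list(N = N, N_cells = ceiling(N), immediate = N <= 0)
}

#' Energy increments of in-plane vs out-of-plane colony growth
#'
#' Compares, at colony area `A`, growing by `d_A` entirely within the
#' monolayer against sending one bacterium into the third dimension:
#' \deqn{\Delta_{2D} = E_{colo}(A + dA) - E_{colo}(A)}
#' \deqn{\Delta_{3D} = \Delta_{2D}(A \to A + dA - \delta A) + E_g -
#'   E^0_{rep}(A) + W}
#' with \eqn{E_{colo}(A) = \alpha F^2 A + (\beta_0+\beta_1 F)A^2}, the mean
#' per-cell repulsion \eqn{E^0_{rep}(A) = (\beta_0+\beta_1 F) A A_0} and the
#' vertical link work \eqn{W = \gamma z F}.  The transition sits where the
#' two increments are equal; treating `d_A` and `delta_A` as first-order
#' infinitesimals, the equality locus is exactly the closed form of
#' [predict_transition_size()] (see [transition_size_from_balance()]).
#'
#' @param A Colony area (\eqn{\mu m^2}).
#' @param d_A Area increment (\eqn{\mu m^2}); the natural discrete choice is
#'   one cell footprint `A_0`.
#' @param F_foci Force at adhesion foci (pN).
#' @param tp A [transition_params()].
#' @param sf A scaling-fit object.
#' @param E_gel Young modulus (Pa); defaults to the one in `tp`.
#' @return A list with `delta_2D` and `delta_3D` (pN \eqn{\mu m}).
#' @export
delta_energy_balance <- function(A, d_A, F_foci, tp, sf, E_gel = tp$E_gel) {
  stopifnot(A > 0, d_A > 0)
  beta <- sf$beta0 + sf$beta1 * F_foci
  E_colo <- function(a) sf$alpha * F_foci^2 * a + beta * a^2
  d2 <- E_colo(A + d_A) - E_colo(A)
  d3 <- (E_colo(A + d_A - tp$delta_A) - E_colo(A)) +
    tp_hertz(tp, E_gel) - beta * A * tp$A_0 + tp$gamma * tp$z * F_foci
  list(delta_2D = d2, delta_3D = d3)
}

#' Transition size as the root of the linearized energy balance
#'
#' Solves \eqn{\Delta_{2D} = \Delta_{3D}} for the colony area numerically,
#' with both increments expanded to first order in `d_A` and `delta_A` (the
#' same approximation under which the closed form is derived), and returns
#' `N = A/A_0`.  Serves as an independent consistency check of
#' [predict_transition_size()].
#'
#' @inheritParams delta_energy_balance
#' @return The real-valued transition size `N`.
#' @export
transition_size_from_balance <- function(F_foci, tp, sf, E_gel = tp$E_gel) {
  beta <- sf$beta0 + sf$beta1 * F_foci
  gap <- function(A) {
    (sf$alpha * F_foci^2 + 2 * beta * A) * tp$delta_A +
      beta * A * tp$A_0 - tp_hertz(tp, E_gel) - tp$gamma * tp$z * F_foci
  }
  hi <- tp$A_0
  while (gap(hi) < 0 && hi < 1e12) hi <- hi * 2
  if (gap(hi) < 0) stop("no balance root found: energy gap never changes sign")
  if (gap(0) > 0) return(0)
  stats::uniroot(gap, c(0, hi), tol = 1e-12)$root / tp$A_0
}

#' Infer the adhesion-focus force from an observed transition size
#'
#' Inverts the closed-form transition size: finds the force `F_foci` at
#' which [predict_transition_size()] equals the observed number of bacteria
#' at second-layer onset, by bracketed root finding on a verified monotone
#' branch.  This is how adhesion forces are estimated in experiments where
#' they cannot be measured directly (e.g. glass-agarose), from a simple
#' count at the onset of the second layer plus the gel Young modulus.
#'
#' @param N_obs Observed colony size at second-layer onset (cells); may
#'   carry uncertainty through `N_sem`.
#' @param E_gel Young modulus of the gel (Pa).
#' @param tp A [transition_params()].
#' @param sf A scaling-fit object.
#' @param F_range Force bracket searched (pN).
#' @param N_sem Optional standard error on `N_obs`; when given, the
#'   inversion is repeated at `N_obs - N_sem` and `N_obs + N_sem` to
#'   propagate an interval.
#' @return A list with `F_foci` (pN) and, when `N_sem` is supplied,
#'   `F_lower`/`F_upper`.
#' @export
infer_foci_force <- function(N_obs, E_gel, tp, sf,
                             F_range = c(1e-6, 500), N_sem = NULL) {
  grid <- seq(F_range[1], F_range[2], length.out = 512)
  Ns <- predict_transition_size(E_gel, grid, tp, sf)$N
  dN <- diff(Ns)
  if (!(all(dN <= 0) || all(dN >= 0))) {
    # restrict to the first monotone branch from the lower end
    turn <- which(diff(sign(dN)) != 0)[1]
    stop("N_2D/3D is not monotone in F_foci over the requested range; ",
         "restrict F_range to a monotone branch (turning point near F = ",
         signif(grid[turn + 1], 4), " pN)")
  }
  rng <- range(Ns)
  solve_one <- function(target) {
    if (target < rng[1] || target > rng[2]) {
      stop("N_obs = ", target, " outside the attainable range [",
           signif(rng[1], 6), ", ", signif(rng[2], 6),
           "] over the given F_range")
    }
    stats::uniroot(
      function(f) predict_transition_size(E_gel, f, tp, sf)$N - target,
      interval = F_range, tol = 1e-10
    )$root
  }
  out <- list(F_foci = solve_one(N_obs))
  if (!is.null(N_sem)) {
    ends <- sort(c(solve_one(N_obs - N_sem), solve_one(N_obs + N_sem)))
    out$F_lower <- ends[1]
    out$F_upper <- ends[2]
  }
  out
}

#' Fit the transition-theory constants z and gamma from observations
#'
#' Least-squares estimate of the critical indentation `z` and the link-work
#' coefficient `gamma` from observed `(E_gel, F_foci, N_2D/3D)` tuples,
#' mirroring the two-parameter fit of the transition curve to experimental
#' data.
#'
#' @param obs A `data.frame` with columns `E_gel` (Pa), `F_foci` (pN) and
#'   `N` (cells at second-layer onset).
#' @param sf A scaling-fit object.
#' @param params A [model_params()] for `A_0`, `r_0`, `nu_gel`.
#' @param start Starting values `c(z, gamma)`.
#' @return A [transition_params()] with the fitted `z` and `gamma`, plus an
#'   `rss` attribute.
#' @export
fit_transition_constants <- function(obs, sf, params = model_params(),
                                     start = c(z = 0.1, gamma = 1)) {
  stopifnot(all(c("E_gel", "F_foci", "N") %in% names(obs)), nrow(obs) >= 2)
  objective <- function(par) {
    if (par[1] <= 0) return(1e12)
    tp <- transition_params(z = par[1], gamma = par[2], params = params)
    pred <- predict_transition_size(obs$E_gel, obs$F_foci, tp, sf)$N
    sum((pred - obs$N)^2)
  }
  fit <- stats::optim(start, objective, method = "Nelder-Mead")
  tp <- transition_params(z = unname(fit$par[1]), gamma = unname(fit$par[2]),
                          params = params)
  attr(tp, "rss") <- fit$value
  tp
}
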