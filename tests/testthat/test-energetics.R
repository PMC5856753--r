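p0 <- model_params()

test_that("adhesion energy matches adaptive quadrature of the WLC force", {
  w <- make_fixture("single_free", p0)
  expect_equal(adhesion_energy(w, p0)$total, 0)

  ext <- p0$L_0 / 2
  w$links <- data.frame(
    cell_id = 1L, ball_index = 1L, frac = -0.5, lat = 0,
    anchor_x = -w$cells$d_c / 2 - ext, anchor_y = 0, created_at = 0,
    pole_tag = "old", rigid = FALSE
  )
  quad <- stats::integrate(function(L) abs(wlc_link_force(L, p0)), 0, ext,
                           rel.tol = 1e-12)$value
  expect_equal(adhesion_energy(w, p0)$total, quad, tolerance = 1e-8)
  # linear in kT
  p2 <- p0; p2$kT <- 2 * p0$kT
  expect_equal(adhesion_energy(w, p2)$total, 2 * quad, tolerance = 1e-8)
})

test_that("repulsion energy counts each overlapping pair once", {
  w <- make_fixture("chain8", p0)  # non-overlapping
  expect_equal(repulsion_energy(w, p0)$total, 0)

  # exactly one ball pair at separation r_0/2
  cells <- rbind(new_cell(1L, 0, 0, 0, 4),
                 new_cell(2L, 4 + p0$r_0 / 2, 0, 0, 4))
  w2 <- world_state(cells)
  er <- repulsion_energy(w2, p0)
  expect_equal(er$total, 0.5 * p0$k_rep * (p0$r_0 / 2)^2)
  expect_equal(unname(er$per_cell["1"]), er$total / 2)
})

test_that("minus the energy gradient reproduces the repulsive force", {
  # displace one whole cell (rigid translation of its 6 balls); only one
  # ball pair overlaps, so dE/dx equals the pair force along the axis
  f_of_gap <- function(gap) {
    cells <- rbind(new_cell(1L, 0, 0, 0, 4),
                   new_cell(2L, 4 + gap, 0, 0, 4))
    repulsion_energy(world_state(cells), p0)$total
  }
  gap <- 0.6 * p0$r_0
  h <- 1e-6
  grad <- (f_of_gap(gap + h) - f_of_gap(gap - h)) / (2 * h)
  expect_equal(-grad, cell_cell_force(gap, p0), tolerance = 1e-5)
})

test_that("Hertz energy matches its integrand and the 5/2 power law", {
  expect_equal(hertz_indentation_energy(0, p0), 0)
  z <- 0.2
  quad <- stats::integrate(
    function(zp) (4 / 3) * (p0$E_gel / (1 - p0$nu_gel^2)) *
      sqrt(p0$r_0 / 2) * zp^1.5,
    0, z, rel.tol = 1e-12
  )$value
  expect_equal(hertz_indentation_energy(z, p0), quad, tolerance = 1e-8)
  expect_equal(hertz_indentation_energy(2 * z, p0) /
                 hertz_indentation_energy(z, p0), 2^2.5)
  zz <- 10^seq(-2, 0, length.out = 50)
  slope <- stats::coef(stats::lm(log(hertz_indentation_energy(zz, p0)) ~
                                   log(zz)))[2]
  expect_equal(unname(slope), 2.5, tolerance = 1e-6)
  expect_error(hertz_indentation_energy(-0.1, p0), ">= 0")
})

test_that("scaling fit recovers known coefficients from noisy summaries", {
  alpha <- 0.004; beta0 <- 0.02; beta1 <- 5e-4
  set.seed(7)
  frames <- do.call(rbind, lapply(1:9, function(r) {
    ff <- c(4, 8, 16)[(r - 1) %% 3 + 1]
    N <- seq(8, 30, by = 2)
    data.frame(
      run = paste0("r", r), F_foci = ff, N_cells = N,
      E_adh = alpha * ff^2 * N * (1 + stats::rnorm(length(N), 0, 0.01)),
      E_rep = (beta0 + beta1 * ff) * N^2 *
        (1 + stats::rnorm(length(N), 0, 0.01))
    )
  }))
  sf <- fit_energy_scalings(frames)
  expect_equal(sf$alpha, alpha, tolerance = 0.05)
  expect_equal(sf$beta0, beta0, tolerance = 0.05)
  expect_equal(sf$beta1, beta1, tolerance = 0.05)
  expect_equal(sf$exponent_adh, 2, tolerance = 0.05)
  expect_equal(sf$exponent_rep, 2, tolerance = 0.05)
  # exact linearity: scaling the adhesion data scales alpha
  frames2 <- frames; frames2$E_adh <- 3 * frames2$E_adh
  expect_equal(fit_energy_scalings(frames2)$alpha, 3 * sf$alpha,
               tolerance = 1e-12)
  # a single rupture force cannot separate beta0 from beta1
  expect_error(fit_energy_scalings(frames[frames$F_foci == 4, ]),
               "degenerate")
})

test_that("closed-form transition size matches independent substitution", {
  sf <- scaling_fit(alpha = 0.004, beta0 = 0.02, beta1 = 5e-4)
  tp <- transition_params(z = 0.12, gamma = 1.3, params = p0)
  for (Ff in c(0, 5, 20, 80)) {
    res <- predict_transition_size(15000, Ff, tp, sf)
    # independent symbolic substitution, written out term by term
    Eg <- (8 / 15) * (15000 / (1 - p0$nu_gel^2)) * sqrt(p0$r_0 / 2) *
      0.12^2.5
    num <- Eg + 1.3 * 0.12 * Ff - 0.004 * Ff^2 * 0.12 * p0$r_0
    den <- p0$A_0 * (2 * 0.12 * p0$r_0 + p0$A_0) * (0.02 + 5e-4 * Ff)
    expect_equal(res$N, num / den, tolerance = 1e-10)
  }
  # F_foci = 0 closed-form limit
  res0 <- predict_transition_size(15000, 0, tp, sf)
  Eg <- rodcolony:::tp_hertz(tp, 15000)
  expect_equal(res0$N, Eg / (p0$A_0 * (2 * 0.12 * p0$r_0 + p0$A_0) * 0.02),
               tolerance = 1e-12)
  # numerator root: gamma z F = alpha F^2 z r_0 - E_g  =>  N = 0
  Fstar <- stats::uniroot(
    function(f) 1.3 * 0.12 * f - 0.004 * f^2 * 0.12 * p0$r_0 + Eg,
    c(1, 1e4)
  )$root
  expect_equal(predict_transition_size(15000, Fstar, tp, sf)$N, 0,
               tolerance = 1e-6)
  expect_true(predict_transition_size(
    15000, Fstar * 1.01, tp, sf
  )$immediate)
})

test_that("the linearized energy balance root equals the closed form", {
  sf <- scaling_fit(alpha = 0.004, beta0 = 0.02, beta1 = 5e-4)
  for (z in c(0.05, 0.1, 0.2)) {
    for (Ff in c(2, 10, 40)) {
      tp <- transition_params(z = z, gamma = 1, params = p0)
      closed <- predict_transition_size(tp$E_gel, Ff, tp, sf)$N
      balance <- transition_size_from_balance(Ff, tp, sf)
      expect_equal(balance, closed, tolerance = 1e-6)
    }
  }
})

test_that("discrete balance degenerates to equality without 3D costs", {
  sf <- scaling_fit(alpha = 0.004, beta0 = 0, beta1 = 0)
  # beta = 0 kills the released repulsion term; z -> 0 kills deltaA, the
  # gel cost and the link work
  tp <- transition_params(z = 1e-9, gamma = 0, params = p0)
  d <- delta_energy_balance(A = 50, d_A = p0$A_0, F_foci = 10, tp, sf)
  expect_equal(d$delta_2D, d$delta_3D, tolerance = 1e-6)
  # Delta_2D increases with area for positive coefficients
  sf2 <- scaling_fit(alpha = 0.004, beta0 = 0.02, beta1 = 5e-4)
  tp2 <- transition_params(z = 0.1, params = p0)
  d2 <- vapply(c(10, 50, 100, 200), function(A) {
    delta_energy_balance(A, p0$A_0, 10, tp2, sf2)$delta_2D
  }, numeric(1))
  expect_true(all(diff(d2) > 0))
})

test_that("force inference inverts the transition size", {
  sf <- scaling_fit(alpha = 0.0005, beta0 = 0.02, beta1 = 5e-4)
  tp <- transition_params(z = 0.1, gamma = 1, params = p0)
  for (Fstar in c(5, 40, 120)) {
    N <- predict_transition_size(15000, Fstar, tp, sf)$N
    inv <- infer_foci_force(N, 15000, tp, sf, F_range = c(1e-6, 200))
    expect_equal(inv$F_foci, Fstar, tolerance = 1e-6)
  }
  # uncertainty propagation brackets the point estimate
  N40 <- predict_transition_size(15000, 40, tp, sf)$N
  inv <- infer_foci_force(N40, 15000, tp, sf, F_range = c(1e-6, 200),
                          N_sem = 0.05 * N40)
  expect_true(inv$F_lower < inv$F_foci && inv$F_foci < inv$F_upper)
  # out-of-range target errors with the attainable interval
  expect_error(infer_foci_force(1e9, 15000, tp, sf, F_range = c(1e-6, 200)),
               "attainable")
  # on a decreasing branch, inference is antitone in N_obs
  grid <- seq(1e-6, 200, length.out = 64)
  Ns <- predict_transition_size(15000, grid, tp, sf)$N
  expect_true(all(diff(Ns) < 0))
  Nobs <- seq(min(Ns) * 1.05, max(Ns) * 0.95, length.out = 8)
  Fs <- vapply(Nobs, function(n) {
    infer_foci_force(n, 15000, tp, sf, F_range = c(1e-6, 200))$F_foci
  }, numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("transition constants are recoverable from observation tuples", {
  sf <- scaling_fit(alpha = 0.0005, beta0 = 0.02, beta1 = 5e-4)
  tp_true <- transition_params(z = 0.15, gamma = 2, params = p0)
  obs <- expand.grid(E_gel = c(4000, 15000), F_foci = c(10, 40, 100))
  obs$N <- predict_transition_size(obs$E_gel, obs$F_foci, tp_true, sf)$N
  tp_fit <- fit_transition_constants(obs, sf, p0, start = c(z = 0.1,
                                                            gamma = 1))
  expect_equal(tp_fit$z, 0.15, tolerance = 0.01)
  expect_equal(tp_fit$gamma, 2, tolerance = 0.05)
  expect_equal(tp_fit$delta_A, tp_fit$z * p0$r_0)
})

test_that("energies are non-negative and additive over disjoint colonies", {
  p <- p0
  traj <- run_simulation(run_config(params = p, mode = "polar", seed = 21,
                                    n_cells_stop = 6))
  w <- last_world(traj)
  ea <- adhesion_energy(w, p); er <- repulsion_energy(w, p)
  expect_gte(min(ea$per_cell), 0)
  expect_gte(min(er$per_cell), 0)
  # duplicate the colony far away: totals double
  w2 <- w
  shifted_cells <- w$cells
  shifted_cells$id <- shifted_cells$id + 1000L
  shifted_cells$cm_x <- shifted_cells$cm_x + 500
  shifted_links <- w$links
  shifted_links$cell_id <- shifted_links$cell_id + 1000L
  shifted_links$anchor_x <- shifted_links$anchor_x + 500
  w2$cells <- rbind(w$cells, shifted_cells)
  w2$links <- rbind(w$links, shifted_links)
  expect_equal(adhesion_energy(w2, p)$total, 2 * ea$total, tolerance = 1e-9)
  expect_equal(repulsion_energy(w2, p)$total, 2 * er$total, tolerance = 1e-9)
})
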