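p0 <- model_params()

test_that("elongation is exactly exponential and CM-symmetric", {
  w <- make_fixture("single_free", p0)
  n_steps <- round(log(2) / p0$g / p0$dt)
  p <- model_params(dt = log(2) / p0$g / n_steps)  # integer steps per doubling
  d0 <- w$cells$d_c
  for (i in seq_len(n_steps)) w <- elongate_cells(w, p)
  expect_equal(w$cells$d_c, 2 * d0, tolerance = 1e-12)
  expect_identical(w$cells$cm_x, 0)
  expect_identical(w$cells$cm_y, 0)
})

test_that("a rigid old-pole pin keeps the pole fixed while the CM advances", {
  w <- make_fixture("single_oldpole_pinned", p0)
  pole0 <- ball_positions(w$cells[1, ], p0)[1, ]
  d0 <- w$cells$d_c
  for (i in 1:200) w <- elongate_cells(w, p0)
  expect_equal(ball_positions(w$cells[1, ], p0)[1, ], pole0,
               tolerance = 1e-12)
  dL <- w$cells$d_c - d0
  expect_equal(w$cells$cm_x, dL / 2, tolerance = 1e-12)
})

test_that("division waiting times follow the exponential law", {
  # 2000 cells held at the division length (g = 0), stepped for 2 min
  p <- model_params(g = 1e-12, dt = 0.25)
  cells <- do.call(rbind, lapply(1:2000, function(i) {
    new_cell(i, cm_x = 10 * i, d_c = p$d_L)  # far apart: no interactions
  }))
  w <- world_state(cells)
  set.seed(11)
  t_tot <- 2
  for (i in seq_len(t_tot / p$dt)) w <- attempt_divisions(w, p)
  frac <- 1 - sum(w$cells$d_c == p$d_L) / 2000
  expected <- 1 - exp(-p$division_rate * t_tot)
  ci <- stats::binom.test(round(frac * 2000), 2000)$conf.int
  expect_true(expected >= ci[1] && expected <= ci[2])
})

test_that("oversized cells divide deterministically, conserving length", {
  p <- p0
  w <- world_state(new_cell(7L, 1, 2, pi / 7, 1.31 * p$d_L))
  set.seed(1)
  w2 <- attempt_divisions(w, p)
  expect_equal(nrow(w2$cells), 2L)
  expect_equal(sum(w2$cells$d_c), 1.31 * p$d_L, tolerance = 1e-12)
  expect_setequal(w2$cells$parent_id, 7L)
  # each daughter axis points old -> new: daughter A keeps theta, B flips
  expect_equal(sort((w2$cells$theta - pi / 7) %% (2 * pi)), c(0, pi),
               tolerance = 1e-12)
  ev <- w2$events[[1]]
  expect_identical(ev$type, "division")
  expect_identical(ev$mother_id, 7L)
})

test_that("daughters inherit pole links and septum poles start bare", {
  p <- p0
  w <- world_state(new_cell(1L, 0, 0, 0, 1.4 * p$d_L,
                            old_pole_generation = 3L))
  # five old-pole links, none at the new pole
  w$links <- data.frame(
    cell_id = 1L, ball_index = 1L, frac = -0.5 + (0:4) * 1e-3, lat = 0,
    anchor_x = -1.4 * p$d_L / 2, anchor_y = 0, created_at = 0,
    pole_tag = "old", rigid = FALSE
  )
  att_before <- rodcolony:::link_attachments(w$cells, w$links)
  set.seed(2)
  w2 <- attempt_divisions(w, p)
  expect_equal(nrow(w2$cells), 2L)
  dA <- w2$cells[w2$cells$old_pole_generation == 4L, ]
  dB <- w2$cells[w2$cells$old_pole_generation == 1L, ]
  expect_equal(nrow(dA), 1L)
  expect_equal(nrow(dB), 1L)
  # all five links follow the old-pole daughter, still tagged old pole
  expect_true(all(w2$links$cell_id == dA$id))
  expect_true(all(w2$links$pole_tag == "old"))
  expect_true(all(w2$links$ball_index == 1L))
  expect_identical(w2$events[[1]]$inherited_link_counts, c(5L, 0L))
  # attachment world points are preserved across the split
  att_after <- rodcolony:::link_attachments(w2$cells, w2$links)
  expect_equal(att_after, att_before, tolerance = 1e-12)
})

test_that("link creation saturates at n_l per ball and stays polar", {
  p <- model_params(k_on = 50, g = 1e-12)  # fast creation, frozen length
  w <- make_fixture("single_free", p)
  set.seed(3)
  for (i in 1:600) w <- spawn_links(w, p, "polar")
  counts <- table(w$links$ball_index)
  expect_true(all(names(counts) %in% c("1", "6")))
  expect_true(all(counts <= p$n_l))
  expect_equal(unname(counts["1"]), p$n_l)  # saturated after 3 min
  # polar support: attachments within r_0/2 of a pole center
  att <- rodcolony:::link_attachments(w$cells, w$links)
  d_old <- sqrt((att[, 1] + w$cells$d_c / 2)^2 + att[, 2]^2)
  d_new <- sqrt((att[, 1] - w$cells$d_c / 2)^2 + att[, 2]^2)
  expect_true(all(pmin(d_old, d_new) <= p$r_0 / 2 + 1e-12))
  # uniform mode spreads over all six balls
  w2 <- make_fixture("single_free", p)
  for (i in 1:600) w2 <- spawn_links(w2, p, "uniform")
  expect_setequal(unique(w2$links$ball_index), 1:6)
  expect_true(any(w2$links$pole_tag == "body"))
})

test_that("creation counts for one unsaturated ball are Poisson", {
  # one ball observed over t = 2 min, far from saturation
  p <- model_params(k_on = 2, n_l = 10000L, g = 1e-12, dt = 0.02)
  set.seed(4)
  n_rep <- 400
  counts <- vapply(seq_len(n_rep), function(r) {
    w <- make_fixture("single_free", p)
    for (i in seq_len(2 / p$dt)) w <- spawn_links(w, p, "polar")
    sum(w$links$ball_index == 1L)
  }, numeric(1))
  lambda <- p$k_on * 2
  # discretized Bernoulli scheme: mean n p with p = 1 - exp(-k_on dt)
  lambda_disc <- (2 / p$dt) * (1 - exp(-p$k_on * p$dt))
  expect_equal(mean(counts), lambda_disc,
               tolerance = 3 * sqrt(lambda / n_rep) / lambda)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.25)
})

test_that("unloaded links survive exponentially and break at threshold", {
  p <- model_params(k_off = 0.5, dt = 0.25)
  w <- make_fixture("single_free", p)
  n0 <- 2000
  w$links <- data.frame(
    cell_id = 1L, ball_index = 1L, frac = -0.5, lat = 0,
    anchor_x = rep(-p$d_L / 4, n0), anchor_y = 0, created_at = 0,
    pole_tag = "old", rigid = FALSE
  )
  set.seed(5)
  t_tot <- 2
  for (i in seq_len(t_tot / p$dt)) w <- rupture_links(w, p)
  surv <- nrow(w$links) / n0
  expected <- exp(-p$k_off * t_tot)
  ci <- stats::binom.test(nrow(w$links), n0)$conf.int
  expect_true(expected >= ci[1] && expected <= ci[2])

  # a link stretched past the rupture force disappears the same step
  w2 <- make_fixture("handforce", model_params(F_link = 2.9))
  w2 <- rupture_links(w2, model_params(F_link = 2.9))
  expect_equal(nrow(w2$links), 0L)
})

test_that("loaded links rupture faster by the arctanh hazard ratio", {
  # two large populations at constant tension 0 and F_link/2; their one-step
  # rupture probabilities must match 1 - exp(-rate dt) for Eq-3 rates
  p <- model_params(k_off = 0.4, dt = 0.5)
  Lhalf <- stats::uniroot(
    function(L) abs(wlc_link_force(L, p)) - p$F_link / 2,
    c(1e-9, p$L_0 * (1 - 1e-9)), tol = 1e-14
  )$root
  n0 <- 5000
  mk <- function(ext) {
    w <- make_fixture("single_free", p)
    w$links <- data.frame(
      cell_id = 1L, ball_index = 1L, frac = -0.5, lat = 0,
      anchor_x = rep(-p$d_L / 4 - ext, n0), anchor_y = 0, created_at = 0,
      pole_tag = "old", rigid = FALSE
    )
    w
  }
  set.seed(6)
  gone0 <- n0 - nrow(rupture_links(mk(0), p)$links)
  gone1 <- n0 - nrow(rupture_links(mk(Lhalf), p)$links)
  p_expect0 <- 1 - exp(-p$k_off * p$dt)
  p_expect1 <- 1 - exp(-p$k_off * (1 + atanh(0.5)) * p$dt)
  expect_true(abs(gone0 / n0 - p_expect0) < 3 * sqrt(p_expect0 / n0))
  expect_true(abs(gone1 / n0 - p_expect1) < 3 * sqrt(p_expect1 / n0))
})

test_that("division never orphans links during a colony run", {
  p <- model_params()
  traj <- run_simulation(run_config(params = p, mode = "polar", seed = 9,
                                    n_cells_stop = 12))
  for (f in traj$frames) {
    if (!nrow(f$links)) next
    expect_true(all(f$links$cell_id %in% f$cells$id))
    # attachments stay on the body span at all times
    expect_true(all(abs(f$links$frac) <= 0.5 + 1e-9))
  }
})
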