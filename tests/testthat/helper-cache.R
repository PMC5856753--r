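# Heavy simulation products shared between property and acceptance tests,
# computed once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# rupture-force sweep used by the energy-scaling criteria (9 colonies to 30
# cells: F_link in {2, 4.25, 8} pN x 3 seeds)
get_sweep <- function() {
  cached("sweep", run_sweep(c(2, 4.25, 8), seeds = 1:3,
                            params = model_params(), n_cells_stop = 30))
}

# five default-F_link colonies for the repulsion-energy scaling (seeds 1:3
# reuse the sweep's F_link = 4.25 runs, which are bit-identical)
get_default_runs <- function() {
  cached("default_runs", {
    sw <- get_sweep()
    fr <- sw$frames[sw$frames$F_link == 4.25, , drop = FALSE]
    extra <- run_sweep(4.25, seeds = 4:5, params = model_params(),
                       n_cells_stop = 30)
    fr2 <- extra$frames
    fr2$run <- paste0(fr2$run, "b")
    rbind(fr, fr2)
  })
}

# population of isolated uniform-mode cells for the asymmetry criterion
get_uniform_population <- function(n = 200) {
  cached(paste0("uniform_pop_", n), {
    vapply(seq_len(n), function(s) {
      simulate_isolated_cell(model_params(), "uniform", seed = s)$A_cell
    }, numeric(1))
  })
}

# matched polar / uniform colonies at 30 cells for shape and order
get_mode_comparison <- function(seeds = 1:10) {
  cached("mode_comparison", {
    p <- model_params()
    do.call(rbind, lapply(seeds, function(s) {
      do.call(rbind, lapply(c("polar", "uniform"), function(m) {
        traj <- run_simulation(run_config(params = p, mode = m, seed = s,
                                          n_cells_stop = 30))
        w <- last_world(traj)
        data.frame(seed = s, mode = m,
                   aspect = aspect_ratio(w, params = p),
                   S = nematic_order(w))
      }))
    }))
  })
}

# world_state from the last frame of a trajectory
last_world <- function(traj) {
  f <- traj$frames[[length(traj$frames)]]
  lk <- f$links
  lk$extension <- NULL
  lk$tension <- NULL
  world_state(f$cells, lk, f$time)
}

# founder track (pose per frame) of a trajectory
founder_track <- function(traj, id = 1L) {
  do.call(rbind, lapply(traj$frames, function(f) {
    row <- f$cells[f$cells$id == id, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    data.frame(time = f$time, cm_x = row$cm_x, cm_y = row$cm_y,
               theta = row$theta, d_c = row$d_c)
  }))
}
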