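TRAJ_SCHEMA <- "rodcolony-trajectory v1"

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a trajectory as versioned delimited text
#'
#' The trajectory container is plain text: a header recording the schema
#' version, units, seed, mode, frame cadence and every model parameter,
#' followed by one block per frame.  Each block starts with an `F` record
#' (frame index, time, cell/link counts and the frame observables) and lists
#' one `C` record per cell and one `L` record per link, tab-separated, at
#' full double precision, so `read_trajectory(write_trajectory(x))`
#' reproduces every field exactly.
#'
#' @param traj A [run_simulation()] trajectory.
#' @param path Output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `colony_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "colony_trajectory"))
  cfg <- traj$config
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("# ", TRAJ_SCHEMA),
    "# units: um pN min Pa",
    paste0("# seed: ", cfg$seed),
    paste0("# mode: ", cfg$mode),
    paste0("# frame_interval: ", fmt_num(cfg$frame_interval)),
    paste0("# stop: ", if (!is.null(cfg$t_end)) {
      paste0("t_end=", fmt_num(cfg$t_end))
    } else paste0("n_cells_stop=", cfg$n_cells_stop)),
    sprintf("# param %s = %s", names(cfg$params),
            vapply(cfg$params, fmt_num, "")),
    paste0("# frames: ", length(traj$frames))
  )
  writeLines(hdr, con)
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    writeLines(paste("F", fi, fmt_num(f$time), nrow(f$cells), nrow(f$links),
                     fmt_num(f$E_adh), fmt_num(f$E_rep), fmt_num(f$F_max),
                     fmt_num(f$F_colo), fmt_num(f$area), sep = "\t"), con)
    if (nrow(f$cells)) {
      writeLines(paste("C", f$cells$id, fmt_num(f$cells$cm_x),
                       fmt_num(f$cells$cm_y), fmt_num(f$cells$theta),
                       fmt_num(f$cells$d_c), fmt_num(f$cells$birth_time),
                       f$cells$old_pole_generation, f$cells$parent_id,
                       sep = "\t"), con)
    }
    if (nrow(f$links)) {
      writeLines(paste("L", f$links$cell_id, f$links$ball_index,
                       fmt_num(f$links$frac), fmt_num(f$links$lat),
                       fmt_num(f$links$anchor_x), fmt_num(f$links$anchor_y),
                       fmt_num(f$links$created_at), f$links$pole_tag,
                       as.integer(f$links$rigid), fmt_num(f$links$extension),
                       fmt_num(f$links$tension), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != paste0("# ", TRAJ_SCHEMA)) {
    stop("unsupported trajectory schema: expected '", TRAJ_SCHEMA, "'")
  }
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get1 <- function(key) sub(paste0("^# ", key, ": "), "",
                            grep(paste0("^# ", key, ": "), hdr, value = TRUE))
  pl <- grep("^# param ", hdr, value = TRUE)
  pv <- sub("^# param [^=]+ = ", "", pl)
  pn <- sub(" = .*$", "", sub("^# param ", "", pl))
  params <- do.call(model_params, stats::setNames(as.list(as.numeric(pv)), pn))
  stop_spec <- get1("stop")
  stop_kv <- strsplit(stop_spec, "=", fixed = TRUE)[[1]]
  cfg <- run_config(
    params = params, mode = get1("mode"), seed = as.integer(get1("seed")),
    t_end = if (stop_kv[1] == "t_end") as.numeric(stop_kv[2]) else NULL,
    n_cells_stop = if (stop_kv[1] == "n_cells_stop") {
      as.integer(stop_kv[2])
    } else NULL,
    frame_interval = as.numeric(get1("frame_interval"))
  )
  n_frames <- as.integer(get1("frames"))
  frames <- vector("list", n_frames)
  pos <- 1L
  for (fi in seq_len(n_frames)) {
    if (pos > length(body)) {
      stop("truncated trajectory: frame ", fi, " of ", n_frames, " missing")
    }
    fhead <- strsplit(body[pos], "\t", fixed = TRUE)[[1]]
    if (fhead[1] != "F" || as.integer(fhead[2]) != fi) {
      stop("parse error at frame ", fi, ": malformed frame header")
    }
    nc <- as.integer(fhead[4]); nl <- as.integer(fhead[5])
    if (pos + nc + nl > length(body)) {
      stop("truncated trajectory: frame ", fi, " ends prematurely")
    }
    crows <- body[pos + seq_len(nc)]
    lrows <- if (nl > 0) body[pos + nc + seq_len(nl)] else character()
    cm <- do.call(rbind, strsplit(crows, "\t", fixed = TRUE))
    cells <- if (nc > 0) data.frame(
      id = as.integer(cm[, 2]), cm_x = as.numeric(cm[, 3]),
      cm_y = as.numeric(cm[, 4]), theta = as.numeric(cm[, 5]),
      d_c = as.numeric(cm[, 6]), birth_time = as.numeric(cm[, 7]),
      old_pole_generation = as.integer(cm[, 8]),
      parent_id = suppressWarnings(as.integer(cm[, 9]))
    ) else empty_cells()
    links <- empty_links()
    links$extension <- numeric(); links$tension <- numeric()
    if (nl > 0) {
      lm <- do.call(rbind, strsplit(lrows, "\t", fixed = TRUE))
      links <- data.frame(
        cell_id = as.integer(lm[, 2]), ball_index = as.integer(lm[, 3]),
        frac = as.numeric(lm[, 4]), lat = as.numeric(lm[, 5]),
        anchor_x = as.numeric(lm[, 6]), anchor_y = as.numeric(lm[, 7]),
        created_at = as.numeric(lm[, 8]), pole_tag = lm[, 9],
        rigid = as.logical(as.integer(lm[, 10])),
        extension = as.numeric(lm[, 11]), tension = as.numeric(lm[, 12])
      )
    }
    frames[[fi]] <- list(
      time = as.numeric(fhead[3]), cells = cells, links = links,
      N_cells = nc, E_adh = as.numeric(fhead[6]),
      E_rep = as.numeric(fhead[7]), F_max = as.numeric(fhead[8]),
      F_colo = as.numeric(fhead[9]), area = as.numeric(fhead[10])
    )
    pos <- pos + 1L + nc + nl
  }
  traj <- list(config = cfg, frames = frames)
  class(traj) <- "colony_trajectory"
  traj
}
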