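#' Simulate one persistent-random-walk trajectory
#'
#' Samples a cell path at the frame interval with every step of length
#' exactly `speed * frame_interval` (so the polyline curvilinear speed of
#' the track equals the generating trait up to floating-point rounding).
#' The heading evolves by wrapped-normal increments with SD
#' `1/sqrt(turning_kappa)`; `turning_kappa = Inf` gives a straight track and
#' `turning_kappa = 0` draws a fresh uniform heading every step.
#'
#' @param speed Curvilinear speed, um/h (> 0).
#' @param gen_time_h Duration of the track, hours (at least one frame
#'   interval).
#' @param cfg A [sim_config()] (frame interval, scale, turning_kappa).
#' @param start Starting position, pixels.
#' @param first_frame Frame index of the first point.
#' @return A tibble (`frame`, `x`, `y`) with `round(gen_time_h / interval)`
#'   steps; positions in pixels.
#' @export
simulate_trajectory <- function(speed, gen_time_h, cfg, start = c(0, 0),
                                first_frame = 0L) {
  ivl_h <- cfg$frame_interval_min / 60
  if (gen_time_h < ivl_h) {
    abort("trajectory duration is shorter than one frame interval",
          class = "clonherit_config_error")
  }
  stopifnot(speed > 0)
  n_steps <- max(1L, as.integer(round(gen_time_h / ivl_h)))
  .walk_steps(speed, n_steps, cfg, start, first_frame)
}

# shared path sampler; n_steps already fixed by the caller
.walk_steps <- function(speed, n_steps, cfg, start, first_frame) {
  ivl_h <- cfg$frame_interval_min / 60
  step_px <- speed * ivl_h / cfg$microns_per_pixel
  kappa <- cfg$turning_kappa
  theta0 <- runif(1, 0, 2 * pi)
  theta <- if (is.infinite(kappa)) {
    rep(theta0, n_steps)
  } else if (kappa == 0) {
    runif(n_steps, 0, 2 * pi)
  } else {
    theta0 + cumsum(rnorm(n_steps, sd = 1 / sqrt(kappa)))
  }
  tibble(frame = first_frame + 0:n_steps,
         x = start[[1]] + c(0, cumsum(step_px * cos(theta))),
         y = start[[2]] + c(0, cumsum(step_px * sin(theta))))
}

#' Simulate a full tracking dataset
#'
#' Realises the pedigree trait draws of [simulate_pedigree_traits()] as
#' tracked trajectories under the recording design: families are plated at
#' frame 0 (founders start at a uniformly drawn residual fraction of their
#' cycle), daughters start at their mother's final position and frame
#' (division anchoring), wells and imaging fields are assigned round-robin,
#' and censoring is applied per cell (off-screen exit or death truncate the
#' track at a uniformly drawn frame and suppress the daughters; cells whose
#' division would fall after the last frame are censored at the end of the
#' recording).
#'
#' Identical configurations (including the seed) produce identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list: `track_set` (a [track_set()]) and `ground_truth` (as
#'   [simulate_pedigree_traits()], with per-cell realisation columns
#'   `tracked`, `fate`, `birth_frame`, `end_frame` added).
#' @export
simulate_trackset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  shape <- .pedigree_shape(cfg$n_generations)
  n <- shape$n_nodes
  ivl_h <- cfg$frame_interval_min / 60
  last_frame <- cfg$n_frames - 1L

  gt_rows <- vector("list", cfg$n_founders)
  track_rows <- vector("list", cfg$n_founders)
  for (f in seq_len(cfg$n_founders)) {
    set.seed(family_seed(cfg$seed, f))
    d <- .draw_family_traits(cfg, shape)
    phase <- runif(1)
    pos0 <- c(runif(1, 0, 1330), runif(1, 0, 1030))
    u_off <- runif(n); u_die <- runif(n); u_trunc <- runif(n)

    tracked <- c(TRUE, rep(FALSE, n - 1L))
    fate <- rep(NA_character_, n)
    birth <- rep(NA_integer_, n); endf <- rep(NA_integer_, n)
    start_x <- rep(NA_real_, n); start_y <- rep(NA_real_, n)
    birth[1] <- 0L; start_x[1] <- pos0[1]; start_y[1] <- pos0[2]
    pts <- vector("list", n)

    for (node in seq_len(n)) {
      if (!tracked[node]) next
      gt_h <- d$generation_time$z[node]
      full_steps <- max(1L, as.integer(round(gt_h / ivl_h)))
      if (node == 1L) {
        # plating catches the founder mid-cycle
        full_steps <- max(1L, as.integer(round(phase * full_steps)))
      }
      room <- last_frame - birth[node]
      if (u_off[node] < cfg$p_offscreen) {
        fate[node] <- "off_screen"
        n_obs <- max(1L, as.integer(ceiling(u_trunc[node] * (full_steps - 1L))))
      } else if (u_die[node] < cfg$p_death) {
        fate[node] <- "died"
        n_obs <- max(1L, as.integer(ceiling(u_trunc[node] * (full_steps - 1L))))
      } else if (full_steps <= room) {
        fate[node] <- "divided"
        n_obs <- full_steps
      } else {
        fate[node] <- "censored_at_end"
        n_obs <- room
      }
      n_obs <- min(n_obs, room)
      if (n_obs < 1L) {  # born on (or one frame before) the final frame
        fate[node] <- "censored_at_end"
        pts[[node]] <- tibble(frame = birth[node],
                              x = start_x[node], y = start_y[node])
        endf[node] <- birth[node]
        next
      }
      tr <- .walk_steps(d$speed$z[node], n_obs, cfg,
                        c(start_x[node], start_y[node]), birth[node])
      pts[[node]] <- tr
      endf[node] <- birth[node] + n_obs
      if (fate[node] == "divided" && 2L * node <= n) {
        for (child in c(2L * node, 2L * node + 1L)) {
          tracked[child] <- TRUE
          birth[child] <- endf[node]
          start_x[child] <- tr$x[nrow(tr)]
          start_y[child] <- tr$y[nrow(tr)]
        }
      }
    }

    base <- (f - 1L) * n
    ids <- as.character(base + seq_len(n))
    gt_rows[[f]] <- tibble(
      node = seq_len(n), tracked = tracked, fate = fate,
      birth_frame = birth, end_frame = endf)
    keep <- which(tracked)
    track_rows[[f]] <- bind_rows(
      lapply(keep, function(k) mutate(pts[[k]], cell_id = ids[[k]], .before = 1)))
  }

  truth <- simulate_pedigree_traits(cfg)  # identical trait draws by design
  real <- bind_rows(gt_rows)
  truth$cells <- bind_cols(truth$cells, real[, c("tracked", "fate",
                                                 "birth_frame", "end_frame")])

  tracked_cells <- truth$cells |> filter(.data$tracked)
  lineage <- tracked_cells |>
    transmute(cell_id = .data$cell_id,
              # a tracked cell's mother is untracked only for founders
              mother_id = ifelse(is.na(.data$mother_id), NA_character_,
                                 .data$mother_id),
              fate = .data$fate,
              well_id = .data$well_id, field_id = .data$field_id)
  ts <- track_set(bind_rows(track_rows), lineage,
                  frame_interval_min = cfg$frame_interval_min,
                  microns_per_pixel = cfg$microns_per_pixel,
                  n_frames = cfg$n_frames)
  list(track_set = ts, ground_truth = truth)
}
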