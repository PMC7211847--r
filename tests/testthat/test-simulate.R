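test_that("degenerate variances give every cell exactly the trait mean", {
  cfg <- sim_config(
    n_founders = 20, seed = 1,
    speed = trait_params(mu = 30, a = 0.5, sigma_delta = 0, sigma_s = 0,
                         sigma_u = 0, floor = 0.1),
    generation_time = trait_params(mu = 12, a = 0.5, sigma_delta = 0,
                                   sigma_s = 0, sigma_u = 0))
  gt <- simulate_pedigree_traits(cfg)
  expect_true(all(gt$cells$speed == 30))
  expect_true(all(gt$cells$generation_time == 12))
})

test_that("a = 0 transmits nothing: mother-daughter g covariance is null", {
  cfg <- sim_config(
    n_founders = 2000, seed = 21,
    speed = trait_params(mu = 30, a = 0, sigma_g = 2, sigma_s = 1, sigma_u = 1))
  cells <- simulate_pedigree_traits(cfg)$cells
  mg <- cells$g_speed[cells$generation == 1 & (as.integer(cells$cell_id) %% 7) == 2]
  dg <- cells$g_speed[cells$generation == 2 & (as.integer(cells$cell_id) %% 7) == 4]
  cv <- cov(mg, dg)
  se <- sd(mg * dg) / sqrt(length(mg))
  expect_lt(abs(cv), 3 * se)
})

test_that("relationship covariances match the closed forms by brute force", {
  # a = 0.9, sigma_g^2 = 4, sigma_s^2 = 1, sigma_u^2 = 3 (sigma_z^2 = 8):
  # expected slopes 0.45 (mother-daughter), 0.53 (sister), 0.328 (cousin)
  cfg <- sim_config(
    n_founders = 30000, seed = 22, n_wells = 1, fields_per_well = 1,
    speed = trait_params(mu = 50, a = 0.9, sigma_g = 2, sigma_s = 1,
                         sigma_u = sqrt(3)))
  cells <- simulate_pedigree_traits(cfg)$cells
  # heap layout within each 7-cell family: founder 1; daughters 2,3;
  # granddaughters 4,5 (under 2) and 6,7 (under 3)
  node <- (as.integer(cells$cell_id) - 1) %% 7 + 1
  z <- cells$speed
  slope_of <- function(i, j) {
    x <- z[node == i]; y <- z[node == j]
    est <- cov(x, y) / var(x)
    se <- sd((x - mean(x)) * (y - mean(y))) / sqrt(length(x)) / var(x)
    c(est, se)
  }
  md <- slope_of(2, 4)
  expect_lt(abs(md[1] - 0.45), 3 * md[2])
  ss <- slope_of(2, 3)
  expect_lt(abs(ss[1] - 0.53), 3 * ss[2])
  cc <- slope_of(4, 6)
  expect_lt(abs(cc[1] - 0.328), 3 * cc[2])
})

test_that("the heritable component is stationary across generations", {
  cfg <- sim_config(
    n_founders = 5000, seed = 23,
    speed = trait_params(mu = 40, a = 0.9, sigma_g = 2, sigma_s = 1, sigma_u = 1))
  cells <- simulate_pedigree_traits(cfg)$cells
  v <- tapply(cells$g_speed, cells$generation, var)
  # variance of g should be ~4 in every generation (MC tolerance)
  expect_true(all(abs(v - 4) / 4 < 0.15))
})

test_that("trajectories realise the generating speed exactly", {
  cfg <- sim_config(seed = 31)
  set.seed(1)
  # ballistic limit: straight track, net displacement equals path length
  cfg_inf <- sim_config(seed = 31, turning_kappa = Inf)
  tr <- simulate_trajectory(30, 10, cfg_inf, start = c(100, 100))
  path <- oracle_path_length(tr$x, tr$y, cfg$microns_per_pixel)
  net <- cfg$microns_per_pixel *
    sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
  expect_equal(net, path, tolerance = 1e-9)

  # any finite kappa: curvilinear speed equals the generating value
  for (kappa in c(0, 0.5, 5, 50)) {
    cfg_k <- sim_config(seed = 31, turning_kappa = kappa)
    tr <- simulate_trajectory(37.55, 14, cfg_k)
    hours <- (nrow(tr) - 1) * cfg_k$frame_interval_min / 60
    speed <- oracle_path_length(tr$x, tr$y, cfg_k$microns_per_pixel) / hours
    expect_equal(speed, 37.55, tolerance = 1e-9)
  }

  expect_error(simulate_trajectory(30, 0.1, cfg),
               class = "clonherit_config_error")
})

test_that("uncorrelated headings give diffusive mean-squared displacement", {
  cfg <- sim_config(seed = 32, turning_kappa = 0, microns_per_pixel = 1)
  set.seed(32)
  n_steps <- 25
  L <- 10 * cfg$frame_interval_min / 60  # step length, um
  r2 <- replicate(10000, {
    tr <- simulate_trajectory(10, n_steps * cfg$frame_interval_min / 60, cfg)
    (tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2
  })
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - n_steps * L^2), 3 * se)
})

test_that("identical config and seed give byte-identical output files", {
  td <- withr::local_tempdir()
  for (run in c("a", "b")) {
    sim <- simulate_trackset(sim_config(n_founders = 10, seed = 77))
    write_track_csv(sim$track_set, file.path(td, paste0(run, "_t.csv")),
                    file.path(td, paste0(run, "_l.csv")))
  }
  expect_identical(readLines(file.path(td, "a_t.csv")),
                   readLines(file.path(td, "b_t.csv")))
  expect_identical(readLines(file.path(td, "a_l.csv")),
                   readLines(file.path(td, "b_l.csv")))
})

test_that("growing n_founders leaves earlier families untouched", {
  small <- simulate_pedigree_traits(sim_config(n_founders = 5, seed = 40))
  big <- simulate_pedigree_traits(sim_config(n_founders = 9, seed = 40))
  expect_equal(small$cells, big$cells[seq_len(nrow(small$cells)), ])
})

test_that("end-to-end: tracking round trip recovers the generating traits", {
  cfg <- sim_config(n_founders = 100, seed = 55)
  sim <- simulate_trackset(cfg)
  td <- withr::local_tempdir()
  write_track_csv(sim$track_set, file.path(td, "t.csv"), file.path(td, "l.csv"))
  ts <- read_track_csv(file.path(td, "t.csv"), file.path(td, "l.csv"),
                       frame_interval_min = cfg$frame_interval_min,
                       microns_per_pixel = cfg$microns_per_pixel,
                       n_frames = cfg$n_frames)
  tt <- compute_traits(build_forest(ts), ts)
  truth <- sim$ground_truth$cells
  cc <- dplyr::filter(tt, complete)
  expect_gt(nrow(cc), 300)
  idx <- match(cc$cell_id, truth$cell_id)
  expect_equal(cc$speed, truth$speed[idx], tolerance = 1e-9)
  # generation times live on the frame grid: within one frame interval
  expect_true(all(abs(cc$generation_time - truth$generation_time[idx]) <=
                    cfg$frame_interval_min / 60 + 1e-9))
  # fates agree with ground truth
  expect_true(all(ts$lineage$fate ==
                    truth$fate[match(ts$lineage$cell_id, truth$cell_id)]))
})

test_that("default trait distributions match the configured moments", {
  cfg <- sim_config(n_founders = 150, seed = 60)
  sim <- simulate_trackset(cfg)
  tt <- compute_traits(build_forest(sim$track_set), sim$track_set)
  cc <- dplyr::filter(tt, complete)
  expect_gt(nrow(cc), 500)
  # family-clustered standard error of the mean
  m <- mean(cc$speed)
  fam_sums <- tapply(cc$speed - m, cc$family_id, sum)
  se <- sqrt(sum(fam_sums^2)) / nrow(cc)
  expect_lt(abs(m - 37.55), 2 * se)
})

test_that("trait floors clip draws to physical values", {
  cfg <- sim_config(
    n_founders = 300, seed = 65,
    speed = trait_params(mu = 1, a = 0.5, sigma_g = 3, sigma_s = 2,
                         sigma_u = 3, floor = 0.1))
  cells <- simulate_pedigree_traits(cfg)$cells
  expect_true(all(cells$speed >= 0.1))
  expect_true(all(cells$generation_time >= 2 * cfg$frame_interval_min / 60))
  expect_error(trait_params(mu = 1, a = 1, sigma_delta = 1, sigma_s = 0,
                            sigma_u = 1),
               class = "clonherit_config_error")
})
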