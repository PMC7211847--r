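test_that("pair enumeration follows the averaging rules on the fixture", {
  tt <- fixture_traits()

  md <- enumerate_pairs(tt, "mother_daughter", "speed")
  expect_equal(nrow(md), 3)
  # mother 2 (speed 10) with daughters 8 and 12 -> (10, 10)
  expect_equal(md$x[md$x_id == "2"], 10)
  expect_equal(md$y[md$x_id == "2"], 10)
  expect_equal(md$y[md$x_id == "11"], 8)   # mean(6, 10)
  expect_equal(md$y[md$x_id == "12"], 9)   # single daughter 15

  ss <- enumerate_pairs(tt, "sister_sister", "speed")
  expect_equal(nrow(ss), 3)
  # first-tracked sister on x: dyad (4, 5) -> (8, 12)
  expect_equal(ss$x[ss$x_id == "4"], 8)
  expect_equal(ss$y[ss$x_id == "4"], 12)

  # branch mode: branch-A {6, 10}, branch-B {9} -> one pair (8, 9)
  cb <- enumerate_pairs(tt, "cousin_cousin", "speed", "branch")
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 8)
  expect_equal(cb$y, 9)

  # focal mode: (6,9), (10,9), (9,8)
  cf <- enumerate_pairs(tt, "cousin_cousin", "speed", "focal")
  expect_equal(nrow(cf), 3)
  cf_sorted <- cf[order(cf$x_id), ]
  expect_equal(cf_sorted$x, c(6, 10, 9))
  expect_equal(cf_sorted$y, c(9, 9, 8))

  expect_error(enumerate_pairs(tt, "cousin_cousin", "speed", "bogus"),
               class = "clonherit_config_error")

  # only complete cells ever enter a pair set
  for (ps in list(md, ss, cb)) {
    ids <- unlist(strsplit(c(ps$x_id, ps$y_id), ";"))
    expect_true(all(tt$complete[match(ids, tt$cell_id)]))
  }
})

test_that("estimate_h2 recovers exact degenerate slopes and rejects bad input", {
  fit <- estimate_h2(tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)

  flat <- estimate_h2(tibble::tibble(x = c(1, 2, 3), y = c(5, 5, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(estimate_h2(tibble::tibble(x = c(1, 2), y = c(1, 2))),
               class = "clonherit_insufficient_data_error")
  expect_error(estimate_h2(tibble::tibble(x = c(2, 2, 2), y = c(1, 2, 3))),
               class = "clonherit_degenerate_predictor_error")
})

test_that("slope equals Cov(x,y)/Var(x) and R2 equals squared Pearson", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    ps <- tibble::tibble(x = rnorm(n, 10, 3), y = rnorm(n, 10, 3))
    fit <- estimate_h2(ps)
    expect_equal(fit$slope, oracle_slope(ps$x, ps$y), tolerance = 1e-12)
    expect_equal(fit$r_squared, oracle_r2(ps$x, ps$y), tolerance = 1e-12)
  }
})

test_that("double-entry sister regression is orientation-invariant with dyad df", {
  cfg <- sim_config(n_founders = 60, p_offscreen = 0, p_death = 0, seed = 9)
  tt <- truth_trait_table(simulate_pedigree_traits(cfg))
  de <- enumerate_pairs(tt, "sister_sister", "speed", "double_entry")
  fit <- estimate_h2(de)
  # swapping every (x, y) leaves the double-entry set identical
  sw <- de
  sw$x <- de$y; sw$y <- de$x
  attr(sw, "relationship") <- "sister_sister"
  fit_sw <- estimate_h2(sw)
  expect_equal(fit$slope, fit_sw$slope, tolerance = 1e-12)
  # df counts unique dyads, not double-entered points
  expect_equal(fit$df, attr(de, "n_dyads") - 2L)
  expect_equal(fit$n_pairs, 2L * attr(de, "n_dyads"))

  first <- estimate_h2(enumerate_pairs(tt, "sister_sister", "speed", "first"))
  # both modes see the same dyads; slopes agree up to orientation noise
  expect_equal(fit$n_dyads, first$n_pairs)
})

test_that("the slope is shift-invariant and rescales as s_y/s_x", {
  set.seed(12)
  ps <- tibble::tibble(x = rnorm(40, 5), y = rnorm(40, 5))
  base <- estimate_h2(ps)$slope
  shifted <- estimate_h2(dplyr::mutate(ps, x = x + 7, y = y - 3))$slope
  expect_equal(shifted, base, tolerance = 1e-12)
  scaled <- estimate_h2(dplyr::mutate(ps, x = 2 * x, y = 5 * y))$slope
  expect_equal(scaled, base * 5 / 2, tolerance = 1e-12)
})

test_that("speed-generation Spearman correlation matches a rank oracle", {
  mk_tt <- function(speed, gt) {
    out <- tibble::tibble(
      cell_id = as.character(seq_along(speed)), mother_id = "0",
      family_id = "F1", well_id = "W1", field_id = "P1", generation = 1L,
      complete = TRUE, exclusion_reason = "none",
      generation_time = gt, observed_hours = gt, speed = speed,
      path_length = speed * gt, net_displacement = NA_real_)
    class(out) <- c("trait_table", class(out))
    out
  }
  up <- mk_tt(1:10, (1:10) * 2)
  expect_equal(speed_generation_correlation(up)$rho, 1)
  down <- mk_tt(1:10, 30 - (1:10))
  expect_equal(speed_generation_correlation(down)$rho, -1)

  set.seed(13)
  sp <- rnorm(30); gt <- rnorm(30)
  got <- speed_generation_correlation(mk_tt(sp, gt))
  expect_equal(got$rho, cor(rank(sp), rank(gt)), tolerance = 1e-12)
  expect_error(speed_generation_correlation(mk_tt(1:2, 1:2)),
               class = "clonherit_insufficient_data_error")
})

test_that("well effect test matches the tie-corrected rank-sum formula", {
  mk_tt <- function(speed, well) {
    out <- tibble::tibble(
      cell_id = as.character(seq_along(speed)), mother_id = "0",
      family_id = "F1", well_id = well, field_id = "P1", generation = 1L,
      complete = TRUE, exclusion_reason = "none",
      generation_time = 10, observed_hours = 10, speed = speed,
      path_length = speed * 10, net_displacement = NA_real_)
    class(out) <- c("trait_table", class(out))
    out
  }
  # identical speed multisets in both wells: H ~ 0, p ~ 1
  same <- mk_tt(c(1:5, 1:5), rep(c("W1", "W2"), each = 5))
  res <- well_effect_test(same)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p.value, 0.99)

  # strongly shifted wells separate
  shift <- mk_tt(c(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1)),
                 rep(c("W1", "W2"), each = 20))
  expect_lt(well_effect_test(shift)$p.value, 0.001)

  set.seed(14)
  sp <- rnorm(60); well <- rep(c("W1", "W2", "W3"), each = 20)
  got <- well_effect_test(mk_tt(sp, well))
  expect_equal(got$statistic, oracle_kruskal_h(sp, well), tolerance = 1e-10)
  expect_error(well_effect_test(mk_tt(rnorm(5), rep("W1", 5))),
               class = "clonherit_insufficient_groups_error")
})

test_that("family-size and off-screen comparisons are Welch t-tests", {
  mk_tt <- function(speed, family, reason = "none") {
    out <- tibble::tibble(
      cell_id = as.character(seq_along(speed)), mother_id = "0",
      family_id = family, well_id = "W1", field_id = "P1", generation = 1L,
      complete = reason == "none", exclusion_reason = reason,
      generation_time = 10, observed_hours = 10, speed = speed,
      path_length = speed * 10, net_displacement = NA_real_)
    class(out) <- c("trait_table", class(out))
    out
  }
  # two family-size classes (size 2 and size 4) with identical speeds: t = 0
  tt0 <- mk_tt(rep(5, 6), rep(c("A", "B"), c(2, 4)))
  expect_equal(family_size_speed_test(tt0)$statistic, 0)

  # separated classes
  set.seed(15)
  tt1 <- mk_tt(c(rnorm(40, 10), rnorm(40, 30)),
               rep(c("A1", "A2", "B1", "B2", "B3", "B4"),
                   c(20, 20, 10, 10, 10, 10)))
  res1 <- family_size_speed_test(tt1)
  expect_lt(min(res1$p.value), 1e-6)

  # random classes match the hand-coded Welch statistic
  sp <- c(rnorm(12, 10, 2), rnorm(20, 11, 3))
  fam <- rep(c("A1", "A2", "A3", "B1", "B2"), c(4, 4, 4, 10, 10))
  got <- family_size_speed_test(mk_tt(sp, fam))
  expect_equal(got$statistic,
               oracle_welch_t(sp[1:12], sp[13:32]), tolerance = 1e-10)

  # off-screen comparison
  tt_off <- mk_tt(c(rnorm(15, 10), rnorm(25, 10.5)), "F1",
                  rep(c("off_screen", "none"), c(15, 25)))
  got_off <- offscreen_speed_test(tt_off)
  expect_equal(got_off$statistic,
               oracle_welch_t(tt_off$speed[1:15], tt_off$speed[16:40]),
               tolerance = 1e-10)
  expect_equal(got_off$n_off_screen, 15L)
  expect_error(offscreen_speed_test(mk_tt(rnorm(5), "F1")),
               class = "clonherit_insufficient_groups_error")
})

test_that("report cells carry the star convention", {
  expect_equal(format_h2_cell(0.5, 0.0005, 0.28), "0.5*** (0.28)")
  expect_equal(h2_stars(0.04), "*")
  expect_equal(h2_stars(0.009), "**")
  expect_equal(h2_stars(0.2), "")

  tt <- fixture_traits()
  fits <- list(estimate_h2(enumerate_pairs(tt, "mother_daughter", "speed")),
               estimate_h2(enumerate_pairs(tt, "sister_sister", "speed")))
  rep_row <- h2_report(fits, tt, cell_line = "FIX")
  expect_equal(rep_row$cell_line, "FIX")
  expect_equal(rep_row$n_families, 3L)
  expect_equal(rep_row$h2_speed_mother, fits[[1]]$slope)
  expect_match(rep_row$fmt_speed_mother, "\\(")
  txt <- format(rep_row)
  expect_true(any(grepl("mean speed", txt)))
})
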