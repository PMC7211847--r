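# Hand-built fixtures used across the suite. All tracks are straight lines
# along x with one step per frame, so curvilinear speed is exactly
# 3 * step_px um/h at a 20-min interval and scale 1 um/px.

# One cell's straight track: frames f0..f1, step `step` px per frame.
mk_track <- function(id, f0, f1, step, y = 0) {
  n <- f1 - f0
  tibble::tibble(cell_id = id, frame = f0:f1, x = step * (0:n), y = y)
}

# Three families covering all four fates.
#
# F1: founder 1 (frames 0-6) -> 2 (6-12, divided), 3 (6-9, off_screen);
#     2 -> 4 (12-18, divided), 5 (12-21, divided)   [daughters untracked]
# F2: founder 10 (0-5) -> 11 (5-11), 12 (5-13);
#     11 -> 13 (11-17), 14 (11-20); 12 -> 15 (13-19, divided), 16 (13-16, died)
# F3: founder 20 (0-4) -> 21 (4-10, divided), 22 (4-30, censored_at_end);
#     21 -> 23 (10-30, censored_at_end), 24 (10-15, off_screen)
#
# Manual enumeration: 17 cells; complete {2,4,5,11,12,13,14,15,21} (9);
# founders 3; off_screen {3,24}; died {16}; censored {22,23};
# cousin-eligible families: F2 only; cousin-eligible cells {13,14,15}.
# Speeds (um/h) = 3 * step: set below per cell.
fixture_trackset <- function() {
  spd <- c("1" = 6, "2" = 10, "3" = 7, "4" = 8, "5" = 12,
           "10" = 6, "11" = 10, "12" = 14, "13" = 6, "14" = 10,
           "15" = 9, "16" = 4, "20" = 6, "21" = 5, "22" = 3,
           "23" = 2, "24" = 8)
  span <- list("1" = c(0, 6), "2" = c(6, 12), "3" = c(6, 9),
               "4" = c(12, 18), "5" = c(12, 21),
               "10" = c(0, 5), "11" = c(5, 11), "12" = c(5, 13),
               "13" = c(11, 17), "14" = c(11, 20), "15" = c(13, 19),
               "16" = c(13, 16), "20" = c(0, 4), "21" = c(4, 10),
               "22" = c(4, 30), "23" = c(10, 30), "24" = c(10, 15))
  tracks <- dplyr::bind_rows(lapply(names(span), function(id)
    mk_track(id, span[[id]][1], span[[id]][2], spd[[id]] / 3,
             y = as.numeric(id))))
  lineage <- tibble::tibble(
    cell_id = c("1", "2", "3", "4", "5",
                "10", "11", "12", "13", "14", "15", "16",
                "20", "21", "22", "23", "24"),
    mother_id = c(NA, "1", "1", "2", "2",
                  NA, "10", "10", "11", "11", "12", "12",
                  NA, "20", "20", "21", "21"),
    fate = c("divided", "divided", "off_screen", "divided", "divided",
             "divided", "divided", "divided", "divided", "divided",
             "divided", "died",
             "divided", "divided", "censored_at_end", "censored_at_end",
             "off_screen"),
    well_id = rep(c("W1", "W2", "W3"), c(5, 7, 5)),
    field_id = "P1")
  track_set(tracks, lineage, frame_interval_min = 20, microns_per_pixel = 1,
            n_frames = 31)
}

fixture_traits <- function() {
  ts <- fixture_trackset()
  compute_traits(build_forest(ts), ts)
}

# Independent polyline-length oracle (brute force, no vectorisation).
oracle_path_length <- function(x, y, scale = 1) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + scale * sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  total
}

# Independent slope / R^2 oracle: the heritability formula written directly.
oracle_slope <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  vx <- sum((x - mean(x))^2) / (n - 1)
  cxy / vx
}
oracle_r2 <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  vx <- sum((x - mean(x))^2) / (n - 1)
  vy <- sum((y - mean(y))^2) / (n - 1)
  cxy^2 / (vx * vy)
}

# Independent Welch t statistic.
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Independent tie-corrected Kruskal-Wallis H from the rank-sum formula.
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Family-block standard error for a slope estimated on clustered pairs:
# families are split into `n_blocks` contiguous blocks, the slope is
# re-estimated per block, and the SE of the full-sample estimator is
# sd(block slopes) / sqrt(n_blocks).
block_slope_se <- function(ps, n_blocks) {
  fams <- sort(unique(ps$family_id))
  bmap <- stats::setNames(rep(seq_len(n_blocks), length.out = length(fams)), fams)
  slopes <- vapply(seq_len(n_blocks), function(b) {
    sub <- ps[bmap[ps$family_id] == b, ]
    oracle_slope(sub$x, sub$y)
  }, numeric(1))
  sd(slopes) / sqrt(n_blocks)
}
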