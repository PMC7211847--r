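#' Spearman correlation between speed and generation time
#'
#' Rank correlation over complete cells (average ranks for ties, two-sided
#' asymptotic p-value), asking whether faster-dividing cells move faster or
#' slower.
#'
#' @param traits A trait table.
#' @return A one-row tibble: `rho`, `p.value`, `n`.
#' @export
speed_generation_correlation <- function(traits) {
  cc <- filter(as_tibble(traits), .data$complete)
  if (nrow(cc) < 3) {
    abort("need at least 3 complete cells", class = "clonherit_insufficient_data_error")
  }
  ct <- cor.test(cc$speed, cc$generation_time, method = "spearman",
                 exact = FALSE)
  tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = nrow(cc))
}

#' Kruskal-Wallis test for a well effect on speed
#'
#' Tests complete-cell speeds grouped by well (tie-corrected H, chi-squared
#' p on k - 1 df). A non-significant result argues that spatial effects,
#' which could exacerbate similarity between relatives, are minimal.
#'
#' @param traits A trait table.
#' @return A one-row tibble: `statistic` (H), `df`, `p.value`, `n_wells`.
#' @export
well_effect_test <- function(traits) {
  cc <- filter(as_tibble(traits), .data$complete, !is.na(.data$well_id))
  if (n_distinct(cc$well_id) < 2) {
    abort("need complete cells in at least 2 wells",
          class = "clonherit_insufficient_groups_error")
  }
  kt <- kruskal.test(cc$speed, factor(cc$well_id))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, n_wells = n_distinct(cc$well_id))
}

#' Welch t-tests of speed between family-size classes
#'
#' Families are classed by their number of complete cells; each pair of
#' observed size classes with at least two cells per class is compared by a
#' two-sided Welch t-test on complete-cell speeds.
#'
#' @param traits A trait table.
#' @return A tibble with one row per size-class comparison: `size_a`,
#'   `size_b`, `n_a`, `n_b`, `statistic`, `df`, `p.value`.
#' @export
family_size_speed_test <- function(traits) {
  cc <- filter(as_tibble(traits), .data$complete)
  cc <- cc |> group_by(.data$family_id) |> mutate(fam_size = n()) |> ungroup()
  sizes <- sort(unique(cc$fam_size))
  sizes <- sizes[vapply(sizes, function(s) sum(cc$fam_size == s) >= 2, logical(1))]
  if (length(sizes) < 2) {
    abort("need at least 2 family-size classes with >= 2 complete cells",
          class = "clonherit_insufficient_groups_error")
  }
  combos <- utils::combn(sizes, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- cc$speed[cc$fam_size == combos[1, j]]
    b <- cc$speed[cc$fam_size == combos[2, j]]
    w <- .welch(a, b)
    tibble(size_a = combos[1, j], size_b = combos[2, j],
           n_a = length(a), n_b = length(b),
           statistic = w$statistic, df = w$df, p.value = w$p.value)
  })
}

# Welch two-sample t-test; degenerate equal-constant groups give t = 0
# rather than t.test()'s "data are essentially constant" error.
.welch <- function(a, b) {
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    return(list(statistic = 0, df = NA_real_, p.value = 1))
  }
  tt <- t.test(a, b)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Welch t-test: off-screen versus completely tracked cells
#'
#' Compares partial-lifetime speeds of cells that moved off-screen with the
#' whole-lifetime speeds of complete cells. A non-significant result argues
#' against a bias from faster cells leaving the field of view.
#'
#' @param traits A trait table.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `n_off_screen`,
#'   `n_complete`.
#' @export
offscreen_speed_test <- function(traits) {
  tt <- as_tibble(traits)
  off <- tt$speed[tt$exclusion_reason == "off_screen" & !is.na(tt$speed)]
  comp <- tt$speed[tt$complete & !is.na(tt$speed)]
  if (length(off) < 2 || length(comp) < 2) {
    abort("need at least 2 off-screen and 2 complete cells",
          class = "clonherit_insufficient_groups_error")
  }
  w <- .welch(off, comp)
  tibble(statistic = w$statistic, df = w$df, p.value = w$p.value,
         n_off_screen = length(off), n_complete = length(comp))
}
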