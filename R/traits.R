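#' Generation time of one cell
#'
#' The time taken for a full cell cycle, cytokinesis to cytokinesis: the
#' cell's birth is anchored at its mother's final frame (which is the cell's
#' first frame) and its own division at its final frame.
#'
#' @param cell_id Id of the cell.
#' @param ts A [track_set()].
#' @return Generation time in hours.
#' @export
generation_time <- function(cell_id, ts) {
  .assert_complete(cell_id, ts)
  fr <- ts$tracks$frame[ts$tracks$cell_id == cell_id]
  (max(fr) - min(fr)) * ts$frame_interval_min / 60
}

#' Curvilinear speed of one cell
#'
#' Total Euclidean length of the polyline through the cell's recorded
#' positions over its whole lifetime, in microns, divided by its generation
#' time in hours. A missing frame contributes a single straight segment
#' across the gap, so the path length is a lower bound.
#'
#' @inheritParams generation_time
#' @return Speed in microns per hour.
#' @export
curvilinear_speed <- function(cell_id, ts) {
  .assert_complete(cell_id, ts)
  p <- ts$tracks[ts$tracks$cell_id == cell_id, ]
  if (nrow(p) < 2) {
    abort("speed needs at least 2 recorded points", class = "clonherit_contract_error")
  }
  path_um <- ts$microns_per_pixel * sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  path_um / generation_time(cell_id, ts)
}

.assert_complete <- function(cell_id, ts) {
  row <- ts$lineage[ts$lineage$cell_id == cell_id, ]
  if (!nrow(row)) {
    abort(paste0("unknown cell ", sQuote(cell_id)), class = "clonherit_integrity_error")
  }
  reason <- if (is.na(row$mother_id)) "founder"
            else if (row$fate != "divided") row$fate
            else "none"
  if (reason != "none") {
    abort(paste0("cell ", sQuote(cell_id), " was not observed for a complete ",
                 "cell cycle (exclusion_reason: ", reason, ")"),
          class = "clonherit_contract_error")
  }
  invisible(TRUE)
}

#' Compute whole-lifetime traits for every cell
#'
#' Applies the cytokinesis-to-cytokinesis inclusion rule: a cell is complete
#' when both its birth (it has a tracked mother) and its division
#' (fate `divided`) were observed. Originally plated founders, cells that
#' moved off-screen or died, and cells that had not divided by the end of
#' the recording keep their rows flagged with an `exclusion_reason`.
#' Excluded cells carry a partial-track speed over their observed lifetime
#' (used only by the off-screen comparison test, never by heritability
#' estimation); their `generation_time` is `NA`.
#'
#' @param forest A [build_forest()] result.
#' @param ts The [track_set()] the forest was built from.
#' @return A tibble of class `trait_table`, one row per cell, ordered by
#'   family, generation, cell id. Columns: pedigree and metadata
#'   (`cell_id`, `mother_id`, `family_id`, `well_id`, `field_id`,
#'   `generation`), flags (`complete`, `exclusion_reason`), and traits
#'   (`generation_time` h, `observed_hours`, `speed` um/h, `path_length` um,
#'   `net_displacement` um).
#' @export
compute_traits <- function(forest, ts) {
  stopifnot(inherits(forest, "lineage_forest"), inherits(ts, "track_set"))
  ivl_h <- ts$frame_interval_min / 60
  mpp <- ts$microns_per_pixel

  geom <- ts$tracks |>
    group_by(.data$cell_id) |>
    summarise(
      first_frame = min(.data$frame),
      last_frame = max(.data$frame),
      path_length = mpp * sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      net_displacement = mpp * sqrt((.data$x[which.max(.data$frame)] -
                                       .data$x[which.min(.data$frame)])^2 +
                                    (.data$y[which.max(.data$frame)] -
                                       .data$y[which.min(.data$frame)])^2),
      .groups = "drop")

  out <- as_tibble(forest) |>
    left_join(geom, by = "cell_id") |>
    mutate(
      exclusion_reason = case_when(
        is.na(.data$mother_id) ~ "founder",
        .data$fate != "divided" ~ .data$fate,
        TRUE ~ "none"),
      complete = .data$exclusion_reason == "none",
      observed_hours = (.data$last_frame - .data$first_frame) * ivl_h,
      generation_time = ifelse(.data$complete, .data$observed_hours, NA_real_),
      speed = ifelse(.data$observed_hours > 0,
                     .data$path_length / .data$observed_hours, NA_real_)) |>
    select("cell_id", "mother_id", "family_id", "well_id", "field_id",
           "generation", "complete", "exclusion_reason", "generation_time",
           "observed_hours", "speed", "path_length", "net_displacement") |>
    arrange(.data$family_id, .data$generation, .data$cell_id)

  attr(out, "frame_interval_min") <- ts$frame_interval_min
  attr(out, "microns_per_pixel") <- mpp
  class(out) <- c("trait_table", class(out))
  out
}

#' Census of families and usable cells
#'
#' Reports how much of the tracked data survives the inclusion rules, and
#' how many families allow at least one cousin comparison (complete cells in
#' at least two granddaughter branches of the same grandmother), the
#' criterion that makes a family usable for all three relationships.
#'
#' @param traits A [compute_traits()] table.
#' @return A one-row tibble: total cells/families, exclusion waterfall
#'   counts, cousin-eligible families, cousin-eligible cells (complete cells
#'   with at least one complete cousin), usable cells (complete cells in
#'   cousin-eligible families) and the usable fraction of tracked cells.
#' @export
family_census <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  cz <- .cousin_frame(traits)
  eligible_fams <- unique(cz$family_id[cz$has_cousin])
  reason <- factor(traits$exclusion_reason,
                   levels = c("none", "founder", "off_screen", "died", "censored_at_end"))
  tab <- table(reason)
  tibble(
    n_cells = nrow(traits),
    n_families = n_distinct(traits$family_id),
    n_complete = unname(tab[["none"]]),
    n_founder = unname(tab[["founder"]]),
    n_off_screen = unname(tab[["off_screen"]]),
    n_died = unname(tab[["died"]]),
    n_censored_at_end = unname(tab[["censored_at_end"]]),
    n_eligible_families = length(eligible_fams),
    n_cousin_cells = sum(cz$has_cousin),
    n_usable = sum(traits$complete & traits$family_id %in% eligible_fams),
    usable_fraction = .data$n_usable / .data$n_cells)
}

# Complete cells annotated with their grandmother and whether a complete
# cousin (same grandmother, different mother) exists.
.cousin_frame <- function(traits) {
  ped <- as_tibble(traits)[, c("cell_id", "mother_id")]
  names(ped) <- c("mid", "grandmother_id")
  as_tibble(traits) |>
    filter(.data$complete, !is.na(.data$mother_id)) |>
    left_join(ped, by = c(mother_id = "mid")) |>
    filter(!is.na(.data$grandmother_id)) |>
    group_by(.data$grandmother_id) |>
    mutate(has_cousin = n_distinct(.data$mother_id) >= 2) |>
    ungroup()
}

#' Write / read a trait table as CSV
#'
#' Row order is deterministic (family, generation, cell id), so writes are
#' reproducible byte-for-byte.
#'
#' @param traits A trait table.
#' @param path Output path.
#' @return `traits` invisibly (writer); a `trait_table` (reader).
#' @export
write_traits_csv <- function(traits, path) {
  readr::write_csv(as_tibble(traits), path)
  invisible(traits)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  out <- readr::read_csv(
    path, show_col_types = FALSE, na = c("", "NA"),
    col_types = readr::cols(
      cell_id = readr::col_character(), mother_id = readr::col_character(),
      family_id = readr::col_character(), well_id = readr::col_character(),
      field_id = readr::col_character(), generation = readr::col_integer(),
      complete = readr::col_logical(), exclusion_reason = readr::col_character(),
      .default = readr::col_double()))
  class(out) <- c("trait_table", class(out))
  out
}

#' Trait distributions at a glance
#'
#' Histograms of whole-lifetime speed and generation time over complete
#' cells.
#'
#' @param object A `trait_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_table <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$complete) |>
    select("cell_id", "speed", "generation_time") |>
    tidyr_longer()
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "grey35") +
    facet_wrap(~.data$trait, scales = "free",
               labeller = as_labeller(c(speed = "speed (µm/h)",
                                        generation_time = "generation time (h)"))) +
    labs(x = NULL, y = "cells", title = "Whole-lifetime traits (complete cells)")
}

# minimal pivot_longer for the two trait columns (avoids a tidyr dependency)
tidyr_longer <- function(df) {
  bind_rows(
    tibble(cell_id = df$cell_id, trait = "speed", value = df$speed),
    tibble(cell_id = df$cell_id, trait = "generation_time", value = df$generation_time))
}
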