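#' Enumerate relative pairs for one relationship and trait
#'
#' Builds the (x, y) pairs fed to the heritability regression. Only cells
#' observed for a complete cell cycle contribute. Averaging rules:
#'
#' * `sister_sister`: one pair per complete sister dyad. Mode `"first"`
#'   (default) puts the first-tracked sister (lower cell id) on x;
#'   `"double_entry"` enters every dyad twice, once per orientation (the
#'   fitted slope is then orientation-invariant and p-values are computed on
#'   `n_dyads - 2` degrees of freedom).
#' * `mother_daughter`: one pair per complete mother with at least one
#'   complete daughter; x = the mother's value, y = the mean over her
#'   complete daughters.
#' * `cousin_cousin`: mode `"branch"` (default) emits one pair per
#'   grandmother whose two daughter-branches both contain complete
#'   grandchildren; x and y are the branch means (branch of the
#'   first-tracked mother on x). Mode `"focal"` emits one point per complete
#'   grandchild that has a complete cousin, with y = the mean of its
#'   cousins; focal points reuse cells across points.
#'
#' @param traits A [compute_traits()] table (or [truth_trait_table()]).
#' @param relationship One of `"sister_sister"`, `"mother_daughter"`,
#'   `"cousin_cousin"`.
#' @param trait `"speed"` or `"generation_time"`.
#' @param mode Pairing mode; `NULL` selects the default for the
#'   relationship (`"first"` for sisters, `"branch"` for cousins).
#' @return A tibble of class `pair_set` with columns `family_id`, `x_id`,
#'   `y_id` (ids averaged into y, `;`-separated), `x`, `y`, and attributes
#'   `relationship`, `trait`, `mode`, `n_dyads`.
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 30, seed = 1)
#' gt <- simulate_pedigree_traits(cfg)
#' tt <- truth_trait_table(gt)
#' enumerate_pairs(tt, "mother_daughter", "speed")
enumerate_pairs <- function(traits, relationship = RELATIONSHIPS,
                            trait = TRAIT_NAMES, mode = NULL) {
  relationship <- match.arg(relationship)
  trait <- match.arg(trait)
  mode <- .check_mode(relationship, mode)

  cc <- as_tibble(traits) |>
    filter(.data$complete) |>
    mutate(.val = .data[[trait]]) |>
    select("cell_id", "mother_id", "family_id", ".val")

  pairs <- switch(relationship,
    sister_sister = .pairs_sister(cc, mode),
    mother_daughter = .pairs_mother_daughter(cc),
    cousin_cousin = .pairs_cousin(cc, as_tibble(traits), mode))

  n_dyads <- attr(pairs, "n_dyads") %||% nrow(pairs)
  pairs <- as_tibble(pairs)
  structure(pairs, relationship = relationship, trait = trait, mode = mode,
            n_dyads = n_dyads, class = c("pair_set", class(pairs)))
}

.check_mode <- function(relationship, mode) {
  allowed <- switch(relationship,
                    sister_sister = c("first", "double_entry"),
                    mother_daughter = "daughter_mean",
                    cousin_cousin = c("branch", "focal"))
  if (is.null(mode)) return(allowed[[1]])
  if (!mode %in% allowed) {
    abort(paste0("unknown mode ", sQuote(mode), " for ", relationship,
                 "; allowed: ", paste(allowed, collapse = ", ")),
          class = "clonherit_config_error")
  }
  mode
}

.pairs_sister <- function(cc, mode) {
  dy <- cc |>
    filter(!is.na(.data$mother_id)) |>
    arrange(.data$mother_id, .data$cell_id) |>
    group_by(.data$mother_id) |>
    filter(n() == 2) |>
    summarise(family_id = .data$family_id[[1]],
              x_id = .data$cell_id[[1]], y_id = .data$cell_id[[2]],
              x = .data$.val[[1]], y = .data$.val[[2]], .groups = "drop") |>
    select(-"mother_id") |>
    arrange(.data$family_id, .data$x_id)
  if (mode == "double_entry") {
    sw <- dy |> rename(x_id = "y_id", y_id = "x_id", x = "y", y = "x")
    out <- bind_rows(dy, sw) |> arrange(.data$family_id, .data$x_id)
    attr(out, "n_dyads") <- nrow(dy)
    return(out)
  }
  dy
}

.pairs_mother_daughter <- function(cc) {
  dmeans <- cc |>
    filter(!is.na(.data$mother_id)) |>
    group_by(.data$mother_id) |>
    summarise(y = mean(.data$.val),
              y_id = paste(.data$cell_id, collapse = ";"), .groups = "drop")
  cc |>
    select(x_id = "cell_id", x = ".val", "family_id") |>
    inner_join(dmeans, by = c(x_id = "mother_id")) |>
    select("family_id", "x_id", "y_id", "x", "y") |>
    arrange(.data$family_id, .data$x_id)
}

.pairs_cousin <- function(cc, traits, mode) {
  ped <- traits[, c("cell_id", "mother_id")]
  names(ped) <- c(".mid", "grandmother_id")
  gc <- cc |>
    filter(!is.na(.data$mother_id)) |>
    left_join(ped, by = c(mother_id = ".mid")) |>
    filter(!is.na(.data$grandmother_id))

  if (mode == "branch") {
    br <- gc |>
      group_by(.data$grandmother_id, .data$mother_id) |>
      summarise(family_id = .data$family_id[[1]],
                m = mean(.data$.val),
                ids = paste(sort(.data$cell_id), collapse = ";"),
                .groups = "drop_last") |>
      arrange(.data$grandmother_id, .data$mother_id) |>
      filter(n() == 2) |>
      summarise(family_id = .data$family_id[[1]],
                x_id = .data$ids[[1]], y_id = .data$ids[[2]],
                x = .data$m[[1]], y = .data$m[[2]], .groups = "drop") |>
      select(-"grandmother_id") |>
      arrange(.data$family_id, .data$x_id)
    return(br)
  }
  # focal: one point per grandchild with >= 1 complete cousin
  gc |>
    group_by(.data$grandmother_id) |>
    filter(n_distinct(.data$mother_id) >= 2) |>
    mutate(
      y = (sum(.data$.val) - .ave_by(.data$.val, .data$mother_id) *
             .n_by(.data$mother_id)) / (n() - .n_by(.data$mother_id)),
      y_id = vapply(seq_len(n()), function(i)
        paste(sort(.data$cell_id[.data$mother_id != .data$mother_id[[i]]]),
              collapse = ";"), character(1))) |>
    ungroup() |>
    select("family_id", x_id = "cell_id", "y_id", x = ".val", "y") |>
    arrange(.data$family_id, .data$x_id)
}

# per-group sum/count helpers used inside a mutate over an outer grouping
.ave_by <- function(v, g) stats::ave(v, g, FUN = mean)
.n_by <- function(g) stats::ave(seq_along(g), g, FUN = length)

#' Write a pair set as CSV
#'
#' @param ps A [enumerate_pairs()] result.
#' @param path Output path.
#' @return `ps`, invisibly.
#' @export
write_pairs_csv <- function(ps, path) {
  out <- as_tibble(ps) |>
    mutate(relationship = attr(ps, "relationship"),
           trait = attr(ps, "trait"), mode = attr(ps, "mode"),
           .before = 1)
  readr::write_csv(out, path)
  invisible(ps)
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %s / %s (mode %s): %d pairs, %d dyads\n",
              attr(x, "relationship"), attr(x, "trait"), attr(x, "mode"),
              nrow(x), attr(x, "n_dyads")))
  print(as_tibble(x), ...)
  invisible(x)
}
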