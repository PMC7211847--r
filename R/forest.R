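#' Build a lineage forest from a track set
#'
#' Partitions all tracked cells into families, each rooted at an originally
#' plated founder, and assigns generation indices (founder = 0) by link
#' depth. Divisions are binary: a cell with more than two declared daughters
#' is a pedigree error; a divided cell with one tracked daughter marks a
#' division with one untracked daughter.
#'
#' @param ts A [track_set()].
#' @return A tibble of class `lineage_forest` with one row per cell:
#'   `cell_id`, `mother_id`, `family_id`, `generation`, `n_daughters`,
#'   `fate`, `well_id`, `field_id`.
#' @export
build_forest <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  ln <- ts$lineage
  if (!nrow(ln)) {
    abort("track set contains no cells; cannot build a lineage forest",
          class = "clonherit_validation_error")
  }
  gen <- .check_acyclic(ln)

  nd <- table(ln$mother_id[!is.na(ln$mother_id)])
  over <- names(nd)[nd > 2]
  if (length(over)) {
    abort(paste0("binary division violated: mother(s) with >2 daughters: ",
                 paste(over, collapse = ", ")),
          class = "clonherit_pedigree_error")
  }

  # propagate founder id down the links
  fam <- ifelse(is.na(ln$mother_id), ln$cell_id, NA_character_)
  idx <- match(ln$mother_id, ln$cell_id)
  repeat {
    open <- which(is.na(fam) & !is.na(fam[idx]))
    if (!length(open)) break
    fam[open] <- fam[idx[open]]
  }

  out <- ln |>
    mutate(family_id = paste0("F", fam),
           generation = gen,
           n_daughters = as.integer(unname(nd[.data$cell_id])),
           n_daughters = ifelse(is.na(.data$n_daughters), 0L, .data$n_daughters)) |>
    select("cell_id", "mother_id", "family_id", "generation", "n_daughters",
           "fate", "well_id", "field_id") |>
    arrange(.data$family_id, .data$generation, .data$cell_id)
  class(out) <- c("lineage_forest", class(out))
  out
}

#' Summarise a lineage forest
#'
#' @param object A `lineage_forest`.
#' @param ... Unused.
#' @return A one-row tibble with family and generation counts.
#' @export
glance.lineage_forest <- function(object, ...) {
  tibble(n_cells = nrow(object),
         n_families = n_distinct(object$family_id),
         max_generation = max(object$generation),
         n_divided = sum(object$fate == "divided"))
}
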