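#' Assemble a validated track set
#'
#' A track set bundles per-cell position time series with the declared
#' lineage (mother-daughter links and cell fates) and the recording
#' parameters needed to interpret them. Positions are in pixels, image
#' convention (origin top-left, y increasing downward); conversion to microns
#' happens only when traits are computed, via `microns_per_pixel`.
#'
#' @param tracks Data frame with columns `cell_id`, `frame`, `x`, `y`; one
#'   row per recorded position. Frames are 0-based; the time of frame k is
#'   `k * frame_interval_min` minutes. Rows are re-sorted by frame within
#'   each cell; duplicate frames within a cell are an error.
#' @param lineage Data frame with columns `cell_id`, `mother_id`, `fate`,
#'   `well_id`, `field_id`; one row per tracked cell. A missing `mother_id`
#'   marks an originally plated founder. `fate` is one of `divided`,
#'   `off_screen`, `died`, `censored_at_end`; a missing fate is inferred:
#'   `divided` if the cell has declared daughters, `censored_at_end` if its
#'   track reaches the final frame, otherwise `off_screen` (the cell was
#'   lost from observation; death cannot be inferred from positions alone).
#' @param frame_interval_min Minutes between frames (default 20).
#' @param microns_per_pixel Spatial scale; required, no default (tracking
#'   systems do not embed it in their output).
#' @param n_frames Total frames in the recording (default 217, i.e. 72 h at
#'   20-min intervals).
#'
#' @return An object of class `track_set`: a list with tibbles `tracks` and
#'   `lineage` plus the recording parameters.
#' @export
#' @examples
#' tr <- tibble::tibble(cell_id = c("1", "1", "2"), frame = c(0L, 1L, 1L),
#'                      x = c(0, 3, 3), y = c(0, 0, 0))
#' ln <- tibble::tibble(cell_id = c("1", "2"), mother_id = c(NA, "1"),
#'                      fate = c("divided", "off_screen"),
#'                      well_id = "W1", field_id = "P1")
#' track_set(tr, ln, microns_per_pixel = 0.65)
track_set <- function(tracks, lineage, frame_interval_min = 20,
                      microns_per_pixel, n_frames = 217) {
  if (missing(microns_per_pixel) || is.null(microns_per_pixel)) {
    abort("`microns_per_pixel` is required: tracking output carries no spatial scale.",
          class = "clonherit_config_error")
  }
  stopifnot(frame_interval_min > 0, microns_per_pixel > 0, n_frames >= 1)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")),
            class = "clonherit_format_error")
    }
  }
  need(tracks, c("cell_id", "frame", "x", "y"), "`tracks`")
  need(lineage, c("cell_id", "mother_id", "fate", "well_id", "field_id"), "`lineage`")

  tracks <- as_tibble(tracks) |>
    mutate(cell_id = as.character(.data$cell_id),
           frame = as.integer(.data$frame),
           x = as.double(.data$x), y = as.double(.data$y)) |>
    arrange(.data$cell_id, .data$frame)
  lineage <- as_tibble(lineage) |>
    mutate(cell_id = as.character(.data$cell_id),
           mother_id = as.character(.data$mother_id),
           fate = as.character(.data$fate),
           well_id = as.character(.data$well_id),
           field_id = as.character(.data$field_id))

  if (anyNA(tracks$frame) || any(tracks$frame < 0)) {
    abort("frames must be non-negative integers", class = "clonherit_format_error")
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    abort("track coordinates must be finite", class = "clonherit_format_error")
  }
  dup <- tracks |> count(.data$cell_id, .data$frame) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate frame(s) within track(s): ",
                 paste(unique(dup$cell_id), collapse = ", ")),
          class = "clonherit_integrity_error")
  }
  if (any(tracks$frame > n_frames - 1)) {
    abort("track frames exceed n_frames - 1", class = "clonherit_integrity_error")
  }

  if (anyDuplicated(lineage$cell_id)) {
    abort("duplicate cell_id in lineage table", class = "clonherit_integrity_error")
  }
  tracked_ids <- unique(tracks$cell_id)
  no_track <- setdiff(lineage$cell_id, tracked_ids)
  if (length(no_track)) {
    abort(paste0("lineage cites cell(s) with no track: ",
                 paste(head(no_track, 5), collapse = ", ")),
          class = "clonherit_integrity_error")
  }
  no_lineage <- setdiff(tracked_ids, lineage$cell_id)
  if (length(no_lineage)) {
    abort(paste0("track(s) with no lineage row: ",
                 paste(head(no_lineage, 5), collapse = ", ")),
          class = "clonherit_integrity_error")
  }
  bad_mother <- setdiff(lineage$mother_id[!is.na(lineage$mother_id)], lineage$cell_id)
  if (length(bad_mother)) {
    abort(paste0("mother_id does not resolve to a tracked cell: ",
                 paste(head(bad_mother, 5), collapse = ", ")),
          class = "clonherit_integrity_error")
  }

  # infer missing fates where possible
  last_frame <- if (nrow(tracks)) {
    tracks |> group_by(.data$cell_id) |>
      summarise(.last = max(.data$frame), .groups = "drop")
  } else {
    tibble(cell_id = character(), .last = integer())
  }
  has_daughter <- lineage$cell_id %in% lineage$mother_id
  ends_at_final <- last_frame$.last[match(lineage$cell_id, last_frame$cell_id)] == n_frames - 1
  inferred <- ifelse(has_daughter, "divided",
                     ifelse(ends_at_final, "censored_at_end", "off_screen"))
  lineage$fate <- ifelse(is.na(lineage$fate), inferred, lineage$fate)
  bad_fate <- setdiff(unique(lineage$fate), FATE_TOKENS)
  if (length(bad_fate)) {
    abort(paste0("unknown fate token(s): ", paste(bad_fate, collapse = ", "),
                 "; allowed: ", paste(FATE_TOKENS, collapse = ", ")),
          class = "clonherit_validation_error")
  }
  non_divided_mothers <- lineage$cell_id[has_daughter & lineage$fate != "divided"]
  if (length(non_divided_mothers)) {
    abort(paste0("cell(s) with declared daughters but fate != divided: ",
                 paste(head(non_divided_mothers, 5), collapse = ", ")),
          class = "clonherit_integrity_error")
  }

  .check_acyclic(lineage)

  structure(
    list(tracks = tracks, lineage = lineage,
         frame_interval_min = frame_interval_min,
         microns_per_pixel = microns_per_pixel,
         n_frames = as.integer(n_frames)),
    class = "track_set")
}

# Generation assignment doubles as the cycle check: founders seed generation
# 0 and generations propagate along links; anything left unassigned after the
# propagation fixpoint sits on a cycle.
.generations <- function(lineage) {
  gen <- ifelse(is.na(lineage$mother_id), 0L, NA_integer_)
  idx <- match(lineage$mother_id, lineage$cell_id)
  repeat {
    open <- which(is.na(gen) & !is.na(gen[idx]))
    if (!length(open)) break
    gen[open] <- gen[idx[open]] + 1L
  }
  gen
}

.check_acyclic <- function(lineage) {
  gen <- .generations(lineage)
  if (anyNA(gen)) {
    abort(paste0("cyclic lineage links involving: ",
                 paste(head(lineage$cell_id[is.na(gen)], 5), collapse = ", ")),
          class = "clonherit_integrity_error")
  }
  invisible(gen)
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set>\n")
  cat("  cells:      ", nrow(x$lineage), "\n")
  cat("  positions:  ", nrow(x$tracks), "\n")
  cat("  frames:     ", x$n_frames, "at", x$frame_interval_min, "min\n")
  cat("  scale:      ", x$microns_per_pixel, "um/px\n")
  cat("  fates:      ",
      paste(names(table(x$lineage$fate)), table(x$lineage$fate),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a track set
#' @param ts A [track_set()].
#' @return Integer count of tracked cells.
#' @export
n_cells <- function(ts) nrow(ts$lineage)
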