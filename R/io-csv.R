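#' Read tracking data in the CSV dialect
#'
#' The CSV dialect is two files: a tracks table (`cell_id, frame, x, y`) and
#' a lineage sidecar (`cell_id, mother_id, fate, well_id, field_id`). Both
#' require header rows. An empty `mother_id` marks a founder.
#'
#' @param tracks_path Path to the tracks CSV.
#' @param lineage_path Path to the lineage CSV.
#' @inheritParams track_set
#' @return A [track_set()].
#' @export
read_track_csv <- function(tracks_path, lineage_path, frame_interval_min = 20,
                           microns_per_pixel, n_frames = 217) {
  tracks <- readr::read_csv(
    tracks_path, show_col_types = FALSE,
    col_types = readr::cols(cell_id = readr::col_character(),
                            frame = readr::col_integer(),
                            x = readr::col_double(),
                            y = readr::col_double()))
  lineage <- read_lineage_csv(lineage_path)
  track_set(tracks, lineage, frame_interval_min = frame_interval_min,
            microns_per_pixel = microns_per_pixel, n_frames = n_frames)
}

read_lineage_csv <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE, na = c("", "NA"),
    col_types = readr::cols(cell_id = readr::col_character(),
                            mother_id = readr::col_character(),
                            fate = readr::col_character(),
                            well_id = readr::col_character(),
                            field_id = readr::col_character()))
}

#' Write a track set in the CSV dialect
#'
#' @param ts A [track_set()].
#' @param tracks_path,lineage_path Output paths.
#' @return `ts`, invisibly.
#' @export
write_track_csv <- function(ts, tracks_path, lineage_path) {
  stopifnot(inherits(ts, "track_set"))
  readr::write_csv(ts$tracks, tracks_path)
  readr::write_csv(ts$lineage, lineage_path)
  invisible(ts)
}
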