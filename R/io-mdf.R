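#' Read an MTrackJ .mdf data file
#'
#' Parses the MTrackJ text format (header line beginning `MTrackJ`, then
#' Assembly/Cluster/Track/Point records; a Point record carries
#' `id x y z t channel`). The z coordinate is read and ignored. MTrackJ time
#' indices are 1-based; frames in the returned set are 0-based.
#'
#' The .mdf format carries no pedigree, so lineage links and fates come from
#' a sidecar lineage CSV (`cell_id, mother_id, fate, well_id, field_id`).
#' Without a sidecar every track is treated as a founder and fates are
#' inferred where possible (see [track_set()]).
#'
#' @param path Path to the .mdf file.
#' @param lineage_path Optional path to the lineage sidecar CSV.
#' @inheritParams track_set
#' @return A [track_set()].
#' @export
read_mdf <- function(path, lineage_path = NULL, frame_interval_min = 20,
                     microns_per_pixel, n_frames = 217) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[[1]], "MTrackJ")) {
    abort(paste0("not an MTrackJ data file; first line: ",
                 if (length(lines)) sQuote(lines[[1]]) else "<empty file>"),
          class = "clonherit_format_error")
  }
  cur_track <- NA_character_
  ids <- character(0)
  acc <- vector("list", 0)
  for (i in seq_along(lines)[-1]) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (!length(tok) || tok[[1]] == "") next
    kind <- tok[[1]]
    if (kind %in% c("Assembly", "Cluster", "Displaying", "Offset", "End")) next
    if (kind == "Track") {
      if (length(tok) < 2) {
        abort(paste0("malformed Track record at line ", i, ": ", sQuote(lines[[i]])),
              class = "clonherit_format_error")
      }
      cur_track <- tok[[2]]
      if (cur_track %in% ids) {
        abort(paste0("duplicate track id ", sQuote(cur_track), " at line ", i),
              class = "clonherit_integrity_error")
      }
      ids <- c(ids, cur_track)
    } else if (kind == "Point") {
      if (is.na(cur_track)) {
        abort(paste0("Point record before any Track record at line ", i, ": ",
                     sQuote(lines[[i]])),
              class = "clonherit_format_error")
      }
      val <- suppressWarnings(as.double(tok[-1]))
      if (length(val) < 5 || anyNA(val[1:5])) {
        abort(paste0("malformed Point record at line ", i, ": ", sQuote(lines[[i]])),
              class = "clonherit_format_error")
      }
      acc[[length(acc) + 1L]] <- c(val[2], val[3], val[5])  # x, y, t
      names(acc)[length(acc)] <- cur_track
    } else {
      abort(paste0("unrecognised record ", sQuote(kind), " at line ", i),
            class = "clonherit_format_error")
    }
  }
  if (!length(acc)) abort("no Point records found", class = "clonherit_format_error")
  m <- do.call(rbind, acc)
  tracks <- tibble(cell_id = names(acc),
                   frame = as.integer(round(m[, 3])) - 1L,
                   x = m[, 1], y = m[, 2])
  if (!is.null(lineage_path)) {
    lineage <- read_lineage_csv(lineage_path)
  } else {
    lineage <- tibble(cell_id = ids, mother_id = NA_character_,
                      fate = NA_character_, well_id = "W1", field_id = "P1")
  }
  track_set(tracks, lineage, frame_interval_min = frame_interval_min,
            microns_per_pixel = microns_per_pixel, n_frames = n_frames)
}

#' Write a track set as an MTrackJ .mdf data file
#'
#' Track ids in .mdf are integers; cell ids must therefore be coercible to
#' integer (the simulator's ids are). Pedigree is not representable in .mdf;
#' write the lineage sidecar with [write_track_csv()] alongside.
#'
#' @param ts A [track_set()].
#' @param path Output path.
#' @return `ts`, invisibly.
#' @export
write_mdf <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  ids <- unique(ts$tracks$cell_id)
  int_ids <- suppressWarnings(as.integer(ids))
  if (anyNA(int_ids) || anyDuplicated(int_ids)) {
    abort("mdf track ids must be unique integers; use the CSV dialect for these cell ids",
          class = "clonherit_format_error")
  }
  out <- c("MTrackJ 1.5.1 Data file", "Assembly 1", "Cluster 1")
  for (k in seq_along(ids)) {
    pts <- ts$tracks[ts$tracks$cell_id == ids[[k]], ]
    out <- c(out, paste("Track", int_ids[[k]]),
             sprintf("Point %d %.10g %.10g 1 %d 1",
                     seq_len(nrow(pts)), pts$x, pts$y, pts$frame + 1L))
  }
  out <- c(out, "End of MTrackJ Data file")
  writeLines(out, path)
  invisible(ts)
}
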