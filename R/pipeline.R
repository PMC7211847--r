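#' Run the full heritability pipeline
#'
#' Sequences read -> forest -> traits -> census -> pairs -> estimates ->
#' auxiliary tests -> report, writing every intermediate table as CSV so any
#' reported statistic is auditable, plus a machine-readable `summary.json`.
#' Counts are logged at every filtering step (the exclusion waterfall).
#' Outputs are deterministic: rerunning with an identical configuration
#' reproduces every file byte-for-byte.
#'
#' @param tracks_path,lineage_path Input files. `tracks_path` may be the
#'   tracking CSV dialect or an MTrackJ `.mdf` file (`format`).
#' @param out_dir Output directory, created if needed.
#' @param format `"csv"` or `"mdf"`.
#' @inheritParams track_set
#' @param cell_line Label used in the report.
#' @param sister_mode,cousin_mode Pairing modes (see [enumerate_pairs()]).
#' @param overwrite Refuse to overwrite an existing run unless `TRUE`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the run summary (list, class `h2_run_summary`):
#'   census, per-relationship pair counts, estimate table and auxiliary test
#'   results.
#' @export
run_pipeline <- function(tracks_path, lineage_path, out_dir,
                         format = c("csv", "mdf"),
                         frame_interval_min = 20, microns_per_pixel,
                         n_frames = 217, cell_line = "line1",
                         sister_mode = "first", cousin_mode = "branch",
                         overwrite = FALSE, quiet = FALSE) {
  format <- match.arg(format)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "clonherit_pipeline_error")
    })
  }

  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "summary.json")) &&
      !overwrite) {
    abort(paste0("output directory ", out_dir,
                 " already holds a run; use overwrite = TRUE"),
          class = "clonherit_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ts <- stage("read", {
    if (format == "csv") {
      read_track_csv(tracks_path, lineage_path,
                     frame_interval_min = frame_interval_min,
                     microns_per_pixel = microns_per_pixel, n_frames = n_frames)
    } else {
      read_mdf(tracks_path, lineage_path,
               frame_interval_min = frame_interval_min,
               microns_per_pixel = microns_per_pixel, n_frames = n_frames)
    }
  })
  say(sprintf("read: %d cells, %d positions", n_cells(ts), nrow(ts$tracks)))

  forest <- stage("forest", build_forest(ts))
  say(sprintf("forest: %d families", n_distinct(forest$family_id)))

  traits <- stage("traits", compute_traits(forest, ts))
  write_traits_csv(traits, file.path(out_dir, "traits.csv"))
  census <- stage("census", family_census(traits))
  readr::write_csv(census, file.path(out_dir, "census.csv"))
  say(sprintf(paste0("traits: %d cells; complete %d; excluded: founder %d, ",
                     "off_screen %d, died %d, censored_at_end %d"),
              census$n_cells, census$n_complete, census$n_founder,
              census$n_off_screen, census$n_died, census$n_censored_at_end))
  say(sprintf("census: %d/%d families cousin-eligible; %d usable cells (%.1f%% of tracked)",
              census$n_eligible_families, census$n_families, census$n_usable,
              100 * census$usable_fraction))

  modes <- c(sister_sister = sister_mode, mother_daughter = "daughter_mean",
             cousin_cousin = cousin_mode)
  fits <- list()
  est_rows <- list()
  for (tr in TRAIT_NAMES) {
    for (rel in RELATIONSHIPS) {
      ps <- stage("pairs", enumerate_pairs(traits, rel, tr, modes[[rel]]))
      write_pairs_csv(ps, file.path(out_dir, paste0("pairs_", rel, "_", tr, ".csv")))
      fit <- tryCatch(estimate_h2(ps), error = function(e) NULL)
      if (is.null(fit)) {
        say(sprintf("h2 %s/%s: skipped (%d pairs, too few to fit)", rel, tr, nrow(ps)))
        next
      }
      say(sprintf("h2 %s/%s: %s over %d pairs", rel, tr,
                  format_h2_cell(fit$slope, fit$p_value, fit$r_squared),
                  fit$n_pairs))
      fits[[paste(rel, tr, sep = "_")]] <- fit
      est_rows[[paste(rel, tr, sep = "_")]] <- glance(fit)
    }
  }
  estimates <- bind_rows(est_rows)
  readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))

  aux <- list()
  for (nm in c("speed_generation_correlation", "well_effect_test",
               "offscreen_speed_test")) {
    aux[[nm]] <- tryCatch(do.call(nm, list(traits)),
                          error = function(e) tibble(note = conditionMessage(e)))
  }
  fst <- tryCatch(family_size_speed_test(traits),
                  error = function(e) tibble(note = conditionMessage(e)))
  readr::write_csv(fst, file.path(out_dir, "family_size_tests.csv"))

  report <- stage("report", h2_report(fits, traits, cell_line = cell_line))
  readr::write_csv(as_tibble(report), file.path(out_dir, "report.csv"))
  writeLines(format(report), file.path(out_dir, "report.txt"))

  summary <- list(cell_line = cell_line,
                  census = as.list(census),
                  n_pairs = lapply(fits, function(f) f$n_pairs),
                  estimates = estimates,
                  aux = aux)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("wrote %s", file.path(out_dir, "summary.json")))
  class(summary) <- "h2_run_summary"
  invisible(summary)
}
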