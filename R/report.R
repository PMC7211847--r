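#' Assemble the heritability report row for one cell line
#'
#' Collects the H2 estimates for all relationship x trait combinations into
#' the standard presentation: family count, mean trait values with per-cell
#' standard deviations, and H2 with significance stars and R2 for each
#' relationship, one row per cell line.
#'
#' @param estimates A list of [estimate_h2()] fits (any subset of
#'   relationship x trait combinations).
#' @param traits The trait table the estimates came from.
#' @param cell_line Label for the row (default `"line1"`).
#' @return A tibble of class `h2_report` with numeric columns
#'   (`h2_<trait>_<relationship>`, `r2_...`, `p_...`) and formatted columns
#'   (`fmt_...`, e.g. `"0.62*** (0.44)"`).
#' @export
h2_report <- function(estimates, traits, cell_line = "line1") {
  if (inherits(estimates, "h2_fit")) estimates <- list(estimates)
  if (!length(estimates)) {
    abort("need at least one estimate", class = "clonherit_insufficient_data_error")
  }
  census <- family_census(traits)
  cc <- filter(as_tibble(traits), .data$complete)
  row <- tibble(
    cell_line = cell_line,
    n_families = census$n_families,
    n_eligible_families = census$n_eligible_families,
    mean_speed = mean(cc$speed),
    sd_speed = sd(cc$speed),
    mean_generation_time = mean(cc$generation_time),
    sd_generation_time = sd(cc$generation_time))
  for (e in estimates) {
    key <- paste0(e$trait, "_", sub("_.*", "", e$relationship))
    row[[paste0("h2_", key)]] <- e$slope
    row[[paste0("r2_", key)]] <- e$r_squared
    row[[paste0("p_", key)]] <- e$p_value
    row[[paste0("n_", key)]] <- e$n_pairs
    row[[paste0("fmt_", key)]] <- format_h2_cell(e$slope, e$p_value, e$r_squared)
  }
  class(row) <- c("h2_report", class(row))
  row
}

#' Format one report cell as `H2stars (R2)`
#'
#' @param h2,p,r2 Slope, p-value and R-squared of one fit.
#' @return A character scalar, e.g. `"0.62*** (0.44)"`.
#' @export
format_h2_cell <- function(h2, p, r2) {
  sprintf("%.2g%s (%.2g)", h2, h2_stars(p), r2)
}

#' Render a report as a plain-text table
#'
#' @param x An `h2_report`.
#' @param ... Unused.
#' @return Character vector of lines, invisibly printed.
#' @export
format.h2_report <- function(x, ...) {
  lines <- character(0)
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    lines <- c(lines,
      sprintf("cell line: %s", r$cell_line),
      sprintf("  families: %d (%d with >=1 cousin pair)",
              r$n_families, r$n_eligible_families),
      sprintf("  mean speed: %.2f +/- %.2f um/h", r$mean_speed, r$sd_speed),
      sprintf("  mean generation time: %.2f +/- %.2f h",
              r$mean_generation_time, r$sd_generation_time))
    fmt_cols <- grep("^fmt_", names(r), value = TRUE)
    for (cl in fmt_cols) {
      lines <- c(lines, sprintf("  H2 %-28s %s",
                                sub("^fmt_", "", cl), r[[cl]]))
    }
    lines <- c(lines, "  stars: * p<0.05, ** p<0.01, *** p<0.001")
  }
  lines
}

#' @export
print.h2_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}
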