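#' Estimate broad-sense heritability from a pair set
#'
#' Fits an ordinary least-squares regression of y on x over the pairs of one
#' relationship; the slope is the broad-sense heritability estimate,
#' H2 = Cov(x, y) / Var(x), the clonal adaptation of parent-offspring
#' regression. The slope's two-sided t-test uses `n_pairs - 2` degrees of
#' freedom, except in sister double-entry mode where each dyad appears twice
#' and degrees of freedom are counted on unique dyads (`n_dyads - 2`).
#'
#' @param ps A [enumerate_pairs()] result (or any data frame with numeric
#'   `x` and `y`; relationship/trait metadata then default to `"custom"`).
#' @return An object of class `h2_fit` with elements `slope`, `intercept`,
#'   `slope_se`, `t_statistic`, `p_value`, `r_squared`, `df`, `n_pairs`,
#'   `n_dyads`, `relationship`, `trait`, `mode`, `pairs`, `model`.
#' @seealso [tidy.h2_fit()], [glance.h2_fit()], [autoplot.h2_fit()]
#' @export
#' @examples
#' ps <- tibble::tibble(x = c(1, 2, 3, 4), y = c(1.1, 1.9, 3.2, 3.8))
#' estimate_h2(ps)
estimate_h2 <- function(ps) {
  n <- nrow(ps)
  if (n < 3) {
    abort(paste0("need at least 3 pairs to fit a regression (got ", n, ")"),
          class = "clonherit_insufficient_data_error")
  }
  if (var(ps$x) == 0) {
    abort("Var(x) = 0: the predictor is degenerate",
          class = "clonherit_degenerate_predictor_error")
  }
  n_dyads <- attr(ps, "n_dyads") %||% n
  mode <- attr(ps, "mode") %||% "custom"
  df <- if (identical(mode, "double_entry")) n_dyads - 2L else n - 2L
  if (df < 1) {
    abort("not enough unique dyads for a p-value (df < 1)",
          class = "clonherit_insufficient_data_error")
  }

  fit <- lm(y ~ x, data = ps)
  slope <- unname(coef(fit)[[2]])
  rss <- sum(fit$residuals^2)
  sxx <- sum((ps$x - mean(ps$x))^2)
  se <- sqrt(rss / df / sxx)
  t_stat <- slope / se
  p <- 2 * pt(-abs(t_stat), df)
  r2 <- if (var(ps$y) == 0) 0 else cor(ps$x, ps$y)^2

  structure(
    list(slope = slope, intercept = unname(coef(fit)[[1]]),
         slope_se = se, t_statistic = t_stat, p_value = p,
         r_squared = r2, df = df, n_pairs = n, n_dyads = n_dyads,
         relationship = attr(ps, "relationship") %||% "custom",
         trait = attr(ps, "trait") %||% "custom",
         mode = mode, pairs = as_tibble(ps), model = fit),
    class = "h2_fit")
}

#' Significance stars for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise empty.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
h2_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.h2_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Broad-sense heritability (%s, %s, mode %s)\n",
              x$relationship, x$trait, x$mode))
  cat(sprintf("  H2 = %.*g%s (R2 = %.*g)\n", digits, x$slope,
              h2_stars(x$p_value), digits, x$r_squared))
  cat(sprintf("  slope SE %.*g, t = %.*g on %d df, p = %.3g, n = %d pairs\n",
              digits, x$slope_se, digits, x$t_statistic, x$df, x$p_value,
              x$n_pairs))
  invisible(x)
}

#' Tidy an H2 fit
#'
#' @param x An `h2_fit`.
#' @param ... Unused.
#' @return A tibble with one row per regression term (the slope row carries
#'   the heritability estimate and its adjusted-degrees-of-freedom test).
#' @export
tidy.h2_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope),
         std.error = c(sm[1, 2], x$slope_se),
         statistic = c(sm[1, 3], x$t_statistic),
         p.value = c(sm[1, 4], x$p_value))
}

#' One-row summary of an H2 fit
#'
#' @param x An `h2_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `relationship`, `trait`, `mode`, `h2`,
#'   `std.error`, `statistic`, `p.value`, `r.squared`, `df`, `n_pairs`.
#' @export
glance.h2_fit <- function(x, ...) {
  tibble(relationship = x$relationship, trait = x$trait, mode = x$mode,
         h2 = x$slope, std.error = x$slope_se, statistic = x$t_statistic,
         p.value = x$p_value, r.squared = x$r_squared, df = x$df,
         n_pairs = x$n_pairs)
}

#' Pair scatter with the fitted heritability line
#'
#' The standard presentation of a clonal parent-offspring regression: one
#' point per pair (e.g. a mother and the mean of her daughters) and the
#' least-squares line whose slope is the H2 estimate.
#'
#' @param object An `h2_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.h2_fit <- function(object, ...) {
  lab <- c(speed = "speed (µm/h)", generation_time = "generation time (h)",
           custom = "trait")[object$trait]
  ggplot(object$pairs, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    labs(x = paste("reference cell", lab), y = paste("relative(s) mean", lab),
         title = sprintf("%s: H2 = %.2f%s (R2 = %.2f, n = %d)",
                         gsub("_", "-", object$relationship), object$slope,
                         h2_stars(object$p_value), object$r_squared,
                         object$n_pairs))
}
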