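#' Per-trait generative parameters
#'
#' The trait model on the pedigree is additive Gaussian:
#' `z = mu + g + s + u`, where `g` is a stably heritable component
#' transmitted with AR(1) coefficient `a` (`g_daughter = a * g_mother +
#' delta`, `delta ~ N(0, sigma_delta^2)`), `s` is a transient sister-shared
#' component drawn once per division and given to both daughters, and `u`
#' is independent environmental noise. At stationarity
#' `Var(g) = sigma_g^2 = sigma_delta^2 / (1 - a^2)`; founders draw `g` from
#' that stationary distribution. Supply either `sigma_g` or `sigma_delta`.
#'
#' @param mu Trait mean.
#' @param a Transmission coefficient in `[0, 1)`.
#' @param sigma_g Stationary SD of the heritable component.
#' @param sigma_delta Innovation SD (alternative to `sigma_g`).
#' @param sigma_s Sister-shared SD.
#' @param sigma_u Independent SD.
#' @param floor Positive lower clip for realised trait values.
#' @return A list of class `trait_params` with both `sigma_g` and
#'   `sigma_delta` filled in and `sigma_z` (total SD) attached.
#' @export
trait_params <- function(mu, a, sigma_g = NULL, sigma_delta = NULL,
                         sigma_s, sigma_u, floor = 1e-6) {
  if (is.na(a) || a < 0 || a >= 1) {
    abort("transmission coefficient `a` must lie in [0, 1): the stationary heritable variance sigma_delta^2/(1 - a^2) must be finite",
          class = "clonherit_config_error")
  }
  if (is.null(sigma_g) == is.null(sigma_delta)) {
    abort("supply exactly one of `sigma_g` or `sigma_delta`",
          class = "clonherit_config_error")
  }
  if (is.null(sigma_g)) sigma_g <- sigma_delta / sqrt(1 - a^2)
  if (is.null(sigma_delta)) sigma_delta <- sigma_g * sqrt(1 - a^2)
  stopifnot(sigma_g >= 0, sigma_s >= 0, sigma_u >= 0, floor > 0)
  structure(list(mu = mu, a = a, sigma_g = sigma_g, sigma_delta = sigma_delta,
                 sigma_s = sigma_s, sigma_u = sigma_u, floor = floor,
                 sigma_z = sqrt(sigma_g^2 + sigma_s^2 + sigma_u^2)),
            class = "trait_params")
}

#' Simulation configuration
#'
#' Defaults emulate the recording design of a 72-h time-lapse at 20-min
#' intervals and a fibrosarcoma-like cell line: whole-lifetime speed
#' 37.55 +/- 10.03 um/h with a large stably heritable variance share
#' (motility-like regime), and generation time 14.22 +/- 4.15 h whose
#' familial similarity is almost entirely sister-shared (generation-time-like
#' regime). See the methods vignette for the derivation of the variance
#' split.
#'
#' @param n_founders Number of originally plated founder cells to track.
#' @param n_generations Tracked generations per family (founder = 1st;
#'   default 3, i.e. founder, daughters, granddaughters).
#' @param frame_interval_min Minutes between frames (default 20).
#' @param total_hours Recording span (default 72).
#' @param microns_per_pixel Spatial scale (default 0.65).
#' @param n_wells,fields_per_well Plate layout used for round-robin
#'   well/field assignment of families (defaults 6 and 5).
#' @param speed,generation_time [trait_params()] for each trait.
#' @param turning_kappa Directional persistence of the walk: heading
#'   increments are wrapped-normal with SD `1/sqrt(turning_kappa)`;
#'   `Inf` gives ballistic tracks, `0` gives fresh uniform headings every
#'   step (isotropic walk).
#' @param p_offscreen,p_death Per-cell probabilities of leaving the field of
#'   view or dying before division.
#' @param u_correlation Optional correlation between the independent (`u`)
#'   components of speed and generation time.
#' @param seed Master seed; per-family substreams are derived from it so
#'   growing `n_founders` does not perturb earlier families.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 110,
                       n_generations = 3,
                       frame_interval_min = 20,
                       total_hours = 72,
                       microns_per_pixel = 0.65,
                       n_wells = 6, fields_per_well = 5,
                       speed = trait_params(mu = 37.55, a = 0.97,
                                            sigma_g = sqrt(52),
                                            sigma_s = sqrt(10),
                                            sigma_u = sqrt(38.6009),
                                            floor = 0.1),
                       generation_time = trait_params(mu = 14.22, a = 0.5,
                                                      sigma_g = sqrt(0.5),
                                                      sigma_s = sqrt(7.75),
                                                      sigma_u = sqrt(8.9725),
                                                      floor = 2 * frame_interval_min / 60),
                       turning_kappa = 5,
                       p_offscreen = 0.05, p_death = 0.01,
                       u_correlation = 0,
                       seed = 1L) {
  stopifnot(n_founders >= 1, n_generations >= 1, frame_interval_min > 0,
            total_hours > 0, microns_per_pixel > 0,
            p_offscreen >= 0, p_offscreen <= 1, p_death >= 0, p_death <= 1,
            abs(u_correlation) <= 1, turning_kappa >= 0,
            inherits(speed, "trait_params"),
            inherits(generation_time, "trait_params"))
  # generation time can never be shorter than two frames
  generation_time$floor <- max(generation_time$floor, 2 * frame_interval_min / 60)
  structure(
    list(n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         frame_interval_min = frame_interval_min,
         total_hours = total_hours,
         microns_per_pixel = microns_per_pixel,
         n_wells = as.integer(n_wells),
         fields_per_well = as.integer(fields_per_well),
         speed = speed, generation_time = generation_time,
         turning_kappa = turning_kappa,
         p_offscreen = p_offscreen, p_death = p_death,
         u_correlation = u_correlation,
         n_frames = as.integer(round(total_hours * 60 / frame_interval_min)) + 1L,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Closed-form expected regression slopes under the generative model
#'
#' With `sigma_z^2 = sigma_g^2 + sigma_s^2 + sigma_u^2`, the expected
#' regression slopes (x a single cell's value) are
#' `a * sigma_g^2 / sigma_z^2` (mother-daughter),
#' `(a^2 sigma_g^2 + sigma_s^2) / sigma_z^2` (sister-sister) and
#' `a^4 sigma_g^2 / sigma_z^2` (cousin-cousin). These hold for the pairing
#' modes that keep a single cell on the x axis (`first`/`double_entry`
#' sisters, mother-daughter, `focal` cousins); the `branch` cousin mode puts
#' a branch mean on x, shrinking Var(x) below `sigma_z^2` when a branch has
#' two cells, so its expected slope is larger.
#'
#' @param cfg A [sim_config()].
#' @return A tibble: `trait`, `relationship`, `slope`.
#' @export
expected_slopes <- function(cfg) {
  one <- function(tp, trait) {
    vz <- tp$sigma_z^2
    tibble(trait = trait,
           relationship = RELATIONSHIPS,
           slope = c((tp$a^2 * tp$sigma_g^2 + tp$sigma_s^2) / vz,
                     tp$a * tp$sigma_g^2 / vz,
                     tp$a^4 * tp$sigma_g^2 / vz))
  }
  bind_rows(one(cfg$speed, "speed"),
            one(cfg$generation_time, "generation_time"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d founders x %d generations; %g min frames over %g h (%d frames)\n",
              x$n_founders, x$n_generations, x$frame_interval_min,
              x$total_hours, x$n_frames))
  for (tr in TRAIT_NAMES) {
    tp <- x[[tr]]
    cat(sprintf("  %s: mu %.3g, a %.3g, sigma_g %.3g, sigma_s %.3g, sigma_u %.3g (sigma_z %.3g)\n",
                tr, tp$mu, tp$a, tp$sigma_g, tp$sigma_s, tp$sigma_u, tp$sigma_z))
  }
  cat(sprintf("  censoring: p_offscreen %.3g, p_death %.3g; kappa %.3g; seed %d\n",
              x$p_offscreen, x$p_death, x$turning_kappa, x$seed))
  invisible(x)
}
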