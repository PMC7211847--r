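# Per-family RNG substreams: each family re-seeds the generator from a
# well-mixed hash of (master seed, family index), so growing n_founders
# appends families without perturbing earlier ones. Arithmetically related
# seeds are a known hazard for Mersenne-Twister initialisation, so the
# derivation runs the combined value through a MurmurHash3-style avalanche
# finalizer rather than using an affine offset directly. All arithmetic is
# exact 32-bit modular arithmetic on doubles (< 2^53).

.xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

.mul32 <- function(a, b) {
  (((a * (b %/% 65536)) %% 4294967296) * 65536 + a * (b %% 65536)) %% 4294967296
}

.fmix32 <- function(h) {
  h <- .xor32(h, h %/% 65536)
  h <- .mul32(h, 2246822507)   # 0x85ebca6b
  h <- .xor32(h, h %/% 8192)
  h <- .mul32(h, 3266489909)   # 0xc2b2ae35
  .xor32(h, h %/% 65536)
}

family_seed <- function(seed, fam) {
  h <- (.mul32(as.double(seed) %% 4294967296, 2654435761) +
          .mul32(as.double(fam), 2246822519)) %% 4294967296
  as.integer(.fmix32(h) %% 2147483647)
}

# Full binary pedigree in heap order: node 1 is the founder, node i's mother
# is i %/% 2, generations are floor(log2(i)).
.pedigree_shape <- function(n_generations) {
  n_nodes <- 2L^n_generations - 1L
  list(n_nodes = n_nodes,
       parent = c(NA_integer_, (2:n_nodes) %/% 2L),
       generation = floor(log2(seq_len(n_nodes))),
       n_internal = 2L^(n_generations - 1L) - 1L)
}

# Draw one family's latent components and trait values. Consumes a fixed
# number of draws in a fixed order so the trait block of the stream is
# identical between simulate_pedigree_traits() and simulate_trackset().
.draw_family_traits <- function(cfg, shape) {
  n <- shape$n_nodes
  ns <- shape$n_internal + 1L
  draw_one <- function(tp, eps_u) {
    eps_g <- rnorm(n)
    eps_s <- rnorm(ns)
    g <- numeric(n)
    g[1] <- tp$sigma_g * eps_g[1]
    if (n > 1) {
      i <- 2:n
      # level-by-level AR(1) transmission down the tree
      for (gen in seq_len(max(shape$generation))) {
        idx <- i[shape$generation[i] == gen]
        g[idx] <- tp$a * g[shape$parent[idx]] + tp$sigma_delta * eps_g[idx]
      }
    }
    # child i inherits the s drawn at its mother's division; the founder's
    # own s comes from its untracked mother's division (last slot)
    s <- tp$sigma_s * eps_s[c(ns, shape$parent[-1])]
    u <- tp$sigma_u * eps_u
    list(g = g, s = s, u = u, z = pmax(tp$floor, tp$mu + g + s + u))
  }
  eps_u_sp <- rnorm(n)
  sp <- draw_one(cfg$speed, eps_u_sp)
  eps_u_gt_raw <- rnorm(n)
  rho <- cfg$u_correlation
  gt <- draw_one(cfg$generation_time,
                 rho * eps_u_sp + sqrt(1 - rho^2) * eps_u_gt_raw)
  list(speed = sp, generation_time = gt)
}

#' Simulate trait values on branching pedigrees
#'
#' Draws the latent heritable (`g`), sister-shared (`s`) and independent
#' (`u`) components for every cell of `n_founders` full binary families and
#' returns the realised trait values together with the closed-form expected
#' regression slopes (the ground truth for parameter recovery). Founders
#' draw `g` from its stationary distribution, so component variances are
#' constant across generations.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ground_truth`: `cells` (tibble with pedigree,
#'   well/field labels, latent components and trait values), `expected`
#'   ([expected_slopes()]), `config`.
#' @export
simulate_pedigree_traits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  shape <- .pedigree_shape(cfg$n_generations)
  n <- shape$n_nodes
  nf <- cfg$n_founders
  cols <- c("g_speed", "s_speed", "u_speed", "speed",
            "g_generation_time", "s_generation_time", "u_generation_time",
            "generation_time")
  buf <- matrix(NA_real_, nf * n, length(cols), dimnames = list(NULL, cols))
  for (f in seq_len(nf)) {
    set.seed(family_seed(cfg$seed, f))
    d <- .draw_family_traits(cfg, shape)
    rows <- ((f - 1L) * n + 1L):(f * n)
    buf[rows, ] <- cbind(d$speed$g, d$speed$s, d$speed$u, d$speed$z,
                         d$generation_time$g, d$generation_time$s,
                         d$generation_time$u, d$generation_time$z)
  }
  fam <- rep(seq_len(nf), each = n)
  base <- (fam - 1L) * n
  node <- rep(seq_len(n), nf)
  parent <- rep(shape$parent, nf)
  cells <- tibble(
    cell_id = as.character(base + node),
    mother_id = ifelse(is.na(parent), NA_character_, as.character(base + parent)),
    family_id = sprintf("F%05d", fam),
    generation = rep(shape$generation, nf),
    well_id = paste0("W", ((fam - 1L) %% cfg$n_wells) + 1L),
    field_id = paste0("P", ((fam - 1L) %/% cfg$n_wells) %% cfg$fields_per_well + 1L),
    as_tibble(buf))
  structure(list(cells = cells, expected = expected_slopes(cfg), config = cfg),
            class = "ground_truth")
}

#' Idealised trait table from simulated ground truth
#'
#' Converts a [simulate_pedigree_traits()] result into a trait table as if
#' every non-founder cell had been observed for a complete cycle (founders
#' are excluded, as their birth is never observed). This is the
#' fully-observed pathway used for estimator validation; realised tracking
#' data with censoring comes from [simulate_trackset()].
#'
#' @param gt A `ground_truth`.
#' @return A tibble of class `trait_table`.
#' @export
truth_trait_table <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  out <- gt$cells |>
    mutate(exclusion_reason = ifelse(is.na(.data$mother_id), "founder", "none"),
           complete = .data$exclusion_reason == "none",
           observed_hours = .data$generation_time,
           generation_time = ifelse(.data$complete, .data$generation_time, NA_real_),
           path_length = .data$speed * .data$observed_hours,
           net_displacement = NA_real_) |>
    select("cell_id", "mother_id", "family_id", "well_id", "field_id",
           "generation", "complete", "exclusion_reason", "generation_time",
           "observed_hours", "speed", "path_length", "net_displacement")
  class(out) <- c("trait_table", class(out))
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells in %d families (%d generations)\n",
              nrow(x$cells), x$config$n_founders, x$config$n_generations))
  print(x$expected, ...)
  invisible(x)
}
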