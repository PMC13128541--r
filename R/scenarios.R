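#' Prebuilt synthetic study designs
#'
#' Three ready-made [synthetic_design()]s used throughout the package's
#' validation:
#'
#' * `scenario_recovery()` — the parameter-recovery benchmark: four 5-taxon
#'   positive blocks and four negative pairs at latent rho 0.95 active in
#'   every treatment, plus two hub cores (64-spoke grouped hubs, see
#'   [block_spec()]; 20-fold enriched under severe drought, prevalence
#'   target 0.9), 15 samples per treatment at depth 50,000.
#' * `scenario_root_like()` — association density and strength increase and
#'   replicate noise decreases along CK -> MD -> SD, with fragile chain
#'   topology only in CK: the drought-stressed root pattern (stability rises
#'   under drought).
#' * `scenario_rhizosphere_like()` — the mirror image (density falls, noise
#'   rises, fragile topology under SD): the rhizosphere pattern.
#'
#' @param seed Master RNG seed passed to the design.
#' @return A `synthetic_design`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_recovery <- function(seed = 1L) {
  blocks <- bind_rows(
    block_spec(5, rho = 0.95, type = "block"),
    block_spec(5, rho = 0.95, type = "block"),
    block_spec(5, rho = 0.95, type = "block"),
    block_spec(5, rho = 0.95, type = "block", kingdom = "fungus"),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair"),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair"),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair"),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", kingdom = "protist"),
    block_spec(64, rho = 0.95, type = "hub"),
    block_spec(64, rho = 0.95, type = "hub")
  )
  cores <- bind_rows(
    core_spec(hub = 9, fold = 20, habitat = "SD", prevalence = 0.9),
    core_spec(hub = 10, fold = 20, habitat = "SD", prevalence = 0.9)
  )
  synthetic_design(
    n_taxa = c(prokaryote = 300, fungus = 200, protist = 150),
    depth_mean = 50000, blocks = blocks, cores = cores,
    noise_sd = 1, seed = seed)
}

# Graded designs for the directional (treatment-contrast) property. `up`
# means association density/strength increase with drought severity while
# replicate noise decreases (the root pattern); `down` is the reverse.
scenario_gradient <- function(direction = c("up", "down"), seed = 1L) {
  direction <- match.arg(direction)
  tr <- c("CK", "MD", "SD")
  lo <- tr[1]; mid <- tr[2]; hi <- tr[3]
  if (direction == "down") { lo <- tr[3]; hi <- tr[1] }
  # `hi` = the treatment with the dense, redundant, quiet community
  blocks <- bind_rows(
    # sparse treatment: a lone fragile chain and no negative complement —
    # cutting its middle collapses most of what little efficiency exists
    block_spec(7, rho = 0.90, type = "chain", treatments = lo),
    # mid: the same chain shape embedded in a larger wired context, so
    # the worst single-node loss is diluted; blocks accumulate
    block_spec(7, rho = 0.90, type = "chain", treatments = mid),
    block_spec(5, rho = 0.95, type = "block", treatments = c(mid, hi)),
    block_spec(5, rho = 0.95, type = "block", treatments = c(mid, hi)),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = c(mid, hi)),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = c(mid, hi)),
    # hi only: larger, redundant blocks (natural connectivity tracks the
    # largest clique) and a heavier negative complement
    block_spec(6, rho = 0.95, type = "block", treatments = hi),
    block_spec(7, rho = 0.95, type = "block", treatments = hi),
    block_spec(8, rho = 0.95, type = "block", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi),
    block_spec(2, rho = 0.95, sign = -1L, type = "pair", treatments = hi)
  )
  noise <- c(1.3, 1.0, 0.75)
  names(noise) <- c(lo, mid, hi)
  # planted taxa sit at 0.25% so that even in the low-dispersion (stable)
  # treatment their counts give enough rank resolution: at 0.1% and these
  # depths, multinomial noise rivals the quiet treatment's dispersion and
  # erodes exactly the dense network the gradient is supposed to show
  synthetic_design(
    n_taxa = c(prokaryote = 300, fungus = 200, protist = 150),
    depth_mean = c(prokaryote = 30000, fungus = 9000, protist = 8000),
    planted_rel = 2.5e-3,
    blocks = blocks, noise_sd = noise, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_root_like <- function(seed = 1L) scenario_gradient("up", seed)

#' @rdname scenarios
#' @export
scenario_rhizosphere_like <- function(seed = 1L) scenario_gradient("down", seed)
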