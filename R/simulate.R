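#' Specify a planted correlation block
#'
#' Building block of a [synthetic_design()]. Four structures are available:
#' \describe{
#'   \item{`block`}{an exchangeable positive block: all member pairs at the
#'     target latent correlation `rho` (a clique in the true network).}
#'   \item{`pair`}{a correlated pair, the only structure allowed to carry a
#'     negative sign: an all-negative block of size > 2 has no
#'     positive-semidefinite correlation matrix.}
#'   \item{`hub`}{a hub centre plus `size` spokes in four groups
#'     (`size` divisible by 4). The centre correlates with every spoke at
#'     `rho` and spokes within a group also sit at `rho`; cross-group
#'     spoke correlations are pushed to their geometric floor
#'     `rho^2 - (rho - rho^2)/3` (0.887 at `rho` = 0.95) — positive
#'     semi-definiteness forbids sparser neighbourhoods around a common
#'     centre. At the default edge rule the centre's ties are detected
#'     nearly always and cross-group ties are missed about a third of the
#'     time, so the centre carries a clear within-module degree excess in
#'     the merged module (module hub, `Zi` > 2.5) or, if the groups split,
#'     an even spread over four modules (connector). The centre is a
#'     planted keystone hub and the core taxon when referenced by
#'     [core_spec()].}
#'   \item{`chain`}{a first-order autoregressive chain: adjacent members at
#'     `rho`, members `l` steps apart at `rho^l`. Removing a middle member
#'     fragments the structure, so chains plant fragile (high-vulnerability)
#'     topology.}
#'   \item{`guild`}{an antagonist facing a guild of four cooperating
#'     sub-blocks (`size` members in total, divisible by 4). Sub-block
#'     mates correlate at `rho` (0.95 by default); the antagonist is
#'     anti-correlated at -0.82 with every guild member, a strength
#'     chosen so that the cross-sub-block couplings the geometry forces
#'     (about 0.58) stay below the edge-detection window while each
#'     sub-block is heavy enough to form its own network module. The
#'     antagonist then collects negative edges spread across all four
#'     modules: a planted connector keystone, in the manner of a
#'     competitive-exclusion core taxon. The correlation matrix is built
#'     as the Gram matrix of explicit unit vectors, so it is positive
#'     semi-definite by construction. Referenced by [core_spec()].}
#' }
#'
#' @param size Number of member taxa (spokes, for `hub`).
#' @param rho Target latent pairwise correlation in `[-1, 1]`.
#' @param sign `+1` or `-1`; `-1` only for `type = "pair"`.
#' @param kingdom Kingdom the members are drawn from.
#' @param treatments Treatments in which the block's correlation is active
#'   (`NULL` = all treatments of the design).
#' @param type One of `"block"`, `"pair"`, `"hub"`, `"chain"`, `"guild"`.
#' @return A one-row tibble; bind rows of these into the `blocks` argument
#'   of [synthetic_design()].
#' @export
block_spec <- function(size, rho = 0.95, sign = 1L, kingdom = "prokaryote",
                       treatments = NULL,
                       type = c("block", "pair", "hub", "chain", "guild")) {
  type <- match.arg(type)
  if (abs(rho) > 1) abort("block `rho` must be in [-1, 1].")
  if (sign < 0 && type != "pair") {
    abort("negative blocks are generated pairwise (type = 'pair'); an all-negative block of size > 2 is not positive semi-definite.")
  }
  if (type == "pair" && size != 2L) abort("type 'pair' requires size 2.")
  if (type %in% c("guild", "hub") && (size %% 4 != 0 || size < 16)) {
    abort(sprintf("type '%s' requires size divisible by 4 and >= 16 (four spoke groups / sub-blocks).", type))
  }
  if (type == "guild" && (rho < 0.9 || rho > 0.98)) {
    abort("guild within-sub-block correlation must lie in [0.9, 0.98] (antagonist geometry).")
  }
  if (size < 2L) abort("blocks need at least 2 member taxa.")
  tibble(size = as.integer(size), rho = rho, sign = as.integer(sign),
         kingdom = kingdom, treatments = list(treatments), type = type)
}

#' Specify a planted core taxon
#'
#' A core taxon is the hub centre of a `hub`-type block that is additionally
#' treatment-enriched (fold-change of its latent mean abundance in its
#' habitat treatment) and prevalent (baseline abundance high enough that it
#' is present in at least `prevalence` of samples at the design depth). By
#' construction every planted core is a planted hub and a planted habitat
#' specialist.
#'
#' @param hub Index (into the design's `blocks` rows) of a `hub`-type block
#'   whose centre becomes the core taxon.
#' @param fold Enrichment fold of latent mean abundance in `habitat`.
#' @param habitat Treatment label the core is enriched in.
#' @param prevalence Target minimum fraction of samples in which the core is
#'   present (default 0.9).
#' @return A one-row tibble for the `cores` argument of [synthetic_design()].
#' @export
core_spec <- function(hub, fold = 20, habitat = "SD", prevalence = 0.9) {
  if (fold <= 0) abort("`fold` must be positive.")
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1).")
  tibble(hub = as.integer(hub), fold = fold, habitat = habitat,
         prevalence = prevalence)
}

#' Design of a synthetic multi-kingdom community
#'
#' Describes the study layout (treatments x growth stages x replicates for
#' one compartment), the sequencing depth per kingdom, and the planted
#' structure: correlated blocks, hub centres and treatment-enriched core
#' taxa. Latent abundances are log-normal with block-structured correlation
#' imposed through a Gaussian copula, so marginal abundance and correlation
#' are controlled independently; counts are multinomial draws per sample at
#' a log-normally varying depth.
#'
#' @param n_taxa Named integer vector of taxa per kingdom. The defaults
#'   (600/300/250) keep each kingdom's composition rich: in small
#'   communities the share variance concentrates in a handful of taxa
#'   and closure then forces strong structural negative correlations
#'   between them (the small-composition bias), which a correlation
#'   network would pick up as spurious edges.
#' @param treatments,stages Treatment and growth-stage labels.
#' @param n_replicates Replicates per treatment x stage (>= 3; Spearman
#'   p-values are degenerate below that).
#' @param compartment Compartment label stamped into the sample metadata.
#' @param depth_mean Mean sequencing depth per kingdom (named vector or a
#'   scalar recycled over kingdoms); libraries are drawn log-normally
#'   around it so rarefaction is exercised.
#' @param depth_sdlog Log-scale sd of library depth (default 0.1).
#' @param blocks Tibble of [block_spec()] rows (may be `NULL`).
#' @param cores Tibble of [core_spec()] rows (may be `NULL`).
#' @param noise_sd Replicate-instability scale, a scalar or a named vector
#'   per treatment. It sets the log-scale dispersion of the planted
#'   (structured) taxa directly — Spearman correlation is rank-based, so
#'   planted correlation structure is invariant to this scale — and
#'   drives the background community's colonization dropout through
#'   `dropout_coef`. Dropout, not dispersion, is the AVD-relevant channel:
#'   the standardised deviation `E|x - mean|/sd` is scale-free, so wider
#'   log-normal noise actually lowers it (heavier tails), whereas
#'   replicates diverging in which taxa they carry — near-binary
#'   presence profiles, the signature of a destabilised community —
#'   push it up.
#' @param bg_noise_sd Log-scale dispersion of background (non-planted)
#'   taxa, fixed at 0.35 by default: the background rides a modest
#'   everyday fluctuation while instability expresses itself through
#'   dropout. Keeping this small also stabilises the compositional
#'   denominator that all relative abundances share.
#' @param dropout_coef Colonization-dropout coefficient: each background
#'   taxon independently fails to colonise a sample with probability
#'   `min(0.6, dropout_coef * noise_sd^2)` (default 0.25). Planted taxa
#'   are exempt so the controlled correlation structure is not eroded.
#' @param base_abund_sdlog Spread (sd of log) of baseline mean abundances
#'   across taxa; the default 2 gives a realistic long-tailed
#'   rank-abundance curve with many rare taxa.
#' @param max_rel Cap on any single taxon's baseline share of its kingdom
#'   (default 0.03). Without it a lone dominant taxon makes the kingdom
#'   total swing coherently, and that shared compositional denominator
#'   systematically attenuates planted negative correlations.
#' @param noise_damp_ref,noise_damp_gamma Taylor's-law-like damping of
#'   per-sample dispersion for abundant taxa: a taxon with baseline share
#'   `s` gets noise scale `noise_sd * (noise_damp_ref / max(s,
#'   noise_damp_ref))^noise_damp_gamma`. Defaults (0.002, 0.35) leave taxa
#'   below 0.2% share at full dispersion while dominant taxa fluctuate
#'   proportionally less, as in real communities — which also keeps the
#'   per-sample library composition from being whipsawed by single
#'   dominant-taxon spikes. Correlations are scale-free, so damping does
#'   not alter planted correlation structure.
#' @param planted_rel Baseline mean relative abundance assigned to planted
#'   taxa so they clear the 0.01% network filter (default 1e-3).
#' @param seed Master RNG seed; every downstream draw derives from it.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_taxa = c(prokaryote = 600, fungus = 300, protist = 250),
                             treatments = c("CK", "MD", "SD"),
                             stages = c("tillering", "jointing", "ripening"),
                             n_replicates = 5,
                             compartment = "root",
                             depth_mean = c(prokaryote = 30000, fungus = 9000,
                                            protist = 8000),
                             depth_sdlog = 0.1,
                             blocks = NULL,
                             cores = NULL,
                             noise_sd = 1,
                             bg_noise_sd = 0.35,
                             dropout_coef = 0.25,
                             base_abund_sdlog = 2,
                             max_rel = 0.03,
                             noise_damp_ref = 0.002,
                             noise_damp_gamma = 0.35,
                             planted_rel = 1e-3,
                             seed = 1L) {
  if (is.null(names(n_taxa))) abort("`n_taxa` must be named by kingdom.")
  if (n_replicates < 3) abort("n_replicates must be >= 3 (Spearman p-values are degenerate otherwise).")
  if (length(depth_mean) == 1L) {
    depth_mean <- stats::setNames(rep(depth_mean, length(n_taxa)), names(n_taxa))
  }
  if (any(depth_mean <= 0)) abort("sequencing depth must be positive.")
  if (length(noise_sd) == 1L) {
    noise_sd <- stats::setNames(rep(noise_sd, length(treatments)), treatments)
  }
  if (!all(treatments %in% names(noise_sd))) {
    abort("`noise_sd` must cover every treatment.")
  }
  if (any(noise_sd <= 0)) abort("`noise_sd` must be positive.")
  if (!is.null(blocks)) {
    blocks <- as_tibble(blocks)
    bad_tr <- setdiff(unlist(blocks$treatments), treatments)
    if (length(bad_tr) > 0) {
      abort(paste0("block treatments not in design: ", paste(bad_tr, collapse = ", ")))
    }
    bad_k <- setdiff(blocks$kingdom, names(n_taxa))
    if (length(bad_k) > 0) {
      abort(paste0("block kingdoms not in design: ", paste(bad_k, collapse = ", ")))
    }
  }
  if (!is.null(cores)) {
    cores <- as_tibble(cores)
    if (is.null(blocks) || any(cores$hub > nrow(blocks)) ||
        !all(blocks$type[cores$hub] %in% c("hub", "guild"))) {
      abort("every core must reference a 'hub'- or 'guild'-type block row.")
    }
    if (!all(cores$habitat %in% treatments)) {
      abort("core habitats must be design treatments.")
    }
  }
  design <- structure(
    list(n_taxa = n_taxa, treatments = treatments, stages = stages,
         n_replicates = as.integer(n_replicates), compartment = compartment,
         depth_mean = depth_mean, depth_sdlog = depth_sdlog,
         blocks = blocks, cores = cores, noise_sd = noise_sd,
         bg_noise_sd = bg_noise_sd, dropout_coef = dropout_coef,
         base_abund_sdlog = base_abund_sdlog, max_rel = max_rel,
         noise_damp_ref = noise_damp_ref, noise_damp_gamma = noise_damp_gamma,
         planted_rel = planted_rel,
         seed = as.integer(seed)),
    class = "synthetic_design")
  # allocation doubles as a capacity check
  invisible(allocate_taxa(design))
  design
}

# Assign member taxon indices (within the global taxon vector) to each block.
# Blocks are disjoint; members are claimed kingdom by kingdom in row order.
allocate_taxa <- function(design) {
  n_total <- sum(design$n_taxa)
  kingdom_of <- rep(names(design$n_taxa), design$n_taxa)
  ids <- paste0("zOTU_", seq_len(n_total))
  next_free <- cumsum(c(1, utils::head(design$n_taxa, -1)))
  names(next_free) <- names(design$n_taxa)
  members <- list()
  if (!is.null(design$blocks)) {
    for (b in seq_len(nrow(design$blocks))) {
      k <- design$blocks$kingdom[b]
      n_mem <- design$blocks$size[b] +
        as.integer(design$blocks$type[b] %in% c("hub", "guild"))
      idx <- seq(next_free[[k]], length.out = n_mem)
      kingdom_end <- sum(design$n_taxa[seq_len(match(k, names(design$n_taxa)))])
      if (max(idx) > kingdom_end) {
        abort(sprintf("block %d does not fit: kingdom '%s' has too few taxa left.", b, k))
      }
      next_free[[k]] <- max(idx) + 1L
      members[[b]] <- idx
    }
  }
  list(ids = ids, kingdom_of = kingdom_of, members = members)
}

# Correlation matrix of one block; errors if not positive semi-definite.
block_sigma <- function(spec, n_mem, label) {
  r <- spec$rho * spec$sign
  sig <- switch(spec$type,
    block = ,
    pair = {
      s <- matrix(r, n_mem, n_mem); diag(s) <- 1; s
    },
    hub = tcrossprod(hub_vectors(n_mem - 1L, r)),
    chain = {
      lag <- abs(outer(seq_len(n_mem), seq_len(n_mem), "-"))
      r^lag
    },
    guild = tcrossprod(guild_vectors(n_mem - 1L, r)))
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf("correlation matrix of block '%s' is not positive semi-definite (min eigenvalue %.3g).",
                  label, min(ev)))
  }
  sig
}

# Unit-vector embedding of the hub structure: row 1 the hub centre x,
# then four spoke groups of m/4 members.
#   centre            = e1
#   spoke in group k  = rho e1 + sqrt(1-rho^2) (alpha U_k + beta W_j)
# with U_k four tetrahedral directions (pairwise cos -1/3) and
# alpha^2 = rho/(1+rho) so that group mates also sit at rho. The grouping
# pushes cross-group spoke correlations down to
# rho^2 - (rho - rho^2)/3 (0.887 at rho = 0.95), the geometric floor for
# spokes around a common centre; closer to the centre tie than one would
# like, but positive semi-definiteness forbids sparser neighbourhoods.
# At the |rho| > 0.8, 15-sample edge rule the centre's ties are detected
# almost surely while cross-group spoke pairs are missed ~1/3 of the
# time, so in the (usual) fully-merged Louvain module the centre has a
# clear within-module degree excess (module hub); if the groups are ever
# split apart, the centre's edges spread evenly over four modules
# (connector). Either role is a keystone.
hub_vectors <- function(m, rho) {
  per <- m %/% 4L
  alpha <- sqrt(rho / (1 + rho))
  u <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  d <- 4L + m
  v <- matrix(0, m + 1L, d)
  v[1, 1] <- 1
  row <- 2L
  for (k in 1:4) {
    for (j in seq_len(per)) {
      v[row, 1] <- rho
      v[row, 2:4] <- sqrt(1 - rho^2) * alpha * u[k, ]
      v[row, 4L + row - 1L] <- sqrt(1 - rho^2) * sqrt(1 - alpha^2)
      row <- row + 1L
    }
  }
  v
}

# Unit-vector embedding of the antagonist-guild structure: row 1 the
# antagonist x, then four sub-blocks of m/4 members. The Gram matrix of
# these rows is the block's correlation matrix (PSD by construction).
#   antagonist            = e1
#   member of sub-block k = -q e1 + sqrt(1-q^2) (alpha U_k + beta W_j)
# with U_k four tetrahedral directions (pairwise cos -1/3) and
# alpha^2 = (rho - q^2)/(1 - q^2) so block mates sit exactly at rho.
# The tie strength q and the sub-block size balance three pressures at
# the |rho| > 0.8, 15-sample edge rule. (i) The antagonist's ties must be
# strong enough to be detected a few times per sub-block. (ii) The
# cross-sub-block couplings the ties force, q^2 - (rho - q^2)/3, must
# stay below the detection window or cross edges fuse the sub-blocks.
# (iii) Each sub-block needs enough internal edges that Louvain does not
# fuse the antagonist's neighbour modules through the antagonist's own
# star of edges — small sub-blocks are always absorbed. q = 0.82 with
# sub-blocks of 8 satisfies all three; ties at -0.95 (or pair-sized
# sub-blocks) collapse the guild into a single module and the antagonist
# degenerates from a connector into an ordinary module member.
guild_vectors <- function(m, rho, q = 0.82) {
  per <- m %/% 4L
  alpha <- sqrt((rho - q^2) / (1 - q^2))
  u <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  d <- 4L + m # e1, 3 dims for U, one W dim per member
  v <- matrix(0, m + 1L, d)
  v[1, 1] <- 1
  row <- 2L
  for (k in 1:4) {
    for (j in seq_len(per)) {
      v[row, 1] <- -q
      v[row, 2:4] <- sqrt(1 - q^2) * alpha * u[k, ]
      v[row, 4L + row - 1L] <- sqrt(1 - q^2) * sqrt(1 - alpha^2)
      row <- row + 1L
    }
  }
  v
}

# Latent pairwise correlations a block implies, split into deliberately
# planted pairs and ambient by-products of the PSD geometry.
block_truth_edges <- function(spec, ids) {
  n <- length(ids)
  planted <- ambient <- NULL
  pair_rows <- function(i, j, rho, class) {
    tibble(from = ids[i], to = ids[j], rho_latent = rho,
           sign = ifelse(rho > 0, 1L, -1L), class = class)
  }
  if (spec$type %in% c("block", "pair")) {
    cmb <- utils::combn(n, 2)
    planted <- pair_rows(cmb[1, ], cmb[2, ], spec$rho * spec$sign, "planted")
  } else if (spec$type == "hub") {
    sig <- tcrossprod(hub_vectors(n - 1L, spec$rho))
    cmb <- utils::combn(n, 2)
    rho_pair <- sig[cbind(cmb[1, ], cmb[2, ])]
    keepable <- abs(rho_pair) > 0.5
    planted <- pair_rows(cmb[1, keepable], cmb[2, keepable],
                         round(rho_pair[keepable], 6), "planted")
  } else if (spec$type == "chain") {
    planted <- pair_rows(1:(n - 1L), 2:n, spec$rho, "planted")
    if (n > 2) {
      cmb <- utils::combn(n, 2)
      lag <- cmb[2, ] - cmb[1, ]
      far <- lag >= 2 & spec$rho^lag > 0.5
      if (any(far)) {
        ambient <- pair_rows(cmb[1, far], cmb[2, far], spec$rho^lag[far], "ambient")
      }
    }
  } else if (spec$type == "guild") {
    sig <- tcrossprod(guild_vectors(n - 1L, spec$rho))
    cmb <- utils::combn(n, 2)
    rho_pair <- sig[cbind(cmb[1, ], cmb[2, ])]
    keepable <- abs(rho_pair) > 0.5
    planted <- pair_rows(cmb[1, keepable], cmb[2, keepable],
                         round(rho_pair[keepable], 6), "planted")
  }
  out <- bind_rows(planted, ambient)
  # scoring classes follow the detection window: pairs at |rho| >= 0.9 are
  # reliably detectable at the default edge rule; weaker planted structure
  # sits in a twilight band and is excluded from edge-recovery scoring
  out$class <- ifelse(abs(out$rho_latent) >= 0.9, "planted", "ambient")
  out
}

#' Generate a synthetic count table with known ground truth
#'
#' Draws the community described by a [synthetic_design()]: correlated
#' standard-normal latents per treatment (Gaussian copula over the design's
#' blocks), log-normal latent abundances, per-kingdom multinomial counts at
#' log-normally drawn depths. Fully reproducible from the design seed; one
#' RNG stream per operation so partial reruns stay stable.
#'
#' @param design A `synthetic_design`.
#' @return A list with elements `table` (a [count_table()]) and `truth`
#'   (a `ground_truth`: planted/ambient latent edges with the treatments in
#'   which they are active, planted hub, specialist and core taxa).
#' @export
simulate_community <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  alloc <- allocate_taxa(design)
  n_total <- length(alloc$ids)
  treatments <- design$treatments

  sample_meta <- tidyr::expand_grid(
    treatment = treatments, stage = design$stages,
    replicate = seq_len(design$n_replicates)) |>
    mutate(compartment = design$compartment,
           sample_id = paste(.data$compartment, .data$treatment, .data$stage,
                             paste0("r", .data$replicate), sep = "_")) |>
    select("sample_id", "compartment", "treatment", "stage", "replicate")
  n_samples <- nrow(sample_meta)

  # stream 1: baseline abundances ------------------------------------------
  w <- with_seed(derive_seed(design$seed, 1L),
                 exp(stats::rnorm(n_total, 0, design$base_abund_sdlog)))
  # cap dominance per kingdom: a single overwhelming taxon makes the
  # compositional denominator a shared noise source for every other taxon
  for (k in names(design$n_taxa)) {
    in_k <- which(alloc$kingdom_of == k)
    for (i in 1:3) w[in_k] <- pmin(w[in_k], design$max_rel * sum(w[in_k]))
  }
  planted_idx <- sort(unique(unlist(alloc$members)))
  # planted taxa get a fixed baseline relative abundance so they clear the
  # 0.01% screen; cores may need more to hit their prevalence target
  if (length(planted_idx) > 0) {
    for (k in names(design$n_taxa)) {
      in_k <- which(alloc$kingdom_of == k)
      pk <- intersect(planted_idx, in_k)
      if (length(pk) == 0) next
      noise_total <- sum(w[setdiff(in_k, pk)])
      share <- design$planted_rel
      w[pk] <- share / (1 - length(pk) * share) * noise_total
    }
  }
  fold <- matrix(1, n_total, length(treatments),
                 dimnames = list(alloc$ids, treatments))
  if (!is.null(design$cores)) {
    for (ci in seq_len(nrow(design$cores))) {
      core_idx <- alloc$members[[design$cores$hub[ci]]][1]
      fold[core_idx, design$cores$habitat[ci]] <- design$cores$fold[ci]
      # the core starts from a modest baseline and is raised to ordinary
      # planted abundance by its enrichment; the baseline must still keep
      # it present in >= `prevalence` of samples, which at depth d needs
      # rel >= -log(1 - prevalence)/d (Poisson tail)
      k <- alloc$kingdom_of[core_idx]
      need <- -log(1 - design$cores$prevalence[ci]) / design$depth_mean[[k]]
      # also clear the 0.01% within-kingdom screen in unenriched
      # treatments (a shared taxon must be detected after the filter in
      # every treatment); the baseline is independent of the fold so the
      # realised habitat abundance grows strictly with enrichment
      target <- max(need, 2.5e-4)
      in_k <- which(alloc$kingdom_of == k)
      w[core_idx] <- target / (1 - target) * sum(w[in_k][-match(core_idx, in_k)])
    }
  }

  # stream 2: correlated latents per treatment ------------------------------
  z <- with_seed(derive_seed(design$seed, 2L), {
    z <- matrix(stats::rnorm(n_total * n_samples), n_total, n_samples)
    if (!is.null(design$blocks)) {
      for (b in seq_len(nrow(design$blocks))) {
        spec <- design$blocks[b, ]
        active <- spec$treatments[[1]] %||% treatments
        mem <- alloc$members[[b]]
        sig <- block_sigma(spec, length(mem), paste0("block ", b))
        ch <- chol(sig + diag(1e-10, length(mem)))
        cols <- which(sample_meta$treatment %in% active)
        z[mem, cols] <- t(ch) %*% z[mem, cols, drop = FALSE]
      }
    }
    z
  })

  # latent abundances: log-normal around baseline, treatment noise scale,
  # with Taylor's-law-like damping of dispersion for abundant taxa
  # shares include treatment enrichment (max over treatments), so an
  # enriched core is damped according to the abundance it actually reaches
  w_max <- w * apply(fold, 1, max)
  share <- unlist(lapply(names(design$n_taxa), function(k) {
    in_k <- alloc$kingdom_of == k
    w_max[in_k] / sum(w_max[in_k])
  }))
  damp <- (design$noise_damp_ref / pmax(share, design$noise_damp_ref))^design$noise_damp_gamma
  # planted taxa keep their specified dispersion: damping is a realism
  # device for the dominant background, and compressing a planted taxon's
  # signal towards the count/compositional noise floor erodes the very
  # correlations the design plants
  damp[planted_idx] <- 1
  sd_t <- design$noise_sd[sample_meta$treatment]
  background <- setdiff(seq_len(n_total), planted_idx)
  # per-taxon dispersion: planted taxa carry the treatment's instability
  # scale, background taxa a modest fixed fluctuation
  sigma <- matrix(sd_t, n_total, n_samples, byrow = TRUE)
  sigma[background, ] <- design$bg_noise_sd
  fold_s <- fold[, sample_meta$treatment, drop = FALSE]
  lat <- w * fold_s * exp(damp * sigma * z)

  # colonization dropout: replicates of an unstable treatment diverge in
  # which background taxa they carry; planted taxa are exempt so the
  # controlled correlation structure survives
  p_drop <- pmin(0.6, design$dropout_coef * sd_t^2)
  if (any(p_drop > 0) && length(background) > 0) {
    drop_mask <- with_seed(derive_seed(design$seed, 5L), {
      matrix(stats::runif(length(background) * n_samples),
             length(background)) <
        matrix(p_drop, length(background), n_samples, byrow = TRUE)
    })
    lat[background, ][drop_mask] <- lat[background, ][drop_mask] * 1e-6
  }

  # streams 3-4: depths and multinomial counts ------------------------------
  depths <- with_seed(derive_seed(design$seed, 3L), {
    vapply(names(design$n_taxa), function(k) {
      mu <- log(design$depth_mean[[k]]) - design$depth_sdlog^2 / 2
      pmax(1, round(stats::rlnorm(n_samples, mu, design$depth_sdlog)))
    }, numeric(n_samples))
  })
  counts <- with_seed(derive_seed(design$seed, 4L), {
    m <- matrix(0, n_total, n_samples)
    for (k in names(design$n_taxa)) {
      rows <- which(alloc$kingdom_of == k)
      for (s in seq_len(n_samples)) {
        p <- lat[rows, s] / sum(lat[rows, s])
        m[rows, s] <- stats::rmultinom(1, depths[s, k], p)
      }
    }
    m
  })
  dimnames(counts) <- list(alloc$ids, sample_meta$sample_id)

  taxon_meta <- tibble(
    zotu_id = alloc$ids, kingdom = alloc$kingdom_of,
    taxonomy = paste0("k__", alloc$kingdom_of, "; g__Genus",
                      stats::ave(seq_len(n_total), alloc$kingdom_of, FUN = seq_along)))

  # ground truth -------------------------------------------------------------
  edges <- hubs <- specialists <- core <- NULL
  if (!is.null(design$blocks)) {
    edges <- purrr::map_dfr(seq_len(nrow(design$blocks)), function(b) {
      spec <- design$blocks[b, ]
      block_truth_edges(spec, alloc$ids[alloc$members[[b]]]) |>
        mutate(block = b,
               treatments = list(spec$treatments[[1]] %||% treatments))
    })
    hub_rows <- which(design$blocks$type %in% c("hub", "guild"))
    hubs <- vapply(hub_rows, function(b) alloc$ids[alloc$members[[b]][1]], character(1))
  }
  if (!is.null(design$cores)) {
    specialists <- tibble(
      zotu_id = vapply(design$cores$hub, function(b) alloc$ids[alloc$members[[b]][1]], character(1)),
      habitat = design$cores$habitat)
    core <- specialists$zotu_id
  }
  truth <- structure(
    list(edges = edges %||% tibble(from = character(), to = character(),
                                   rho_latent = numeric(), sign = integer(),
                                   class = character(), block = integer(),
                                   treatments = list()),
         hubs = hubs %||% character(),
         specialists = specialists %||% tibble(zotu_id = character(), habitat = character()),
         core = core %||% character()),
    class = "ground_truth")

  list(table = count_table(counts, sample_meta, taxon_meta), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted edges (+%d ambient), %d hubs, %d specialists, %d core taxa\n",
              sum(x$edges$class == "planted"), sum(x$edges$class == "ambient"),
              length(x$hubs), nrow(x$specialists), length(x$core)))
  invisible(x)
}

#' Generate a random phylogeny over a set of taxa
#'
#' A rooted bifurcating tree with uniform positive branch lengths, via
#' `ape::rtree`, reproducible from the seed. Supports NTI testing.
#'
#' @param taxa Character vector of taxon ids (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree whose tips are exactly `taxa`.
#' @export
simulate_tree <- function(taxa, seed = 1L) {
  if (length(taxa) < 2) abort("need at least 2 taxa for a tree.")
  with_seed(seed, ape::rtree(length(taxa), tip.label = taxa))
}

#' Score recovered network edges against planted ground truth
#'
#' Compares a built network's edge set with the latent pairs the generator
#' planted for the network's treatment. Pairs labelled `ambient` in the
#' truth (correlations that are geometric by-products of hub construction,
#' sitting in a detection no-man's band) are excluded from both the recall
#' denominator and the false-positive count — a don't-care band.
#'
#' @param net A `cooccurrence_network`.
#' @param truth A `ground_truth`.
#' @param treatment Treatment label the network was built for.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
edge_recovery <- function(net, truth, treatment) {
  stopifnot(inherits(net, "cooccurrence_network"), inherits(truth, "ground_truth"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  active <- purrr::map_lgl(truth$edges$treatments, ~ treatment %in% .x)
  planted <- truth$edges[active & truth$edges$class == "planted", ]
  ambient <- truth$edges[active & truth$edges$class == "ambient", ]
  got <- key(net$edges$from, net$edges$to)
  want <- key(planted$from, planted$to)
  dont_care <- key(ambient$from, ambient$to)
  tp <- sum(got %in% want)
  fp <- sum(!(got %in% want) & !(got %in% dont_care))
  fn <- sum(!(want %in% got))
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Score recovered core taxa against planted ground truth
#'
#' @param core_set Character vector of identified core taxa.
#' @param truth A `ground_truth` with planted cores.
#' @return A one-row tibble: `recovered`, `planted`, `recall`.
#' @export
core_recovery <- function(core_set, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- length(truth$core)
  tibble(recovered = sum(truth$core %in% core_set), planted = n,
         recall = if (n == 0) NA_real_ else sum(truth$core %in% core_set) / n)
}
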