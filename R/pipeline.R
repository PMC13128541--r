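#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline uses. A
#' config round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param counts_file,sample_meta_file,taxon_meta_file Input TSV paths
#'   (see [read_count_table()]); all `NULL` when `scenario` is given.
#' @param tree_file Optional newick tree for the NTI stage; when absent
#'   the stage is skipped with a warning.
#' @param scenario Optional name of a built-in synthetic scenario
#'   (`"recovery"`, `"root_like"`, `"rhizosphere_like"`) used instead of
#'   input files.
#' @param rarefaction_depths Named integer vector of depth per kingdom;
#'   `NULL` disables rarefaction.
#' @param min_rel_abund,rho_threshold,alpha Network construction settings
#'   (see [build_network()]).
#' @param robustness_fractions,robustness_reps Robustness grid (see
#'   [robustness_curve()]).
#' @param closeness_min,degree_min Network-hub thresholds.
#' @param spec_min,occu_min,top_n SPEC-OCCU settings.
#' @param n_random_modularity Null graphs for relative modularity.
#' @param nti_n_null NTI randomisations.
#' @param core_network_treatment Treatment whose network supplies the
#'   keystone set for the core-taxa screen (default `"SD"`).
#' @param seed Global seed; every random stage derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_file = NULL, sample_meta_file = NULL,
                            taxon_meta_file = NULL, tree_file = NULL,
                            scenario = NULL,
                            rarefaction_depths = NULL,
                            min_rel_abund = 1e-4,
                            rho_threshold = 0.8, alpha = 0.05,
                            robustness_fractions = seq(0, 0.8, by = 0.05),
                            robustness_reps = 100,
                            closeness_min = 0.25, degree_min = 40,
                            spec_min = 0.7, occu_min = 0.7, top_n = 500,
                            n_random_modularity = 100,
                            nti_n_null = 999,
                            core_network_treatment = "SD",
                            seed = 1L) {
  if (is.null(scenario) &&
      (is.null(counts_file) || is.null(sample_meta_file) || is.null(taxon_meta_file))) {
    abort("either a scenario or the three input files must be given.")
  }
  if (!is.null(scenario) &&
      !scenario %in% c("recovery", "root_like", "rhizosphere_like")) {
    abort("unknown scenario; use 'recovery', 'root_like' or 'rhizosphere_like'.")
  }
  assert_scalar_number(rho_threshold, "rho_threshold", lower = 0, upper = 1)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  assert_scalar_number(min_rel_abund, "min_rel_abund", lower = 0, upper = 1)
  assert_scalar_number(spec_min, "spec_min", lower = 0, upper = 1)
  assert_scalar_number(occu_min, "occu_min", lower = 0, upper = 1)
  if (any(robustness_fractions < 0 | robustness_fractions >= 1)) {
    abort("robustness fractions must lie in [0, 1).")
  }
  cfg <- list(
    counts_file = counts_file, sample_meta_file = sample_meta_file,
    taxon_meta_file = taxon_meta_file, tree_file = tree_file,
    scenario = scenario,
    rarefaction_depths = rarefaction_depths,
    min_rel_abund = min_rel_abund, rho_threshold = rho_threshold,
    alpha = alpha,
    robustness_fractions = robustness_fractions,
    robustness_reps = robustness_reps,
    closeness_min = closeness_min, degree_min = degree_min,
    spec_min = spec_min, occu_min = occu_min, top_n = top_n,
    n_random_modularity = n_random_modularity,
    nti_n_null = nti_n_null,
    core_network_treatment = core_network_treatment,
    seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$robustness_fractions <- as.numeric(raw$robustness_fractions %||% seq(0, 0.8, 0.05))
  if (!is.null(raw$rarefaction_depths)) {
    raw$rarefaction_depths <- unlist(raw$rarefaction_depths)
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config[!vapply(config, is.null, logical(1))]
  # yaml drops names from atomic vectors; store named vectors as maps
  if (!is.null(out$rarefaction_depths)) {
    out$rarefaction_depths <- as.list(out$rarefaction_depths)
  }
  yaml::write_yaml(out, path)
  invisible(config)
}

load_pipeline_input <- function(config) {
  if (!is.null(config$scenario)) {
    design <- switch(config$scenario,
                     recovery = scenario_recovery(config$seed),
                     root_like = scenario_root_like(config$seed),
                     rhizosphere_like = scenario_rhizosphere_like(config$seed))
    sim <- simulate_community(design)
    list(table = sim$table, truth = sim$truth)
  } else {
    list(table = read_count_table(config$counts_file, config$sample_meta_file,
                                  config$taxon_meta_file),
         truth = NULL)
  }
}

#' Run the full pipeline
#'
#' Orchestrates, per compartment of the input table: per-kingdom
#' rarefaction, per-treatment network construction, topology and
#' stability reports, cohesion, AVD, Zi-Pi roles, SPEC-OCCU (treatments
#' as habitats), shared-taxa Venn, the three-way core screen, the
#' correlation of core abundance with absolute negative cohesion, and —
#' when a tree is supplied — per-sample NTI. All randomness derives from
#' the config seed, so a rerun with the same config and inputs reproduces
#' every output byte for byte. Any stage error aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory: when given, every result table is
#'   written as TSV together with a run manifest (package version, config
#'   hash, design-decision flags).
#' @return A named list of results per compartment (`networks`,
#'   `topology`, `stability`, `roles`, `spec_occu`, `shared`, `core`,
#'   `core_cohesion_cor`, `nti`), plus `table` and (for scenarios)
#'   `truth`, invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  input <- stage("input", load_pipeline_input(config))
  table <- input$table

  table <- stage("rarefaction", {
    if (is.null(config$rarefaction_depths)) table else {
      parts <- lapply(names(config$rarefaction_depths), function(k) {
        taxa <- table$taxon_meta$zotu_id[table$taxon_meta$kingdom == k]
        if (length(taxa) == 0) return(NULL)
        rarefy(subset_count_table(table, taxa = taxa),
               depth = config$rarefaction_depths[[k]],
               seed = derive_seed(config$seed, 10L))
      })
      parts <- parts[!vapply(parts, is.null, logical(1))]
      common <- Reduce(intersect, lapply(parts, function(p) colnames(p$counts)))
      if (length(common) == 0) abort("no sample survived rarefaction in every kingdom.")
      counts <- do.call(rbind, lapply(parts, function(p) p$counts[, common, drop = FALSE]))
      count_table(counts,
                  table$sample_meta[table$sample_meta$sample_id %in% common, ],
                  table$taxon_meta[table$taxon_meta$zotu_id %in% rownames(counts), ])
    }
  })

  compartments <- unique(table$sample_meta$compartment)
  tree_dist <- NULL
  if (!is.null(config$tree_file)) {
    tree_dist <- stage("tree", patristic_distances(ape::read.tree(config$tree_file)))
  }

  results <- lapply(compartments, function(cp) {
    samp_cp <- table$sample_meta$sample_id[table$sample_meta$compartment == cp]
    tab_cp <- subset_count_table(table, samples = samp_cp)
    treatments <- unique(tab_cp$sample_meta$treatment)

    nets <- list(); topo <- list(); stab <- list(); roles <- list()
    for (tr in treatments) {
      ids <- tab_cp$sample_meta$sample_id[tab_cp$sample_meta$treatment == tr]
      tab_tr <- subset_count_table(tab_cp, samples = ids)
      net <- stage(paste0("network[", cp, ",", tr, "]"),
                   suppressMessages(build_network(
                     tab_tr, rho_threshold = config$rho_threshold,
                     alpha = config$alpha,
                     min_rel_abund = config$min_rel_abund,
                     dataset = paste(cp, tr, sep = "_"))))
      nets[[tr]] <- net
      if (nrow(net$edges) > 0) {
        topo[[tr]] <- stage(paste0("topology[", cp, ",", tr, "]"),
                            suppressMessages(network_topology(
                              net, n_random = config$n_random_modularity,
                              seed = derive_seed(config$seed, 20L),
                              closeness_min = config$closeness_min,
                              degree_min = config$degree_min)))
        stab[[tr]] <- stage(paste0("stability[", cp, ",", tr, "]"),
                            suppressMessages(stability_report(
                              net, tab_tr,
                              fractions = config$robustness_fractions,
                              n_rep = config$robustness_reps,
                              seed = derive_seed(config$seed, 30L))))
        roles[[tr]] <- stage(paste0("roles[", cp, ",", tr, "]"),
                             suppressMessages(zi_pi(net, topo[[tr]]$nodes[, c("node", "module")])))
      }
    }

    rel_cp <- relative_abundance(tab_cp)
    habitats <- stats::setNames(tab_cp$sample_meta$treatment,
                                tab_cp$sample_meta$sample_id)
    so <- stage(paste0("spec_occu[", cp, "]"),
                spec_occu(rel_cp, habitats, top_n = config$top_n,
                          spec_min = config$spec_min, occu_min = config$occu_min))
    sh <- stage(paste0("shared[", cp, "]"),
                shared_taxa(tab_cp, min_rel_abund = config$min_rel_abund))

    core_tr <- config$core_network_treatment
    core <- cohesion_cor <- NULL
    if (!is.null(roles[[core_tr]])) {
      # keystones: Zi-Pi module hubs/connectors/network hubs plus the
      # degree-and-closeness network hubs (the operational hub call)
      keys <- union(roles[[core_tr]]$node[roles[[core_tr]]$keystone],
                    topo[[core_tr]]$hubs$node)
      core <- stage(paste0("core_taxa[", cp, "]"),
                    core_taxa(sh, so, keys, table = tab_cp))
      if (length(core$core) > 0) {
        coh <- stab[[core_tr]]$cohesion
        cohesion_cor <- stage(paste0("core_cohesion_cor[", cp, "]"),
                              suppressMessages(abundance_stability_correlation(
                                rel_cp[core$core, , drop = FALSE],
                                stats::setNames(abs(coh$neg_cohesion), coh$sample_id))))
      }
    }

    nti_tbl <- NULL
    if (!is.null(tree_dist)) {
      nti_tbl <- stage(paste0("nti[", cp, "]"),
                       suppressMessages(nti_per_sample(
                         tab_cp, tree_dist, n_null = config$nti_n_null,
                         seed = derive_seed(config$seed, 40L))))
    }
    list(networks = nets, topology = topo, stability = stab, roles = roles,
         spec_occu = so, shared = sh, core = core,
         core_cohesion_cor = cohesion_cor, nti = nti_tbl)
  })
  names(results) <- compartments
  if (is.null(tree_dist)) {
    warn("run_pipeline: no tree supplied; NTI stage skipped.")
  }
  bundle <- c(results, list(table = table, truth = input$truth, config = config))

  if (!is.null(outdir)) {
    write_pipeline_bundle(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

write_pipeline_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- bundle$config
  for (cp in setdiff(names(bundle), c("table", "truth", "config"))) {
    res <- bundle[[cp]]
    pre <- file.path(outdir, cp)
    for (tr in names(res$networks)) {
      net <- res$networks[[tr]]
      write_network(net, paste0(pre, "_", tr, "_edges.tsv"),
                    paste0(pre, "_", tr, "_nodes.tsv"),
                    graphml = paste0(pre, "_", tr, ".graphml"))
      if (!is.null(res$topology[[tr]])) {
        readr::write_tsv(res$topology[[tr]]$summary, paste0(pre, "_", tr, "_topology.tsv"))
        readr::write_tsv(res$topology[[tr]]$nodes, paste0(pre, "_", tr, "_node_topology.tsv"))
        readr::write_tsv(res$stability[[tr]]$summary, paste0(pre, "_", tr, "_stability.tsv"))
        readr::write_tsv(res$stability[[tr]]$robustness, paste0(pre, "_", tr, "_robustness.tsv"))
        readr::write_tsv(res$stability[[tr]]$cohesion, paste0(pre, "_", tr, "_cohesion.tsv"))
        readr::write_tsv(res$roles[[tr]], paste0(pre, "_", tr, "_node_roles.tsv"))
      }
    }
    readr::write_tsv(res$spec_occu, paste0(pre, "_spec_occu.tsv"))
    readr::write_tsv(res$shared$venn, paste0(pre, "_venn.tsv"))
    if (!is.null(res$core)) {
      readr::write_tsv(tibble(zotu_id = res$core$core), paste0(pre, "_core_taxa.tsv"))
      if (!is.null(res$core$abundance)) {
        readr::write_tsv(res$core$abundance, paste0(pre, "_core_abundance.tsv"))
      }
    }
    if (!is.null(res$core_cohesion_cor)) {
      readr::write_tsv(res$core_cohesion_cor, paste0(pre, "_core_cohesion_cor.tsv"))
    }
    if (!is.null(res$nti)) readr::write_tsv(res$nti, paste0(pre, "_nti.tsv"))
  }
  manifest <- c(
    paste0("package_version: ", as.character(utils::packageVersion("rhizonet"))),
    paste0("config_hash: ", rlang::hash(unclass(config))),
    paste0("seed: ", config$seed),
    "flags:",
    "  spearman_p: t-approximation (exact permutation available for small n)",
    "  fdr_scope: per network, over all tested pairs",
    "  connectedness: mean of significant correlations per taxon (sum via flag)",
    "  cohesion_abundance: renormalised over network taxa per sample",
    "  closeness: component-scaled (Wasserman-Faust)",
    "  modularity: Louvain, unweighted, fixed seed",
    "  rm_null: degree-preserving rewiring (Erdos-Renyi fallback for rigid degree sequences)",
    "  isolated_nodes: excluded from network node counts",
    "  rarefaction: without replacement; shallow samples dropped",
    "  zi_pi_precedence: network hub > module hub > connector",
    "  occupancy_presence: count > 0, no minimum-count threshold",
    "  spec_occu_screen: top-n by mean relative abundance per habitat",
    "  nti: unweighted MNTD, taxa-label shuffling null")
  writeLines(manifest, file.path(outdir, "run_manifest.yml"))
  invisible(bundle)
}
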