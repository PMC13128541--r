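small_design <- function(seed = 1, blocks = NULL, cores = NULL, ...) {
  # planted taxa carry a generous share so they stay above the occupancy
  # screen at these modest depths
  synthetic_design(
    n_taxa = c(prokaryote = 60, fungus = 20, protist = 10),
    depth_mean = c(prokaryote = 20000, fungus = 6000, protist = 4000),
    planted_rel = 0.005,
    blocks = blocks, cores = cores, seed = seed, ...)
}

test_that("designs are validated", {
  expect_error(synthetic_design(n_replicates = 2), "n_replicates")
  expect_error(synthetic_design(depth_mean = -5), "positive")
  expect_error(block_spec(5, rho = 1.3), "-1, 1")
  expect_error(block_spec(5, sign = -1L), "pairwise")
  expect_error(block_spec(3, sign = -1L, type = "pair"), "size 2")
  expect_error(block_spec(18, type = "hub"), "divisible by 4")
  expect_error(small_design(blocks = block_spec(5, treatments = "XX")),
               "not in design")
  # blocks that exceed a kingdom's capacity are rejected up front
  expect_error(small_design(blocks = block_spec(70, rho = 0.9, type = "block")),
               "too few taxa")
  # cores must point at hub- or guild-type blocks
  expect_error(small_design(blocks = block_spec(5), cores = core_spec(1)),
               "hub|guild")
})

test_that("simulation is reproducible and respects the drawn depths", {
  d <- small_design(seed = 42, blocks = block_spec(5, rho = 0.95))
  sim1 <- simulate_community(d)
  sim2 <- simulate_community(d)
  expect_identical(sim1$table$counts, sim2$table$counts)
  expect_identical(sim1$truth$edges, sim2$truth$edges)

  # per-kingdom column sums are exactly the drawn library depths
  tab <- sim1$table
  for (k in unique(tab$taxon_meta$kingdom)) {
    rows <- tab$taxon_meta$zotu_id[tab$taxon_meta$kingdom == k]
    sums <- colSums(tab$counts[rows, , drop = FALSE])
    expect_true(all(sums == round(sums)))
    expect_true(all(sums > 0))
  }
  # study layout: treatments x stages x replicates samples
  expect_equal(ncol(tab$counts), 3 * 3 * 5)
  expect_equal(sort(unique(tab$sample_meta$treatment)), c("CK", "MD", "SD"))
})

test_that("planted ground truth is internally consistent", {
  d <- scenario_recovery(seed = 3)
  sim <- simulate_community(d)
  truth <- sim$truth
  # cores are hubs and specialists by construction
  expect_true(all(truth$core %in% truth$hubs))
  expect_true(all(truth$core %in% truth$specialists$zotu_id))
  # planted edges reference real taxa, no self loops, sign matches rho
  expect_true(all(c(truth$edges$from, truth$edges$to) %in%
                    rownames(sim$table$counts)))
  expect_false(any(truth$edges$from == truth$edges$to))
  expect_equal(truth$edges$sign, ifelse(truth$edges$rho_latent > 0, 1L, -1L))
  # scoring classes split at the detection window
  expect_true(all(abs(truth$edges$rho_latent[truth$edges$class == "planted"]) >= 0.9))
  expect_true(all(abs(truth$edges$rho_latent[truth$edges$class == "ambient"]) < 0.9))
})

test_that("block correlation matrices are positive semi-definite or rejected", {
  for (type in c("block", "hub", "chain", "guild")) {
    size <- if (type %in% c("hub", "guild")) 16L else 5L
    spec <- block_spec(size, rho = 0.95, type = type)
    n_mem <- size + as.integer(type %in% c("hub", "guild"))
    sig <- rhizonet:::block_sigma(spec[1, ], n_mem, type)
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(unname(diag(sig)), rep(1, n_mem))
  }
})

test_that("enrichment fold raises the core's relative abundance in its habitat", {
  # monotonicity averaged over seeds: larger fold => larger SD-mean share
  mean_share <- function(fold) {
    mean(vapply(1:12, function(s) {
      d <- small_design(seed = s,
                        blocks = block_spec(16, rho = 0.95, type = "hub"),
                        cores = core_spec(1, fold = fold, habitat = "SD"))
      sim <- simulate_community(d)
      core <- sim$truth$core
      sm <- sim$table$sample_meta
      sd_cols <- sm$sample_id[sm$treatment == "SD"]
      rel <- suppressMessages(relative_abundance(sim$table))
      mean(rel[core, sd_cols])
    }, numeric(1)))
  }
  shares <- c(mean_share(2), mean_share(8), mean_share(25))
  expect_true(all(diff(shares) > 0))
})

test_that("random trees cover the taxa and reproduce from the seed", {
  taxa <- paste0("t", 1:7)
  tr <- simulate_tree(taxa, seed = 5)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, taxa)
  expect_equal(tr$Nnode, 6L) # rooted bifurcating: n - 1 internal nodes
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(taxa, seed = 5)))
  expect_error(simulate_tree("one"), "at least 2")

  # two taxa: a single cherry whose patristic distance is the branch sum
  ch <- simulate_tree(c("a", "b"), seed = 1)
  expect_equal(unname(patristic_distances(ch)["a", "b"]),
               sum(ch$edge.length))
})

test_that("a planted block is recovered as positive edges at default thresholds", {
  recalls <- vapply(11:13, function(s) {
    d <- small_design(seed = s, blocks = block_spec(5, rho = 0.95))
    sim <- simulate_community(d)
    sm <- sim$table$sample_meta
    tab <- subset_count_table(sim$table,
                              samples = sm$sample_id[sm$treatment == "CK"])
    net <- suppressMessages(build_network(tab))
    rec <- edge_recovery(net, sim$truth, "CK")
    key <- paste(net$edges$from, net$edges$to)
    truth_key <- paste(sim$truth$edges$from, sim$truth$edges$to)
    expect_true(all(net$edges$sign[key %in% truth_key] == "positive"))
    rec$recall
  }, numeric(1))
  expect_gte(mean(recalls), 0.9) # nearly all within-block pairs recovered
})
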