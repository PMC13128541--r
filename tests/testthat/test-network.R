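test_that("Spearman matrix matches hand-computed rank correlations", {
  # identical rank order over 10 samples -> rho 1; reversed -> -1
  x <- matrix(c(1:10, (1:10)^2, 10:1), nrow = 3, byrow = TRUE)
  sp <- spearman_matrix(x)
  expect_equal(sp$rho[1, 2], 1)
  expect_equal(sp$rho[1, 3], -1)

  # (1,2,3,4,5) vs (2,1,4,3,5): sum d^2 = 4, rho = 1 - 6*4/(5*24) = 0.8
  y <- rbind(1:5, c(2, 1, 4, 3, 5), c(5, 1, 2, 4, 3), c(1, 1, 1, 1, 1))
  sp2 <- spearman_matrix(y)
  expect_equal(sp2$rho[1, 2], 0.8)
  # constant taxon: rho undefined for its pairs
  expect_true(all(is.na(sp2$rho[4, ])))
  expect_true(all(is.na(sp2$p[4, ])))
  expect_error(spearman_matrix(y[, 1:3]), "at least 4")
})

test_that("exact permutation p-values agree with the t-approximation in rank", {
  set.seed(1)
  x <- matrix(rnorm(5 * 7), nrow = 5)
  ex <- spearman_matrix(x, exact = TRUE)
  ap <- spearman_matrix(x, exact = FALSE)
  expect_identical(ex$rho, ap$rho)
  # exact p of a perfectly concordant pair equals 2/n! (both extremes)
  z <- rbind(1:7, (1:7)^3, rnorm(7))
  exz <- spearman_matrix(z, exact = TRUE)
  expect_equal(exz$p[1, 2], 2 / factorial(7))
  expect_error(spearman_matrix(matrix(rnorm(33), 3), exact = TRUE), "n <= 10")
})

test_that("BH adjustment matches hand computation", {
  # (0.01, 0.02, 0.03): min over tail of p*m/rank
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.1, 1.4)), "0, 1")
  # oracle: direct step-up on random vectors
  set.seed(2)
  for (i in 1:5) {
    p <- runif(20)
    o <- order(p)
    manual <- numeric(20)
    manual[o] <- rev(cummin(rev(p[o] * 20 / seq_len(20))))
    expect_equal(fdr_adjust(p), pmin(manual, 1))
  }
})

test_that("build_network matches a brute-force Spearman+BH oracle edge-for-edge", {
  d <- synthetic_design(n_taxa = c(prokaryote = 18),
                        depth_mean = c(prokaryote = 20000), planted_rel = 0.01,
                        blocks = dplyr::bind_rows(
                          block_spec(4, rho = 0.95),
                          block_spec(2, rho = 0.95, sign = -1L, type = "pair")),
                        seed = 5)
  sim <- simulate_community(d)
  sm <- sim$table$sample_meta
  tab <- subset_count_table(sim$table,
                            samples = sm$sample_id[sm$treatment == "MD"])
  net <- suppressMessages(build_network(tab, perm_refine = FALSE))

  # oracle: per-pair cor() on ranks, t-test p, manual BH, same screens
  # (relative abundances keep the full-table denominators)
  rel_full <- relative_abundance(tab)
  keep1 <- rowMeans(rel_full) > 1e-4
  occ <- rowMeans(tab$counts > 0)
  rel <- rel_full[keep1 & occ >= 0.9, , drop = FALSE]
  ids <- rownames(rel)
  n <- ncol(rel)
  pairs <- t(utils::combn(length(ids), 2))
  rho <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- rank(rel[pairs[k, 1], ]); b <- rank(rel[pairs[k, 2], ])
    rho[k] <- suppressWarnings(cor(a, b))
    tt <- rho[k] * sqrt((n - 2) / (1 - rho[k]^2))
    p[k] <- 2 * pt(-abs(tt), n - 2)
  }
  ok <- is.finite(rho)
  padj <- rep(NA_real_, length(p))
  o <- order(p[ok]); m <- sum(ok)
  adj <- numeric(m); adj[o] <- rev(cummin(rev(p[ok][o] * m / seq_len(m))))
  padj[ok] <- pmin(adj, 1)
  keep <- ok & abs(rho) > 0.8 & padj < 0.05
  oracle_edges <- sort(paste(pmin(ids[pairs[keep, 1]], ids[pairs[keep, 2]]),
                             pmax(ids[pairs[keep, 1]], ids[pairs[keep, 2]])))
  got <- sort(paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to)))
  expect_identical(got, oracle_edges)
  expect_gt(length(got), 0)

  # the permutation refinement can only remove edges, never add them
  net_ref <- suppressMessages(build_network(tab))
  expect_true(all(paste(net_ref$edges$from, net_ref$edges$to) %in%
                    paste(net$edges$from, net$edges$to)))
})

test_that("network construction invariants hold", {
  d <- synthetic_design(n_taxa = c(prokaryote = 40),
                        depth_mean = c(prokaryote = 20000), planted_rel = 0.01,
                        blocks = block_spec(5, rho = 0.95), seed = 9)
  sim <- simulate_community(d)
  sm <- sim$table$sample_meta
  ids <- sm$sample_id[sm$treatment == "CK"]
  tab <- subset_count_table(sim$table, samples = ids)
  net <- suppressMessages(build_network(tab))

  # permuting sample order leaves the network unchanged
  tab_perm <- subset_count_table(sim$table, samples = rev(ids))
  net_perm <- suppressMessages(build_network(tab_perm))
  expect_equal(net$edges, net_perm$edges)

  # raising the threshold never adds edges; an impossible threshold
  # empties the network
  net_hi <- suppressMessages(build_network(tab, rho_threshold = 0.9))
  expect_true(all(paste(net_hi$edges$from, net_hi$edges$to) %in%
                    paste(net$edges$from, net$edges$to)))
  net_none <- suppressMessages(build_network(tab, rho_threshold = 1.01))
  expect_equal(nrow(net_none$edges), 0L)
  expect_equal(nrow(net_none$nodes), 0L)

  # every edge satisfies the construction rule; signs follow rho
  expect_true(all(abs(net$edges$rho) > 0.8))
  expect_true(all(net$edges$p_fdr < 0.05))
  expect_identical(net$edges$sign, ifelse(net$edges$rho > 0, "positive", "negative"))
  expect_error(suppressMessages(build_network(
    subset_count_table(tab, samples = colnames(tab$counts)[1:3]))),
    "at least 4 samples")
})

test_that("kingdom and sign summaries are conserving", {
  g <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  net <- net_from_graph(g, rho = c(0.9, -0.85, 0.95))
  net$nodes$kingdom <- c("prokaryote", "prokaryote", "fungus", "protist")

  ks <- edge_kingdom_summary(net)
  expect_equal(sum(ks$edges$n), nrow(net$edges))
  expect_equal(ks$edges$n[ks$edges$type == "intra"], 1) # a-b intra prokaryote
  expect_setequal(ks$nodes$n, c(2, 1, 1))

  ss <- edge_sign_summary(net)
  expect_equal(ss$n_positive + ss$n_negative, nrow(net$edges))
  expect_equal(ss$n_negative, 1L)

  empty <- net_from_graph(igraph::make_empty_graph(0, directed = FALSE))
  es <- edge_sign_summary(empty)
  expect_equal(c(es$n_positive, es$n_negative), c(0L, 0L))

  net$nodes$kingdom[2] <- NA
  expect_error(edge_kingdom_summary(net), "kingdom")
})

test_that("networks round-trip through edge-list TSVs and GraphML", {
  g <- graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
  net <- net_from_graph(g, rho = c(0.9, -0.9))
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "edges.tsv"); nf <- file.path(dir, "nodes.tsv")
  gf <- file.path(dir, "net.graphml")
  write_network(net, ef, nf, graphml = gf)
  back <- read_network(ef, nf)
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  g2 <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(igraph::vertex_attr(g2, "kingdom"), "prokaryote")
})
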