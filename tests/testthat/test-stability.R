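test_that("natural connectivity matches hand eigendecompositions", {
  # edgeless graph: all eigenvalues 0 -> ln(1) = 0
  expect_equal(natural_connectivity(matrix(0, 4, 4)), 0, tolerance = 1e-12)

  # single edge, N = 2: eigenvalues {1, -1} -> ln(cosh 1)
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(natural_connectivity(a2), log(cosh(1)), tolerance = 1e-12)
  expect_equal(natural_connectivity(a2), 0.433781, tolerance = 1e-6)

  # triangle K3: eigenvalues {2, -1, -1}
  a3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(a3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(a3), 0.996311, tolerance = 1e-6)

  # closed form for complete graphs
  for (n in 2:8) {
    expect_equal(natural_connectivity(complete_graph(n)),
                 log((exp(n - 1) + (n - 1) * exp(-1)) / n), tolerance = 1e-9)
  }
})

test_that("adding an edge never decreases natural connectivity", {
  # exhaustive over all graphs on 4 nodes (64 edge subsets)
  pairs <- t(utils::combn(4, 2))
  for (mask in 0:(2^6 - 1)) {
    adj <- matrix(0, 4, 4)
    on <- which(bitwAnd(mask, 2^(0:5)) > 0)
    for (k in on) { adj[pairs[k, 1], pairs[k, 2]] <- adj[pairs[k, 2], pairs[k, 1]] <- 1 }
    base <- natural_connectivity(adj)
    for (k in setdiff(1:6, on)) {
      adj2 <- adj
      adj2[pairs[k, 1], pairs[k, 2]] <- adj2[pairs[k, 2], pairs[k, 1]] <- 1
      expect_gte(natural_connectivity(adj2), base - 1e-12)
    }
  }
})

test_that("robustness curves start exactly at the intact network", {
  k10 <- complete_graph(10)
  rc <- robustness_curve(k10, fractions = c(0, 0.1, 0.5), n_rep = 20, seed = 3)
  expect_equal(rc$mean_nc[1], natural_connectivity(k10), tolerance = 1e-12)
  expect_equal(rc$sd_nc[1], 0)
  expect_equal(rc$mean_avg_degree[1], 9)

  # K10 minus any one node is K9: all draws identical, sd 0
  row01 <- rc[rc$fraction == 0.1, ]
  expect_equal(row01$mean_nc, natural_connectivity(complete_graph(9)),
               tolerance = 1e-12)
  expect_equal(row01$sd_nc, 0)

  # mean average degree non-increasing in the removal fraction for K_n
  rc2 <- robustness_curve(k10, fractions = seq(0, 0.8, 0.2), n_rep = 10, seed = 1)
  expect_true(all(diff(rc2$mean_avg_degree) <= 1e-12))

  expect_error(robustness_curve(k10, fractions = c(0, 1)), "\\[0, 1\\)")
  # reproducible from seed
  expect_identical(robustness_curve(k10, n_rep = 5, seed = 8),
                   robustness_curve(k10, n_rep = 5, seed = 8))
})

test_that("connectedness averages signed correlations per taxon", {
  g <- graph_from_pairs(rbind(c("a", "b"), c("a", "c"), c("a", "d")))
  net <- net_from_graph(g, rho = c(0.9, 0.85, -0.82))
  net$nodes <- dplyr::bind_rows(net$nodes,
                                tibble::tibble(node = "e", kingdom = "prokaryote"))
  conn <- connectedness(net)
  expect_equal(conn$pos_connectedness[conn$node == "a"], 0.875)
  expect_equal(conn$neg_connectedness[conn$node == "a"], -0.82)
  expect_equal(conn$neg_connectedness[conn$node == "d"], -0.82)
  expect_equal(conn$pos_connectedness[conn$node == "d"], 0)
  # isolated taxon: (0, 0)
  expect_equal(unlist(conn[conn$node == "e", c("pos_connectedness", "neg_connectedness")]),
               c(pos_connectedness = 0, neg_connectedness = 0))
  # sum flag switches the aggregation
  conn_sum <- connectedness(net, method = "sum")
  expect_equal(conn_sum$pos_connectedness[conn_sum$node == "a"], 1.75)
})

test_that("cohesion is the abundance-weighted sum of connectedness", {
  conn <- tibble::tibble(node = c("a", "b"),
                         pos_connectedness = c(0.8, 0.8),
                         neg_connectedness = c(-0.4, -0.2))
  abund <- matrix(c(0.5, 0.5, 0.25, 0.75), nrow = 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  coh <- cohesion(abund, conn)
  expect_equal(coh$pos_cohesion[1], 0.8, tolerance = 1e-12)
  expect_equal(coh$neg_cohesion[2], -0.25, tolerance = 1e-12) # 0.25*(-0.4)+0.75*(-0.2)
  expect_equal(coh$total_cohesion, coh$pos_cohesion + abs(coh$neg_cohesion),
               tolerance = 1e-12)
  expect_equal(coh$neg_pos_ratio[2], 0.25 / 0.8, tolerance = 1e-12)

  # all-zero connectedness: total cohesion 0
  conn0 <- dplyr::mutate(conn, pos_connectedness = 0, neg_connectedness = 0)
  expect_equal(cohesion(abund, conn0)$total_cohesion, c(0, 0))

  # zero abundance on the network taxa: flagged, zeros, ratio NA
  abund0 <- abund; abund0[, 2] <- 0
  expect_message(c0 <- cohesion(abund0, conn), "zero abundance")
  expect_equal(c0$pos_cohesion[2], 0)
  expect_true(is.na(c0$neg_pos_ratio[2]))

  # community-wide weighting: halving the network taxa's community share
  # halves cohesion, while the renormalised variant is unaffected
  expect_equal(cohesion(abund / 2, conn)$pos_cohesion, coh$pos_cohesion / 2,
               tolerance = 1e-12)
  expect_equal(cohesion(abund / 2, conn, renormalise = TRUE)$pos_cohesion,
               coh$pos_cohesion)

  # cohesion is linear in the renormalised weights
  conn_b <- tibble::tibble(node = c("a", "b"),
                           pos_connectedness = c(1, 0), neg_connectedness = 0)
  w1 <- matrix(c(0.2, 0.8), 2, dimnames = list(c("a", "b"), "s"))
  w2 <- matrix(c(0.4, 0.6), 2, dimnames = list(c("a", "b"), "s"))
  expect_equal(cohesion(w2, conn_b)$pos_cohesion,
               2 * cohesion(w1, conn_b)$pos_cohesion)
})

test_that("AVD matches closed-form replicate cases", {
  # identical replicates: sd = 0 everywhere -> AVD exactly 0
  same <- matrix(5, 3, 4, dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  expect_equal(avd(same), 0)

  # one zOTU, two distinct replicates: |x - mean| = d/2, sd = d/sqrt(2)
  two <- matrix(c(0.2, 0.6), 1, dimnames = list("t1", c("s1", "s2")))
  expect_equal(avd(two), 1 / sqrt(2), tolerance = 1e-12)

  # scale invariance per zOTU
  set.seed(4)
  x <- matrix(runif(20), 4, 5, dimnames = list(paste0("t", 1:4), paste0("s", 1:5)))
  y <- x; y[2, ] <- y[2, ] * 37
  expect_equal(avd(x), avd(y), tolerance = 1e-12)

  expect_error(avd(x[, 1, drop = FALSE]), "at least 2")
  expect_error(avd(x, samples = c("s1", "zz")), "unknown")
})

test_that("vulnerability reproduces hand-computed efficiencies", {
  # P3: E = 5/6; centre removal -> 0 (V = 1); leaf removal -> 1 (V = -0.2)
  p3 <- graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
  v <- vulnerability(p3)
  expect_equal(v$efficiency, 5 / 6, tolerance = 1e-12)
  expect_equal(v$vulnerability, 1, tolerance = 1e-12)
  expect_equal(v$nodes$vulnerability[v$nodes$node == "b"], 1, tolerance = 1e-12)
  expect_equal(v$nodes$vulnerability[v$nodes$node == "a"], -0.2, tolerance = 1e-12)

  # K4: removing any node leaves K3 with E = 1 -> V = 0
  v4 <- vulnerability(complete_graph(4))
  expect_equal(v4$vulnerability, 0, tolerance = 1e-12)
  expect_true(all(v4$nodes$vulnerability <= 1))

  expect_error(vulnerability(graph_from_pairs(rbind(c("a", "b")))), "3 nodes")
  expect_error(vulnerability(igraph::make_empty_graph(4, directed = FALSE)),
               "edgeless")
})

test_that("denser planted structure raises cohesion and natural connectivity", {
  # natural connectivity is intensive: disjoint copies of the same clique
  # leave it unchanged, so association density is graded through block
  # size (and block count for the cohesion side)
  level_stats <- function(level, s) {
    size <- c(4L, 6L, 8L)[level]
    blocks <- dplyr::bind_rows(lapply(seq_len(level),
                                      function(i) block_spec(size, rho = 0.95)))
    d <- synthetic_design(n_taxa = c(prokaryote = 80),
                          depth_mean = c(prokaryote = 20000),
                          planted_rel = 0.005, blocks = blocks, seed = s)
    sim <- simulate_community(d)
    sm <- sim$table$sample_meta
    tab <- subset_count_table(sim$table, samples = sm$sample_id[sm$treatment == "CK"])
    net <- suppressMessages(build_network(tab))
    if (nrow(net$edges) == 0) return(c(nc = 0, coh = 0))
    coh <- cohesion(relative_abundance(tab), connectedness(net))
    c(nc = natural_connectivity(net), coh = mean(coh$total_cohesion))
  }
  seeds <- 1:12
  res <- lapply(1:3, function(nb)
    rowMeans(vapply(seeds, function(s) level_stats(nb, s), numeric(2))))
  ncs <- vapply(res, `[[`, numeric(1), "nc")
  cohs <- vapply(res, `[[`, numeric(1), "coh")
  expect_true(all(diff(ncs) > 0))
  expect_true(all(diff(cohs) > 0))
})
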