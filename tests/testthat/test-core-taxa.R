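test_that("Zi-Pi matches the worked module example", {
  # M1 = {a,b,c} triangle, M2 = {d,e} edge, plus bridge a-d
  g <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                              c("d", "e"), c("a", "d")))
  mods <- tibble::tibble(node = c("a", "b", "c", "d", "e"),
                         module = c(1L, 1L, 1L, 2L, 2L))
  roles <- zi_pi(g, mods)
  a <- roles[roles$node == "a", ]
  expect_equal(a$pi, 1 - ((2 / 3)^2 + (1 / 3)^2), tolerance = 1e-12) # 4/9
  expect_equal(a$zi, 0) # within-module degrees in M1 all equal
  # all links inside own module -> Pi = 0
  expect_equal(roles$pi[roles$node == "b"], 0)
})

test_that("Pi of an evenly split node and degree-0 handling", {
  # hub with one link into each of 4 modules -> Pi = 0.75
  g <- graph_from_pairs(cbind("h", c("a", "b", "c", "d")))
  g <- igraph::add_vertices(g, 1, name = "iso")
  mods <- tibble::tibble(node = c("h", "a", "b", "c", "d", "iso"),
                         module = c(1L, 1L, 2L, 3L, 4L, 2L))
  expect_message(roles <- zi_pi(g, mods), "degree 0")
  expect_equal(roles$pi[roles$node == "h"], 1 - 4 * (1 / 4)^2, tolerance = 1e-12)
  expect_equal(roles$pi[roles$node == "iso"], 0)
})

test_that("Zi-Pi matches direct enumeration on random partitioned graphs", {
  for (s in 1:6) {
    g <- withr::with_seed(s, igraph::sample_gnp(12, 0.35))
    igraph::V(g)$name <- paste0("n", 1:12)
    mod <- withr::with_seed(s + 100, sample(1:3, 12, replace = TRUE))
    mods <- tibble::tibble(node = paste0("n", 1:12), module = mod)
    roles <- suppressMessages(zi_pi(g, mods))

    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    for (i in 1:12) {
      k_by_mod <- vapply(sort(unique(mod)), function(m) sum(adj[i, mod == m]),
                         numeric(1))
      k_tot <- sum(k_by_mod)
      pi_exp <- if (k_tot == 0) 0 else 1 - sum((k_by_mod / k_tot)^2)
      own <- which(mod == mod[i])
      k_own <- vapply(own, function(j) sum(adj[j, mod == mod[i]]), numeric(1))
      zi_exp <- if (length(own) < 2 || sd(k_own) == 0) 0 else
        (sum(adj[i, mod == mod[i]]) - mean(k_own)) / sd(k_own)
      expect_equal(roles$pi[i], pi_exp, tolerance = 1e-12)
      expect_equal(roles$zi[i], zi_exp, tolerance = 1e-12)
    }
    # role partition is exhaustive and exclusive
    expect_true(all(roles$role %in% c("peripheral", "connector",
                                      "module hub", "network hub")))
    expect_equal(nrow(roles), 12L)
  }
})

test_that("role thresholds follow the printed inequalities with precedence", {
  fake_roles <- function(zi, pi) {
    # classify through the same rule the package applies
    dplyr::case_when(
      zi >= 2.5 & pi >= 0.62 ~ "network hub",
      zi > 2.5 & pi <= 0.62 ~ "module hub",
      zi <= 2.5 & pi > 0.62 ~ "connector",
      .default = "peripheral")
  }
  expect_equal(fake_roles(2.6, 0.5), "module hub")
  expect_equal(fake_roles(2.0, 0.7), "connector")
  expect_equal(fake_roles(2.6, 0.7), "network hub")
  expect_equal(fake_roles(2.5, 0.62), "network hub") # overlap resolved first
  expect_equal(fake_roles(2.5, 0.5), "peripheral")   # Zi > 2.5 is strict
})

test_that("specificity and occupancy follow their ratio definitions", {
  abund <- matrix(c(0.02, 0.01, 0.01, # present everywhere, spec (.5,.25,.25)
                    0.05, 0, 0,       # exclusive to habitat A
                    0, 0, 0),         # absent everywhere
                  nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("t", 1:3), NULL))
  abund <- abund[, c(1, 1, 2, 2, 3, 3)]
  colnames(abund) <- paste0("s", 1:6)
  habitats <- setNames(rep(c("A", "B", "C"), each = 2), colnames(abund))
  so <- spec_occu(abund, habitats, top_n = 500)
  t1 <- so[so$zotu_id == "t1", ]
  expect_equal(t1$specificity[t1$habitat == "A"], 0.5)
  expect_equal(t1$specificity[t1$habitat == "B"], 0.25)
  t2 <- so[so$zotu_id == "t2", ]
  expect_equal(t2$specificity[t2$habitat == "A"], 1)
  expect_equal(sum(t2$specificity), 1, tolerance = 1e-9)
  # specificity rows sum to 1 for every detected zOTU
  sums <- tapply(so$specificity, so$zotu_id, sum)
  expect_equal(as.numeric(sums[c("t1", "t2")]), c(1, 1), tolerance = 1e-9)
  expect_equal(as.numeric(sums["t3"]), 0)

  # occupancy: present in 4 of 5 samples of a habitat -> 0.8
  ab3 <- matrix(c(1, 1, 1, 1, 0, 2, 2, 2, 2, 2), 1,
                dimnames = list("x", paste0("s", 1:10)))
  hab3 <- setNames(rep(c("A", "B"), each = 5), colnames(ab3))
  so3 <- spec_occu(rbind(ab3, filler = 1), hab3)
  expect_equal(so3$occupancy[so3$zotu_id == "x" & so3$habitat == "A"], 0.8)

  expect_error(spec_occu(abund, habitats[1:4]), "unlabelled")
  expect_error(spec_occu(abund, setNames(rep("A", 6), colnames(abund))),
               "2 habitats")
})

test_that("specialist flags apply strict thresholds and the top-n screen", {
  # boundary: specificity exactly 0.7 is NOT a specialist
  abund <- matrix(c(0.7, 0.3, 0.8, 0.2, 0.9, 0.1), nrow = 3, byrow = TRUE,
                  dimnames = list(c("bnd", "ok", "okk"), NULL))
  abund <- abund[, c(1, 1, 1, 2, 2, 2)]
  colnames(abund) <- paste0("s", 1:6)
  hab <- setNames(rep(c("A", "B"), each = 3), colnames(abund))
  so <- spec_occu(abund, hab)
  expect_false(so$specialist[so$zotu_id == "bnd" & so$habitat == "A"]) # 0.7 exactly
  expect_true(so$specialist[so$zotu_id == "ok" & so$habitat == "A"])   # 0.8 > 0.7
  # the top-n screen gates specialists
  so_top1 <- spec_occu(abund, hab, top_n = 1)
  expect_false(any(so_top1$specialist[so_top1$abundance_rank > 1]))
})

test_that("shared taxa and Venn regions partition the union", {
  counts <- matrix(c(50, 50, 50, 50, 50, 50, # everywhere
                     60, 60, 60, 60, 0, 0,   # CK & MD only
                     0, 0, 0, 0, 70, 70),    # SD only
                   nrow = 3, byrow = TRUE)
  tab <- toy_table(toy_counts(counts, samples = paste0("s", 1:6)),
                   treatments = rep(c("CK", "MD", "SD"), each = 2))
  sh <- shared_taxa(tab, min_rel_abund = 0)
  expect_identical(sh$shared, "zOTU_1")
  expect_equal(sum(sh$venn$n), 3) # regions partition the union of detected
  expect_false("zOTU_2" %in% sh$shared) # absent in SD -> not shared

  # identical tables across treatments: everything detected is shared
  same <- toy_table(toy_counts(matrix(30, 4, 6), samples = paste0("s", 1:6)),
                    treatments = rep(c("CK", "MD", "SD"), each = 2))
  sh2 <- shared_taxa(same, min_rel_abund = 0)
  expect_setequal(sh2$shared, paste0("zOTU_", 1:4))
})

test_that("core screen intersects the three sets", {
  expect_warning(ct <- core_taxa(c("a", "b"), c("c"), c("d")), "empty")
  expect_equal(length(ct$core), 0L)

  ct2 <- core_taxa(c("a", "b", "c"), c("b", "c"), c("c", "z"))
  expect_identical(ct2$core, "c")
  expect_true(all(ct2$core %in% ct2$keystones)) # subset property
  td <- tidy(ct2)
  expect_true(td$core[td$zotu_id == "c"])
  expect_equal(sum(td$core), 1L)
})

test_that("abundance-stability correlations reproduce closed forms", {
  stab <- setNames(c(1, 3, 2, 4), paste0("s", 1:4))
  abund <- rbind(lin = 2 * stab + 1, neg = -stab,
                 hand = c(1, 2, 3, 4), flat = rep(1, 4))
  colnames(abund) <- names(stab)
  expect_message(res <- abundance_stability_correlation(abund, stab),
                 "zero variance")
  expect_equal(res$r[res$zotu_id == "lin"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$zotu_id == "neg"], -1, tolerance = 1e-12)
  # x = (1,2,3,4) vs y = (1,3,2,4): r = 0.8 by hand covariance
  expect_equal(res$r[res$zotu_id == "hand"], 0.8, tolerance = 1e-12)
  expect_true(is.na(res$r[res$zotu_id == "flat"]))
  expect_error(abundance_stability_correlation(abund[, 1:3], stab[1:3]),
               "at least 4")
})
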