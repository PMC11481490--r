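test_that("simulation is reproducible under a fixed seed", {
  s1 <- simulate_gene_trees(30, t_internal = 0.7, seed = 12)
  s2 <- simulate_gene_trees(30, t_internal = 0.7, seed = 12)
  expect_identical(vapply(s1$trees, write_newick, ""),
                   vapply(s2$trees, write_newick, ""))
  expect_identical(s1$truth, s2$truth)

  g1 <- simulate_site_patterns(500, gamma = 0.1, seed = 3)
  g2 <- simulate_site_patterns(500, gamma = 0.1, seed = 3)
  expect_identical(g1$seqs, g2$seqs)
})

test_that("simulated trees are valid ultrametric phylo objects", {
  for (sim in list(simulate_gene_trees(40, seed = 2),
                   simulate_gene_trees(30, n_taxa = c(3, 2, 2),
                                       t_split = 2, seed = 2))) {
    for (tr in sim$trees) {
      expect_identical(sort(tr$tip.label), sort(unique(tr$tip.label)))
      expect_true(all(tr$edge.length >= 0))
      s <- write_newick(tr)
      expect_identical(topology_id(parse_newick(s)), topology_id(tr))
      depth <- ape::node.depth.edgelength(tr)
      tips <- depth[seq_len(ape::Ntip(tr))]
      expect_lt(max(tips) - min(tips), 1e-9)
      sup <- node_supports(tr)
      expect_true(all(is.na(sup) | (sup >= 0 & sup <= 100)))
    }
  }
})

test_that("backbone class frequencies follow the MSC closed form", {
  # deep internal branch: essentially no discordance
  deep <- simulate_gene_trees(1000, t_internal = 10, seed = 14,
                              support_model = NULL)
  expect_gte(mean(deep$truth$class_true == "TREE1"), 0.99)

  # star tree: the three classes are exchangeable
  star <- simulate_gene_trees(9000, t_internal = 0, seed = 15,
                              support_model = NULL)
  tab <- table(star$truth$class_true)
  se <- sqrt(9000 * (1 / 3) * (2 / 3))
  for (cl in c("TREE1", "TREE2", "TREE3"))
    expect_lt(abs(tab[[cl]] - 3000), 3 * se)

  # intermediate branch: P(TREE1) = 1 - (2/3) exp(-t)
  for (t in c(0.25, 2)) {
    sim <- simulate_gene_trees(6000, t_internal = t, seed = 16,
                               support_model = NULL)
    p1 <- 1 - (2 / 3) * exp(-t)
    se1 <- sqrt(6000 * p1 * (1 - p1))
    expect_lt(abs(sum(sim$truth$class_true == "TREE1") - 6000 * p1), 3 * se1)
  }
})

test_that("the general engine agrees with the closed form too", {
  # gamma > 0 with an L1 donor routes around the vectorized fast path
  sim <- simulate_gene_trees(4000, t_internal = 1, gamma = 1e-9,
                             donor = "L1", recipient = "L2", seed = 18,
                             support_model = NULL)
  p1 <- 1 - (2 / 3) * exp(-1)
  se <- sqrt(4000 * p1 * (1 - p1))
  expect_lt(abs(sum(sim$truth$class_true == "TREE1") - 4000 * p1), 3.5 * se)
})

test_that("the introgression pulse biases the donor-recipient pairing", {
  sim <- simulate_gene_trees(4000, t_internal = 0.5, gamma = 0.3,
                             donor = "L3", recipient = "L2", seed = 19,
                             support_model = NULL)
  n2 <- sum(sim$truth$class_true == "TREE2")
  n3 <- sum(sim$truth$class_true == "TREE3")
  expect_gt(n3 - n2, 3 * sqrt(n2 + n3))
  expect_gt(mean(sim$truth$rerouted), 0.25)
  expect_lt(mean(sim$truth$rerouted), 0.35)
})

test_that("site patterns are balanced under the null and skewed under flow", {
  ga0 <- simulate_site_patterns(30000, gamma = 0, seed = 20)
  r0 <- abba_baba(ga0)
  expect_lt(abs(r0$Z), 4)

  ga1 <- simulate_site_patterns(30000, gamma = 0.3, direction = "P3->P2",
                                seed = 21)
  r1 <- abba_baba(ga1)
  expect_gt(r1$D, 0)
  expect_gt(r1$Z, 3)

  ga2 <- simulate_site_patterns(30000, gamma = 0.3, direction = "P3->P1",
                                seed = 22)
  expect_lt(abba_baba(ga2)$D, 0)
})

test_that("nni_perturb always changes the unrooted topology", {
  set.seed(25)
  for (rep in 1:30) {
    tr <- random_tree(sample(4:10, 1))
    tr2 <- nni_perturb(tr)
    expect_gt(rf_distance(tr, tr2), 0)
    expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
  }
  # balanced and caterpillar 4-tip trees
  expect_gt(rf_distance(parse_newick("((a,b),(c,d));"),
                        nni_perturb(parse_newick("((a,b),(c,d));"))), 0)
  expect_gt(rf_distance(parse_newick("(((a,b),c),d);"),
                        nni_perturb(parse_newick("(((a,b),c),d);"))), 0)
})

test_that("support simulation favours long internal branches", {
  set.seed(26)
  model <- default_support_model()
  long_sup <- mean(phyloconflict:::sim_supports(rep(1, 500), model))
  short_sup <- mean(phyloconflict:::sim_supports(rep(0.01, 500), model))
  expect_gt(long_sup, 90)
  expect_lt(short_sup, 40)
})

test_that("make_fixture writes a complete, reproducible bundle", {
  dir1 <- withr::local_tempdir()
  paths <- make_fixture("null-ils", dir = dir1, seed = 5)
  for (p in paths) expect_true(file.exists(p))
  truth <- readr::read_tsv(paths$truth, show_col_types = FALSE)
  expect_equal(nrow(truth), 300L)
  expect_true(all(truth$class_true %in%
                    c("TREE1", "TREE2", "TREE3", "UNCLASSIFIED")))
  dir2 <- withr::local_tempdir()
  paths2 <- make_fixture("null-ils", dir = dir2, seed = 5)
  expect_identical(readLines(paths$gene_trees_a),
                   readLines(paths2$gene_trees_a))
  expect_identical(readLines(paths$alignment), readLines(paths2$alignment))
  expect_error(make_fixture("nope", dir = dir1), "mini-ntf")
})
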