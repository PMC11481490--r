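lm7 <- micro_lineage_map()

test_that("classify_topology identifies the three backbones", {
  expect_equal(classify_topology(
    parse_newick("((((a1,a2),(d1,d2)),(r1,r2)),out);"), lm7), "TREE1")
  expect_equal(classify_topology(
    parse_newick("((((a1,a2),(r1,r2)),(d1,d2)),out);"), lm7), "TREE2")
  expect_equal(classify_topology(
    parse_newick("((((d1,d2),(r1,r2)),(a1,a2)),out);"), lm7), "TREE3")
  expect_equal(classify_topology(
    parse_newick("((((a1,d1),(a2,d2)),(r1,r2)),out);"), lm7), "UNCLASSIFIED")
  # backbone polytomy
  expect_equal(classify_topology(
    parse_newick("(((a1,a2),(d1,d2),(r1,r2)),out);"), lm7), "UNCLASSIFIED")
  expect_error(classify_topology(parse_newick("((a1,d1),out);"), lm7),
               "mismatch")
})

test_that("classification is invariant to rotation, lengths and rooting", {
  variants <- c(
    "((((a1,a2),(d1,d2)),(r1,r2)),out);",
    "(out,((r2,r1),((d2,d1),(a2,a1))));",
    "((((a1:9,a2:1):5,(d1:2,d2:2):1):4,(r1:1,r2:1):2):1,out:9);",
    "(((a1,a2),(d1,d2)),((r1,r2),out));"  # rooted elsewhere
  )
  for (s in variants)
    expect_equal(classify_topology(parse_newick(s), lm7), "TREE1")
})

test_that("cross-strategy consistency filter compares topology only", {
  ta <- parse_newick("((((a1,a2),(d1,d2)),(r1,r2)),out);")
  tb <- parse_newick("((((a1:1,a2:2):9,(d1:1,d2:1):1):1,(r1:5,r2:1):1):2,out:9);")
  expect_true(filter_consistent(ta, tb))
  expect_false(filter_consistent(ta, nni_perturb(ta)))
  single <- filter_consistent(ta, NULL)
  expect_true(single)
  expect_true(attr(single, "single_strategy"))
})

test_that("support filter keeps the boundary and honours the statistic", {
  expect_true(filter_support(parse_newick("((a,b)90,(c,d)70);"), 80))
  expect_false(filter_support(parse_newick("((a,b)75,(c,d)75);"), 80))
  expect_true(filter_support(parse_newick("((a,b)100,(c,d)100);"), 100))
  expect_false(filter_support(parse_newick("((a,b)90,(c,d)70);"), 80,
                              statistic = "min"))
  expect_error(filter_support(parse_newick("((a,b),(c,d));")), "support")
})

test_that("divergence branch length is the node1-node2 path", {
  expect_equal(divergence_branch_length(
    parse_newick("((((a1,a2):0.1,(d1,d2):0.1):0.25,(r1,r2):0.3):0.05,out:1);"),
    lm7), 0.25)
  expect_equal(divergence_branch_length(
    parse_newick("((((a1,a2):0.1,(d1,d2):0.1):0,(r1,r2):0.3):0.05,out:1);"),
    lm7), 0)
  expect_error(divergence_branch_length(
    parse_newick("((((a1,d1),(a2,d2)),(r1,r2)),out);"), lm7),
    "UNCLASSIFIED")
})

test_that("simulated divergence segments match the simulator's bookkeeping", {
  sim <- simulate_gene_trees(400, t_internal = 1, seed = 5)
  keep <- which(!is.na(sim$truth$segment_true))
  expect_gt(length(keep), 300)
  got <- vapply(keep, function(i)
    divergence_branch_length(sim$trees[[i]], sim$lineage_map), numeric(1))
  expect_equal(got, sim$truth$segment_true[keep], tolerance = 1e-10)
})

test_that("evolutionary rate follows its definition and scales linearly", {
  tr <- parse_newick("((a:1,b:2):3,c:4);")
  expect_equal(evolutionary_rate(tr), 10 / 3)
  expect_equal(evolutionary_rate(tr, method = "total"), 10)
  expect_equal(evolutionary_rate(parse_newick("((a:0,b:0):0,c:0);")), 0)
  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 2.5
  expect_equal(evolutionary_rate(scaled), 2.5 * evolutionary_rate(tr))
})

test_that("compare_groups runs Welch tests per pair", {
  d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("A", "B"), each = 3))
  res <- compare_groups(d, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(1)
  d2 <- data.frame(v = c(rnorm(50), rnorm(50, 5)),
                   g = rep(c("A", "B"), each = 50))
  expect_lt(compare_groups(d2, v, g)$p_value, 1e-10)

  d3 <- data.frame(v = c(1, 2, 3, 4), g = c("A", "A", "A", "B"))
  expect_warning(res3 <- compare_groups(d3, v, g), "n < 2")
  expect_equal(nrow(res3), 0L)
})

test_that("compare_groups holds its nominal type-I error", {
  set.seed(99)
  reps <- 1000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- data.frame(v = rnorm(40), g = rep(c("A", "B"), each = 20))
    p[i] <- compare_groups(d, v, g)$p_value
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("classification summary accounts for every gene", {
  sim <- simulate_gene_trees(150, t_internal = 0.5, seed = 21)
  trees_b <- sim$trees
  for (id in names(trees_b)[1:10]) trees_b[[id]] <- nni_perturb(trees_b[[id]])
  rec <- classify_gene_trees(sim$trees, trees_b, sim$lineage_map,
                             support_threshold = 80)
  expect_equal(nrow(rec), 150L)
  expect_equal(sum(!rec$consistent), 10L)
  summ <- classification_summary(rec)
  f <- with(summ$filters, stats::setNames(n, stage))
  expect_equal(f[["input"]],
               f[["removed_inconsistent"]] + f[["removed_low_support"]] +
                 f[["retained"]])
  expect_equal(sum(summ$classes$proportion), 1)
  expect_equal(sum(summ$classes$n), f[["retained"]])
  expect_equal(tidy(summ), summ$classes)
  expect_equal(glance(summ)$input, 150L)
  expect_error(classification_summary(rec[0, ]), "no gene")
})

test_that("minor topology classes are symmetric under pure ILS", {
  sim <- simulate_gene_trees(6000, t_internal = 0.5, seed = 13,
                             support_model = NULL)
  rec <- classify_gene_trees(sim$trees, NULL, sim$lineage_map,
                             support_threshold = NULL)
  n2 <- sum(rec$class == "TREE2")
  n3 <- sum(rec$class == "TREE3")
  p_minor <- (1 / 3) * exp(-0.5)
  se <- sqrt(6000 * p_minor * (1 - p_minor))
  expect_lt(abs(n2 - n3), 3 * sqrt(2) * se)
  expect_lt(abs(n2 - 6000 * p_minor), 3 * se)
})

test_that("unclassified fraction rises as within-lineage time shrinks", {
  frac <- vapply(c(4, 1, 0.25), function(ts) {
    sim <- simulate_gene_trees(150, n_taxa = c(2, 2, 2), t_split = ts,
                               t_internal = 0.5, seed = 31,
                               support_model = NULL)
    mean(sim$truth$class_true == "UNCLASSIFIED")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})
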