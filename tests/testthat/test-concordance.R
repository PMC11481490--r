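test_that("gCF is 100 for identical trees and counts decisive trees", {
  sp <- parse_newick("(((a,b),c),(d,e));")
  identical10 <- replicate(10, parse_newick("(((a,b),c),(d,e));"),
                           simplify = FALSE)
  g <- gene_concordance_factors(sp, identical10)
  expect_equal(nrow(g), 2L)
  expect_true(all(g$gcf == 100))
  expect_true(all(g$n_decisive == 10))
  expect_true(all(g$highlight))

  # 5 complete gene trees, 4 concordant for the (a,b) branch
  gt <- c(replicate(4, parse_newick("(((a,b),c),(d,e));"), simplify = FALSE),
          list(parse_newick("(((a,c),b),(d,e));")))
  g2 <- gene_concordance_factors(sp, gt)
  ab <- g2[vapply(g2$side, function(s) setequal(s, c("a", "b")) ||
                    setequal(s, c("c", "d", "e")), logical(1)), ]
  expect_equal(ab$gcf, 80)
  expect_true(ab$highlight)
})

test_that("gCF highlight threshold is strict", {
  sp <- parse_newick("(((a,b),c),(d,e));")
  gt <- c(replicate(3, parse_newick("(((a,b),c),(d,e));"), simplify = FALSE),
          replicate(2, parse_newick("(((a,c),b),(d,e));"), simplify = FALSE))
  g <- gene_concordance_factors(sp, gt, highlight_threshold = 60)
  ab <- g[vapply(g$side, function(s) setequal(s, c("c", "d", "e")) ||
                   setequal(s, c("a", "b")), logical(1)), ]
  expect_equal(ab$gcf, 60)   # 3/5
  expect_false(ab$highlight) # 60 is not > 60
})

test_that("gCF matches the double-loop oracle on random fixtures", {
  set.seed(17)
  sim <- simulate_gene_trees(25, n_taxa = c(3, 3, 2), t_split = 2,
                             t_internal = 0.5, seed = 17,
                             support_model = NULL)
  sp <- sim$trees[[1]]
  gene_trees <- sim$trees[-1]
  # prune random taxa from some gene trees to exercise decisiveness
  for (i in seq(2, 24, by = 3)) {
    drop <- sample(sp$tip.label, 2)
    gene_trees[[i]] <- ape::drop.tip(gene_trees[[i]], drop)
  }
  got <- gene_concordance_factors(sp, gene_trees)
  want <- oracle_gcf(sp, gene_trees)
  m <- match(got$key, want$key)
  expect_false(anyNA(m))
  expect_equal(got$n_decisive, want$n_decisive[m])
  expect_equal(got$n_concordant, want$n_concordant[m])
  expect_equal(sum(got$n_concordant), sum(want$n_concordant))
})

test_that("gcf_annotated_tree writes gCF values onto node labels", {
  sp <- parse_newick("(((a,b),c),(d,e));")
  gt <- c(replicate(4, parse_newick("(((a,b),c),(d,e));"), simplify = FALSE),
          list(parse_newick("(((a,c),b),(d,e));")))
  ann <- gcf_annotated_tree(sp, gene_concordance_factors(sp, gt))
  expect_true("80.0" %in% ann$node.label)
})

test_that("rf_matrix is symmetric with zero diagonal", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,b),(c,d));")
  t3 <- parse_newick("((a,c),(b,d));")
  m <- rf_matrix(list(x = t1, y = t2, z = t3))
  expect_equal(diag(m), c(x = 0L, y = 0L, z = 0L))
  expect_equal(m["x", "y"], 0L)
  expect_equal(m["x", "z"], 2L)
  expect_identical(m, t(m))
  expect_error(rf_matrix(list(t1, parse_newick("((a,b),(c,e));"))),
               "leaf set")

  set.seed(23)
  trees <- replicate(12, random_tree(7), simplify = FALSE)
  m2 <- rf_matrix(trees)
  for (i in 1:11) for (j in (i + 1):12)
    expect_identical(m2[i, j], oracle_rf(trees[[i]], trees[[j]]))
})

test_that("classical MDS reproduces known configurations", {
  # equilateral triangle, side 1
  d <- matrix(1, 3, 3); diag(d) <- 0
  fit <- classical_mds(d, k = 2)
  pts <- as.matrix(fit$points[, c("MDS1", "MDS2")])
  expect_equal(as.numeric(dist(pts)), rep(1, 3), tolerance = 1e-9)
  expect_equal(colMeans(pts), c(MDS1 = 0, MDS2 = 0), tolerance = 1e-9)

  # planar points: embedded distances reproduce the input
  set.seed(5)
  xy <- matrix(rnorm(20), ncol = 2)
  d2 <- as.matrix(dist(xy))
  fit2 <- classical_mds(d2, k = 2)
  emb <- as.matrix(fit2$points[, c("MDS1", "MDS2")])
  expect_lt(max(abs(as.matrix(dist(emb)) - d2)), 1e-8)
  expect_true(all(diff(fit2$eigenvalues) <= 1e-9))

  # degenerate all-zero matrix
  expect_warning(fit3 <- classical_mds(matrix(0, 4, 4), k = 2), "positive")
  expect_true(all(as.matrix(fit3$points[, -1]) == 0))
})

test_that("classical MDS validates input and is sign-deterministic", {
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(classical_mds(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
  d <- as.matrix(dist(matrix(rnorm(16, sd = 3), ncol = 2)))
  f1 <- classical_mds(d)
  f2 <- classical_mds(d)
  expect_identical(f1$points, f2$points)
  # largest-magnitude loading on each axis is positive
  for (ax in c("MDS1", "MDS2")) {
    v <- f1$points[[ax]]
    expect_gte(v[which.max(abs(v))], 0)
  }
})

test_that("duplicate trees embed at distance zero", {
  set.seed(29)
  trees <- replicate(8, random_tree(7), simplify = FALSE)
  trees <- c(trees, trees[1])
  names(trees) <- sprintf("g%d", seq_along(trees))
  m <- rf_matrix(trees)
  fit <- classical_mds(m, k = 2)
  pts <- as.matrix(fit$points[, -1])
  expect_lt(sqrt(sum((pts[1, ] - pts[9, ])^2)), 1e-9)
})

test_that("rf_mds marks the species tree row", {
  sim <- simulate_gene_trees(15, seed = 3, support_model = NULL)
  sp <- sim$trees[[1]]
  tbl <- rf_mds(sim$trees[-1], sp)
  expect_equal(sum(tbl$is_species_tree), 1L)
  expect_true(all(c("MDS1", "MDS2") %in% names(tbl)))
  expect_s3_class(attr(tbl, "mds"), "phylo_mds")
  expect_s3_class(plot_mds(tbl), "ggplot")
})
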