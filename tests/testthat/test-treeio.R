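test_that("parse_newick reads topology, lengths and supports", {
  tr <- parse_newick("((a:1,b:2):0.5,c:3);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(ape::Ntip(tr), 3L)
  ab <- mrca_node(tr, c("a", "b"))
  expect_equal(tr$edge.length[tr$edge[, 2] == ab], 0.5)

  tr2 <- parse_newick("((a,b)95,c);")
  expect_equal(node_supports(tr2), c(NA, 95))
})

test_that("parse_newick rejects malformed or invalid input", {
  expect_error(parse_newick("((a,b,c);"), "unbalanced")
  expect_error(parse_newick("((a,b),c)"), ";")
  expect_error(parse_newick("((a,a),c);"), "duplicate")
  expect_error(parse_newick("((a:-1,b),c);"), "negative")
})

test_that("support dialect handles composite and disabled labels", {
  tr <- parse_newick("((a,b)87.2/95,c);", support_split = "/",
                     support_field = 2)
  expect_equal(node_supports(tr), c(NA, 95))
  tr2 <- parse_newick("((a,b)95,c);", supports_from_labels = FALSE)
  expect_true(all(is.na(node_supports(tr2))))
})

test_that("parse/write round-trips topology, lengths and supports", {
  s <- "((a:1,b:2)95:0.5,c:3);"
  expect_equal(write_newick(parse_newick(s)), s)
  expect_false(grepl(":", write_newick(parse_newick("((a,b),c);"))))

  set.seed(41)
  sim <- simulate_gene_trees(60, t_internal = 0.8, seed = 41)
  for (tr in sim$trees[1:60]) {
    s1 <- write_newick(tr)
    back <- parse_newick(s1)
    expect_equal(write_newick(back), s1)
    expect_identical(topology_id(back), topology_id(tr))
  }
  for (n in c(5, 8, 12)) {
    for (rep in 1:20) {
      tr <- random_tree(n)
      s1 <- write_newick(tr)
      expect_equal(write_newick(parse_newick(s1)), s1)
    }
  }
})

test_that("bipartitions enumerates exactly the internal edges", {
  expect_equal(bipartitions(parse_newick("((a,b),(c,d));"))$key, "c\x1fd")
  expect_equal(nrow(bipartitions(parse_newick("(((a,b),c),(d,e));"))), 2L)
  expect_equal(nrow(bipartitions(parse_newick("((a,b),c);"))), 0L)
  # polytomies contribute fewer splits
  expect_equal(nrow(bipartitions(parse_newick("((a,b,c),(d,e));"))), 1L)
  set.seed(7)
  for (rep in 1:25) {
    tr <- random_tree(8)
    expect_equal(nrow(bipartitions(tr)), 8L - 3L)  # binary: n - 3
  }
})

test_that("rf_distance matches a brute-force oracle and is a metric", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, parse_newick("((a,b),(c,e));")),
               "leaf sets differ")

  set.seed(11)
  trees <- replicate(60, random_tree(7), simplify = FALSE)
  for (rep in 1:200) {
    ij <- sample.int(60, 2)
    a <- trees[[ij[1]]]; b <- trees[[ij[2]]]
    d <- rf_distance(a, b)
    expect_identical(d, oracle_rf(a, b))
    expect_equal(d, as.numeric(phangorn::RF.dist(a, b)))   # second oracle
    expect_identical(d, rf_distance(b, a))                 # symmetry
    expect_lte(d, 2 * (7 - 3))                              # upper bound
    expect_equal(d == 0L, topology_id(a) == topology_id(b))
  }
  # triangle inequality on sampled triples
  for (rep in 1:50) {
    ijk <- sample.int(60, 3)
    a <- trees[[ijk[1]]]; b <- trees[[ijk[2]]]; c <- trees[[ijk[3]]]
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
  }
})

test_that("mrca, total length and mean support behave as specified", {
  tr <- parse_newick("(((a,b),c),d);")
  expect_equal(mrca_node(tr, tr$tip.label), ape::Ntip(tr) + 1L)
  expect_equal(mrca_node(tr, c("a", "b")), ape::getMRCA(tr, c("a", "b")))
  expect_equal(mrca_node(tr, "a"), which(tr$tip.label == "a"))
  expect_error(mrca_node(tr, "zz"), "unknown")

  expect_equal(total_tree_length(parse_newick("((a:1,b:2):3,c:4);")), 10)
  expect_equal(total_tree_length(parse_newick("((a:0,b:0):0,c:0);")), 0)
  expect_error(total_tree_length(parse_newick("((a,b),c);")),
               "branch length")

  expect_equal(mean_support(parse_newick("((a,b)90,(c,d)70);")), 80)
  expect_equal(mean_support(parse_newick("(((a,b)100,c)100,d);")), 100)
  expect_error(mean_support(parse_newick("((a,b),(c,d));")), "support")
  # random support sets equal a hand-summed mean
  set.seed(3)
  for (rep in 1:20) {
    sup <- sample(0:100, 2)
    tr <- parse_newick(sprintf("(((a,b)%d,c)%d,d);", sup[1], sup[2]))
    expect_equal(mean_support(tr), mean(sup))
  }
})

test_that("topology_id ignores label order, lengths and supports", {
  expect_identical(topology_id(parse_newick("((a,b),(c,d));")),
                   topology_id(parse_newick("((b,a),(d,c));")))
  expect_identical(topology_id(parse_newick("((a:1,b:9)5:2,(c:1,d:1):3);")),
                   topology_id(parse_newick("((a,b),(c,d));")))
  expect_false(topology_id(parse_newick("((a,b),(c,d));")) ==
                 topology_id(parse_newick("((a,c),(b,d));")))
})

test_that("gene-tree files round-trip with and without gene ids", {
  sim <- simulate_gene_trees(5, seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_trees(sim$trees, path)
  back <- read_gene_trees(path)
  expect_identical(names(back), names(sim$trees))
  expect_identical(vapply(back, topology_id, ""),
                   vapply(sim$trees, topology_id, ""))
  # bare newick lines fall back to line order
  writeLines(vapply(sim$trees, write_newick, ""), path)
  expect_message(bare <- read_gene_trees(path), "line order")
  expect_equal(length(bare), 5L)
})
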