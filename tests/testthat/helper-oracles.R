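# Independent oracles and small fixture builders used across the suite.

# Random rooted binary tree with branch lengths, labels t1..tn.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Brute-force RF oracle: symmetric difference of clade sets computed with
# ape::prop.part (a code path entirely separate from the package's own
# bipartition traversal), canonicalised against the full taxon set.
oracle_rf <- function(t1, t2) {
  canon_splits <- function(tr) {
    taxa <- sort(tr$tip.label)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    out <- character(0)
    for (cl in pp) {
      side <- sort(labs[cl])
      if (length(side) < 2L || length(side) > length(taxa) - 2L) next
      if (taxa[1] %in% side) side <- setdiff(taxa, side)
      out <- c(out, paste(side, collapse = "|"))
    }
    unique(out)
  }
  s1 <- canon_splits(t1)
  s2 <- canon_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Double-loop gCF oracle: for every species-tree branch and gene tree,
# restrict the branch's two sides to the gene taxa and test concordance by
# comparing against every clade of the gene tree (both orientations).
oracle_gcf <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  pp <- ape::prop.part(species_tree)
  labs <- attr(pp, "labels")
  branches <- list()
  for (cl in pp) {
    side <- sort(labs[cl])
    if (length(side) >= 2L && length(side) <= length(taxa) - 2L)
      branches[[length(branches) + 1L]] <- side
  }
  res <- data.frame(n_decisive = integer(length(branches)),
                    n_concordant = integer(length(branches)))
  gene_clades <- lapply(gene_trees, function(g) {
    gp <- ape::prop.part(g)
    gl <- attr(gp, "labels")
    lapply(gp, function(cl) sort(gl[cl]))
  })
  for (i in seq_along(branches)) {
    for (j in seq_along(gene_trees)) {
      gt <- sort(gene_trees[[j]]$tip.label)
      a <- intersect(branches[[i]], gt)
      b <- setdiff(gt, a)
      if (length(a) < 2L || length(b) < 2L) next
      res$n_decisive[i] <- res$n_decisive[i] + 1L
      hit <- FALSE
      for (cl in gene_clades[[j]]) {
        if (identical(cl, sort(a)) || identical(cl, sort(b))) {
          hit <- TRUE
          break
        }
      }
      if (hit) res$n_concordant[i] <- res$n_concordant[i] + 1L
    }
  }
  res$key <- vapply(branches, function(s) {
    if (min(taxa) %in% s) s <- setdiff(taxa, s)
    paste(sort(s), collapse = "\x1f")
  }, character(1))
  res
}

# 7-taxon lineage map shared by classification tests.
micro_lineage_map <- function() {
  lineage_map(c("a1", "a2", "d1", "d2", "r1", "r2", "out"),
              c("L1", "L1", "L2", "L2", "L3", "L3", "OUT"))
}

# Toy 10-column alignment with exactly 3 ABBA columns and 1 BABA column
# (hand-counted; remaining columns uninformative or monomorphic).
toy_abba_alignment <- function() {
  grouped_alignment(
    c(P1 = "ACGTAAACTC",
      P2 = "CATGACACTC",
      P3 = "CCTGAGCATC",
      O  = "AAGTAAAATA"),
    c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O")
  )
}
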