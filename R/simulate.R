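# Multispecies-coalescent simulators.
#
# Species-tree model (times in coalescent units, tips at 0):
#   t12   = t_split                 L1 and L2 populations merge
#   t123  = t_split + t_internal    ancestor of (L1,L2) merges with L3
#   troot = t123 + t_root           ingroup ancestor merges with the outgroup
# t_internal is the ILS-controlling branch: the probability that a gene tree
# is discordant with the species backbone is (2/3) * exp(-t_internal) for one
# sampled lineage per species. An optional introgression pulse reroutes the
# recipient lineage's ancestry into the donor population at time t_mig with
# probability gamma per gene (or per site).

# Tip bitmasks for the 4-taxon vectorized core: L1/P1 = 1, L2/P2 = 2,
# L3/P3 = 4, OUT/O = 8.

# Vectorized 4-taxon coalescent. Returns the labelled history of each
# genealogy as (cl1, T1) for the first coalescence (a 2-bit clade), (cl2, T2)
# for the second (either a superset of cl1 or a disjoint pair) and the root
# time T3. Migration: with probability gamma the migrant tip (1 or 2) moves
# into the L3/P3 population at t_mig and stays with it until t123.
sim_quartet_core <- function(n, t12, t123, troot, gamma = 0,
                             migrant = 2L, t_mig = t12 / 2) {
  stopifnot(t12 >= 0, t123 >= t12, troot >= t123,
            gamma >= 0, gamma <= 1, migrant %in% c(1L, 2L))
  if (gamma > 0) stopifnot(t_mig >= 0, t_mig <= t12)
  w3 <- troot - t123
  mig <- if (gamma > 0) stats::runif(n) < gamma else rep(FALSE, n)
  # early pair: {1,2} in the merged (L1,L2) population over [t12, t123), or
  # {migrant, 3} in the L3 population over [t_mig, t123) for migrant genes
  pair_mask <- ifelse(mig, bitwOr(migrant, 4L), 3L)
  pair_start <- ifelse(mig, t_mig, t12)
  pair_window <- ifelse(mig, t123 - t_mig, t123 - t12)
  e0 <- stats::rexp(n)
  early <- e0 < pair_window

  cl1 <- integer(n); T1 <- numeric(n)
  cl2 <- integer(n); T2 <- numeric(n)
  T3 <- numeric(n)
  cl1[early] <- pair_mask[early]
  T1[early] <- pair_start[early] + e0[early]

  # epoch [t123, troot): all surviving ingroup lineages in one population
  k_in <- rep(3L, n)          # ingroup lineages entering the root epoch
  # early-pair genes: two lineages {pair, third}
  e1 <- stats::rexp(n)
  two <- early & (e1 < w3)
  cl2[two] <- 7L
  T2[two] <- t123 + e1[two]
  k_in[early] <- ifelse(two[early], 1L, 2L)
  # no-early genes: three singleton lineages
  ne <- which(!early)
  if (length(ne)) {
    g1 <- stats::rexp(length(ne)) / 3
    pick <- c(3L, 5L, 6L)[sample.int(3L, length(ne), replace = TRUE)]
    f1 <- g1 < w3
    idx1 <- ne[f1]
    cl1[idx1] <- pick[f1]
    T1[idx1] <- t123 + g1[f1]
    g2 <- stats::rexp(length(ne))
    f2 <- f1 & (g1 + g2 < w3)
    idx2 <- ne[f2]
    cl2[idx2] <- 7L
    T2[idx2] <- t123 + g1[f2] + g2[f2]
    k_in[ne] <- ifelse(f2, 1L, ifelse(f1, 2L, 3L))
  }

  # root epoch [troot, Inf): outgroup joins; free Kingman coalescent
  k2 <- which(k_in == 1L)
  if (length(k2)) T3[k2] <- troot + stats::rexp(length(k2))
  k3 <- which(k_in == 2L)
  if (length(k3)) {
    # lineages {X = cl1 node, Y = remaining ingroup tip, d}
    ev1 <- troot + stats::rexp(length(k3)) / 3
    y_mask <- 7L - cl1[k3]
    pairpick <- sample.int(3L, length(k3), replace = TRUE)
    cl2[k3] <- ifelse(pairpick == 1L, 7L,                       # (X, Y)
                      ifelse(pairpick == 2L, bitwOr(cl1[k3], 8L),  # (X, d)
                             bitwOr(y_mask, 8L)))               # (Y, d)
    T2[k3] <- ev1
    T3[k3] <- ev1 + stats::rexp(length(k3))
  }
  k4 <- which(k_in == 3L)
  if (length(k4)) {
    m <- length(k4)
    ev1 <- troot + stats::rexp(m) / 6
    pair6 <- c(3L, 5L, 9L, 6L, 10L, 12L)[sample.int(6L, m, replace = TRUE)]
    cl1[k4] <- pair6
    T1[k4] <- ev1
    ev2 <- ev1 + stats::rexp(m) / 3
    # remaining singles
    rest <- 15L - pair6
    s1 <- ifelse(bitwAnd(rest, 1L) > 0, 1L,
                 ifelse(bitwAnd(rest, 2L) > 0, 2L, 4L))
    s2 <- rest - s1
    pick3 <- sample.int(3L, m, replace = TRUE)
    cl2[k4] <- ifelse(pick3 == 1L, bitwOr(pair6, s1),
                      ifelse(pick3 == 2L, bitwOr(pair6, s2), rest))
    T2[k4] <- ev2
    T3[k4] <- ev2 + stats::rexp(m)
  }
  list(cl1 = cl1, T1 = T1, cl2 = cl2, T2 = T2, T3 = T3, mig = mig)
}

# Backbone class of a 4-taxon labelled history: the ingroup pair on the
# opposite side of the internal edge from the outgroup.
quartet_core_class <- function(h) {
  split <- ifelse(bitwAnd(h$cl1, 8L) > 0L, 15L - h$cl1, h$cl1)
  c(`3` = "TREE1", `5` = "TREE2", `6` = "TREE3")[as.character(split)]
}

# True node1-node2 segment length of the outgroup-rooted genealogy (see the
# vignette for the case analysis).
quartet_core_segment <- function(h) {
  disjoint <- bitwAnd(h$cl1, h$cl2) == 0L
  ifelse(disjoint, 2 * h$T3 - h$T1 - h$T2, h$T2 - h$T1)
}

# Simulated bootstrap supports: a logistic push towards 100 for long
# subtending branches, beta noise around it.
sim_supports <- function(lengths, model) {
  p <- stats::plogis((lengths - model$midpoint) / model$scale)
  k <- model$concentration
  round(100 * stats::rbeta(length(lengths), 1 + k * p, 1 + k * (1 - p)))
}

default_support_model <- function() {
  list(midpoint = 0.2, scale = 0.1, concentration = 30)
}

# phylo object from one 4-taxon labelled history.
quartet_core_tree <- function(cl1, T1, cl2, T2, T3, tip_names,
                              sup1 = NULL, sup2 = NULL) {
  bits <- function(mask) which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)
  p1 <- bits(cl1)
  caterpillar <- bitwAnd(cl1, cl2) != 0L
  # nodes: root = 5; cl2 node = 6; cl1 node = 7
  if (caterpillar) {
    mid <- setdiff(bits(cl2), p1)
    top <- setdiff(1:4, bits(cl2))
    edge <- rbind(c(7L, p1[1]), c(7L, p1[2]),
                  c(6L, 7L), c(6L, mid),
                  c(5L, 6L), c(5L, top))
    len <- c(T1, T1, T2 - T1, T2, T3 - T2, T3)
  } else {
    p2 <- bits(cl2)
    edge <- rbind(c(7L, p1[1]), c(7L, p1[2]),
                  c(6L, p2[1]), c(6L, p2[2]),
                  c(5L, 7L), c(5L, 6L))
    len <- c(T1, T1, T2, T2, T3 - T1, T3 - T2)
  }
  lab2 <- if (is.null(sup2)) "" else as.character(sup2)
  lab1 <- if (is.null(sup1)) "" else as.character(sup1)
  structure(list(edge = edge, edge.length = len, tip.label = tip_names,
                 Nnode = 3L, node.label = c("", lab2, lab1)),
            class = "phylo")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws `n_genes` genealogies on the three-lineage-plus-outgroup species
#' tree. Within each species-tree branch, lineages coalesce pairwise at rate
#' `choose(k, 2)` per coalescent-time unit, truncated at the branch end;
#' survivors pass rootward. With probability `gamma` a gene's recipient
#' lineage is rerouted into the donor population at `t_mig` (pulse
#' approximation of introgression). Output trees are ultrametric with
#' coalescent-unit branch lengths and simulated bootstrap supports; the truth
#' table records each gene's realized backbone class, whether the pulse
#' fired, and the true node1-node2 divergence segment.
#'
#' @param n_genes Number of gene trees.
#' @param n_taxa Integer vector `c(n1, n2, n3)`: sampled taxa per ingroup
#'   lineage (a single outgroup taxon is always added).
#' @param t_split Time from the tips to the L1/L2 population merger
#'   (coalescent units); the window for within-lineage coalescence.
#' @param t_internal The internal branch between the (L1,L2) ancestor and the
#'   ingroup root: the ILS-controlling parameter.
#' @param t_root Extra time from the ingroup root to the outgroup join.
#' @param gamma Introgression pulse probability per gene, in \[0, 1\].
#' @param donor,recipient Lineage labels (`"L1"`, `"L2"`, `"L3"`); with
#'   probability `gamma` the recipient's lineages move into the donor
#'   population at `t_mig`.
#' @param t_mig Pulse time, in `(0, t_split)`; default `t_split / 2`.
#' @param support_model List with `midpoint`, `scale`, `concentration`
#'   controlling the logistic-beta support sampler, or `NULL` for trees
#'   without supports.
#' @param seed Optional integer seed (the simulation is fully reproducible
#'   under it).
#' @return A list with `trees` (named list of `"phylo"`), `truth` (tibble:
#'   `gene_id`, `class_true`, `rerouted`, `segment_true`) and `lineage_map`
#'   (the matching [lineage_map()]).
#' @examples
#' sim <- simulate_gene_trees(100, t_internal = 1, seed = 1)
#' table(sim$truth$class_true)
#' @export
simulate_gene_trees <- function(n_genes, n_taxa = c(1L, 1L, 1L),
                                t_split = 1, t_internal = 1, t_root = 2,
                                gamma = 0, donor = "L3", recipient = "L2",
                                t_mig = t_split / 2,
                                support_model = default_support_model(),
                                seed = NULL) {
  stopifnot(n_genes >= 1, length(n_taxa) == 3L, all(n_taxa >= 1L),
            t_split >= 0, t_internal >= 0, t_root >= 0,
            gamma >= 0, gamma <= 1)
  if (gamma > 0) {
    stopifnot(donor %in% c("L1", "L2", "L3"),
              recipient %in% c("L1", "L2", "L3"), donor != recipient,
              t_mig > 0, t_mig < t_split)
  }
  if (!is.null(seed)) set.seed(seed)
  t12 <- t_split; t123 <- t_split + t_internal; troot <- t123 + t_root
  taxa <- c(paste0("L1_", seq_len(n_taxa[1])),
            paste0("L2_", seq_len(n_taxa[2])),
            paste0("L3_", seq_len(n_taxa[3])), "OUT")
  lin <- c(rep("L1", n_taxa[1]), rep("L2", n_taxa[2]),
           rep("L3", n_taxa[3]), "OUT")
  lm <- lineage_map(taxa, lin)
  ids <- sprintf("gene_%05d", seq_len(n_genes))
  fast <- all(n_taxa == 1L) &&
    (gamma == 0 || (donor == "L3" && recipient %in% c("L1", "L2")))
  if (fast) {
    migrant <- if (gamma > 0 && recipient == "L1") 1L else 2L
    h <- sim_quartet_core(n_genes, t12, t123, troot, gamma = gamma,
                          migrant = migrant, t_mig = t_mig)
    cls <- unname(quartet_core_class(h))
    seg <- quartet_core_segment(h)
    tip_names <- c("L1_1", "L2_1", "L3_1", "OUT")
    sup1 <- sup2 <- vector("list", n_genes)
    if (!is.null(support_model)) {
      cat2 <- bitwAnd(h$cl1, h$cl2) != 0L
      len1 <- ifelse(cat2, h$T2 - h$T1, h$T3 - h$T1)
      len2 <- h$T3 - h$T2
      s1 <- sim_supports(len1, support_model)
      s2 <- sim_supports(len2, support_model)
    }
    trees <- lapply(seq_len(n_genes), function(i) {
      quartet_core_tree(h$cl1[i], h$T1[i], h$cl2[i], h$T2[i], h$T3[i],
                        tip_names,
                        sup1 = if (is.null(support_model)) NULL else s1[i],
                        sup2 = if (is.null(support_model)) NULL else s2[i])
    })
    names(trees) <- ids
    truth <- tibble::tibble(gene_id = ids, class_true = cls,
                            rerouted = h$mig, segment_true = seg)
    return(list(trees = trees, truth = truth, lineage_map = lm))
  }
  # general per-gene engine
  trees <- vector("list", n_genes)
  cls <- character(n_genes)
  seg <- numeric(n_genes)
  rer <- logical(n_genes)
  lin_tips <- split(seq_along(taxa), lin)[c("L1", "L2", "L3", "OUT")]
  for (i in seq_len(n_genes)) {
    reroute <- gamma > 0 && stats::runif(1) < gamma
    g <- sim_gene_generic(lin_tips, t_mig = t_mig, t12 = t12, t123 = t123,
                          troot = troot, reroute = reroute,
                          donor = donor, recipient = recipient)
    trees[[i]] <- merges_to_phylo(g, taxa, support_model)
    tr <- truth_from_merges(g, lin_tips)
    cls[i] <- tr$class
    seg[i] <- tr$segment
    rer[i] <- reroute
  }
  names(trees) <- ids
  truth <- tibble::tibble(gene_id = ids, class_true = cls,
                          rerouted = rer, segment_true = seg)
  list(trees = trees, truth = truth, lineage_map = lm)
}

# One gene under the general structured coalescent. lin_tips: list of tip
# index vectors per population. Returns merges: matrix (child1, child2) with
# merge times; internal node ids follow tips in merge order.
sim_gene_generic <- function(lin_tips, t_mig, t12, t123, troot, reroute,
                             donor, recipient) {
  n_tips <- sum(lengths(lin_tips))
  node_time <- numeric(2L * n_tips)        # indexed by node id
  merges <- matrix(0L, nrow = n_tips - 1L, ncol = 2L)
  merge_time <- numeric(n_tips - 1L)
  n_merge <- 0L
  pops <- lin_tips
  coalesce_pop <- function(ids, t0, t1) {
    while (length(ids) >= 2L) {
      k <- length(ids)
      dt <- stats::rexp(1, k * (k - 1) / 2)
      if (t0 + dt > t1) break
      t0 <- t0 + dt
      pr <- sample.int(k, 2L)
      n_merge <<- n_merge + 1L
      new_id <- n_tips + n_merge
      merges[n_merge, ] <<- c(ids[pr[1]], ids[pr[2]])
      merge_time[n_merge] <<- t0
      node_time[new_id] <<- t0
      ids <- c(ids[-pr], new_id)
    }
    ids
  }
  bounds <- c(if (reroute) t_mig, t12, t123, troot, Inf)
  cur <- 0
  for (b in bounds) {
    for (p in names(pops))
      pops[[p]] <- coalesce_pop(pops[[p]], cur, b)
    if (reroute && b == t_mig) {
      pops[[donor]] <- c(pops[[donor]], pops[[recipient]])
      pops[[recipient]] <- integer(0)
    } else if (b == t12) {
      pops <- c(list(A12 = c(pops$L1, pops$L2)),
                pops[setdiff(names(pops), c("L1", "L2"))])
    } else if (b == t123) {
      pops <- c(list(A123 = c(pops$A12, pops$L3)),
                pops[setdiff(names(pops), c("A12", "L3"))])
    } else if (b == troot) {
      pops <- list(R = unlist(pops, use.names = FALSE))
    }
    cur <- b
  }
  list(merges = merges, merge_time = merge_time, node_time = node_time,
       n_tips = n_tips)
}

# Convert a merge record to an ape phylo (root renumbered to n + 1).
merges_to_phylo <- function(g, taxa, support_model) {
  n <- g$n_tips
  m <- nrow(g$merges)
  # internal node g id n + j  ->  ape id n + (m - j + 1); root (last merge)
  # becomes n + 1
  remap <- function(id) ifelse(id <= n, id, n + (m - (id - n) + 1L))
  parent <- remap(n + seq_len(m))
  edge <- rbind(cbind(parent, remap(g$merges[, 1])),
                cbind(parent, remap(g$merges[, 2])))
  child_old <- c(g$merges[, 1], g$merges[, 2])
  len <- rep(g$merge_time, 2L) - g$node_time[child_old]
  storage.mode(edge) <- "integer"
  node_label <- rep("", m)
  if (!is.null(support_model)) {
    # subtending branch length of each non-root internal node
    for (j in seq_len(m - 1L)) {
      ape_id <- n + (m - j + 1L)
      sub_len <- len[which(edge[, 2] == ape_id)]
      node_label[ape_id - n] <-
        as.character(sim_supports(sub_len, support_model))
    }
  }
  structure(list(edge = edge, edge.length = unname(len), tip.label = taxa,
                 Nnode = m, node.label = node_label),
            class = "phylo")
}

# Realized backbone class + divergence segment from the merge record,
# independent of any tree-object machinery: a lineage is monophyletic iff its
# exact tip set appears as a merge clade; the sister pair is read off the
# first clade that unites two complete lineages (or a complete lineage with
# the outgroup).
truth_from_merges <- function(g, lin_tips) {
  n <- g$n_tips
  m <- nrow(g$merges)
  clade <- vector("list", n + m)
  for (i in seq_len(n)) clade[[i]] <- i
  for (j in seq_len(m)) {
    pr <- g$merges[j, ]
    clade[[n + j]] <- sort(c(clade[[pr[1]]], clade[[pr[2]]]))
  }
  int_clades <- clade[n + seq_len(m)]
  has_clade <- function(tipset) {
    tipset <- sort(unname(tipset))
    for (cl in int_clades) if (identical(cl, tipset)) return(TRUE)
    FALSE
  }
  clade_time <- function(tipset) {
    tipset <- sort(unname(tipset))
    for (j in seq_len(m))
      if (identical(int_clades[[j]], tipset)) return(g$merge_time[j])
    NA_real_
  }
  mono <- vapply(c("L1", "L2", "L3"), function(p) {
    length(lin_tips[[p]]) == 1L || has_clade(lin_tips[[p]])
  }, logical(1))
  if (!all(mono))
    return(list(class = "UNCLASSIFIED", segment = NA_real_))
  pairs <- list(TREE1 = c("L1", "L2"), TREE2 = c("L1", "L3"),
                TREE3 = c("L2", "L3"))
  cls <- NA_character_
  for (nm in names(pairs)) {
    if (has_clade(unlist(lin_tips[pairs[[nm]]]))) { cls <- nm; break }
  }
  if (is.na(cls)) {
    # a complete lineage forms a cherry with the outgroup: the other two
    # ingroup lineages are sisters in the outgroup-rooted tree
    third <- c(TREE1 = "L3", TREE2 = "L2", TREE3 = "L1")
    for (nm in names(third)) {
      if (has_clade(c(lin_tips[[third[[nm]]]], lin_tips$OUT))) {
        cls <- nm; break
      }
    }
  }
  if (is.na(cls))
    return(list(class = "UNCLASSIFIED", segment = NA_real_))
  seg <- NA_real_
  t_pair <- clade_time(unlist(lin_tips[pairs[[cls]]]))
  t_ing <- clade_time(unlist(lin_tips[c("L1", "L2", "L3")]))
  if (!is.na(t_pair) && !is.na(t_ing)) seg <- t_ing - t_pair
  list(class = cls, segment = seg)
}

#' Simulate biallelic site patterns for the ABBA-BABA test
#'
#' Draws one four-tip genealogy per site under the multispecies coalescent
#' (with the optional introgression pulse), places exactly one mutation
#' uniformly along the total branch length, and emits the resulting
#' biallelic column — the generative counterpart of the ABBA/BABA pattern
#' counts. One sequence per population `P1`, `P2`, `P3`, `O`.
#'
#' @param n_sites Number of columns.
#' @param t12,t_internal,t_root Species-tree times as in
#'   [simulate_gene_trees()] (`t12` plays the role of `t_split`).
#' @param gamma Pulse probability per site.
#' @param direction `"P3->P2"` (gene flow into P2, expected D > 0) or
#'   `"P3->P1"` (expected D < 0).
#' @param t_mig Pulse time in `(0, t12)`.
#' @param seed Optional integer seed; fixed seed gives a byte-identical
#'   alignment.
#' @return A [grouped_alignment()] with sequences `P1`, `P2`, `P3`, `O`.
#' @export
simulate_site_patterns <- function(n_sites, t12 = 1, t_internal = 1,
                                   t_root = 1, gamma = 0,
                                   direction = c("P3->P2", "P3->P1"),
                                   t_mig = t12 / 2, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  t123 <- t12 + t_internal
  troot <- t123 + t_root
  migrant <- if (direction == "P3->P2") 2L else 1L
  h <- sim_quartet_core(n_sites, t12, t123, troot, gamma = gamma,
                        migrant = migrant, t_mig = t_mig)
  cat2 <- bitwAnd(h$cl1, h$cl2) != 0L
  # edge lengths: four pendant edges + two internal edges
  join_time <- function(bit) {
    ifelse(bitwAnd(h$cl1, bit) > 0L, h$T1,
           ifelse(bitwAnd(h$cl2, bit) > 0L, h$T2, h$T3))
  }
  la <- join_time(1L); lb <- join_time(2L)
  lc <- join_time(4L); ld <- join_time(8L)
  li1 <- ifelse(cat2, h$T2 - h$T1, h$T3 - h$T1)
  li2 <- h$T3 - h$T2
  seg <- cbind(la, lb, lc, ld, li1, li2)
  total <- rowSums(seg)
  u <- stats::runif(n_sites) * total
  cum <- t(apply(seg, 1, cumsum))
  pick <- max.col(cum >= u, ties.method = "first")
  masks <- cbind(1L, 2L, 4L, 8L, h$cl1, h$cl2)
  derived_mask <- masks[cbind(seq_len(n_sites), pick)]
  acgt <- c("A", "C", "G", "T")
  anc <- sample(acgt, n_sites, replace = TRUE)
  shift <- sample.int(3L, n_sites, replace = TRUE)
  der <- acgt[(match(anc, acgt) - 1L + shift) %% 4L + 1L]
  col_for <- function(bit) {
    ifelse(bitwAnd(derived_mask, bit) > 0L, der, anc)
  }
  seqs <- rbind(P1 = col_for(1L), P2 = col_for(2L),
                P3 = col_for(4L), O = col_for(8L))
  grouped_alignment(seqs, c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"))
}

#' One random nearest-neighbour interchange
#'
#' Applies a single NNI move across a randomly chosen internal edge,
#' guaranteeing a changed unrooted topology. Used to inject controlled
#' inconsistencies between the two inference-strategy tree sets.
#'
#' @inheritParams write_newick
#' @return A `"phylo"` object with RF distance > 0 to the input.
#' @export
nni_perturb <- function(tree) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 4L)
  n <- ape::Ntip(tree)
  root <- find_root(tree)
  id0 <- topology_id(tree)
  # candidate adjacent internal-node pairs (u, v): parent/child pairs of
  # internal nodes, plus sibling internal children of the root (the root is
  # a degree-2 point on an internal edge of the unrooted tree)
  pc <- tree$edge[tree$edge[, 1] != root & tree$edge[, 2] > n, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(pc)), function(i) pc[i, ])
  root_int <- tree$edge[tree$edge[, 1] == root & tree$edge[, 2] > n, 2]
  if (length(root_int) >= 2L)
    pairs <- c(pairs, utils::combn(root_int, 2, simplify = FALSE))
  if (!length(pairs)) stop("no internal edge to swap", call. = FALSE)
  for (attempt in 1:30) {
    pr <- pairs[[sample.int(length(pairs), 1)]]
    u <- pr[1]; v <- pr[2]
    e_x <- which(tree$edge[, 1] == u & tree$edge[, 2] != v)
    e_y <- which(tree$edge[, 1] == v & tree$edge[, 2] != u)
    if (!length(e_x) || !length(e_y)) next
    e_x <- e_x[sample.int(length(e_x), 1)]
    e_y <- e_y[sample.int(length(e_y), 1)]
    new <- tree
    new$edge[e_x, 1] <- v
    new$edge[e_y, 1] <- u
    if (topology_id(new) != id0) return(new)
  }
  stop("failed to produce a topology-changing NNI", call. = FALSE)
}

#' Write a self-contained simulated fixture bundle
#'
#' Generates a small data set that exercises the whole pipeline: gene trees
#' under two "strategies" (strategy B is a copy of strategy A with a random
#' NNI applied to a configured fraction of genes), the species tree, the
#' lineage map, a site-pattern alignment with population map, the truth
#' table, and a YAML configuration echo pointing at the files.
#'
#' Presets: `"mini-ntf"` (200 genes, 3+3+2 ingroup taxa + outgroup, 5%
#' injected inconsistencies), `"null-ils"` (300 genes, one taxon per lineage,
#' t_internal = 0.5, no introgression), `"introgression"` (as null-ils with a
#' gamma = 0.3 pulse from L3 into L2).
#'
#' @param preset Preset name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of file paths (also a valid
#'   [run_conflict_pipeline()] config).
#' @export
make_fixture <- function(preset = c("mini-ntf", "null-ils", "introgression"),
                         dir, seed = 1L) {
  presets <- list(
    "mini-ntf" = list(n_genes = 200L, n_taxa = c(3L, 3L, 2L), t_split = 4,
                      t_internal = 0.5, t_root = 2, gamma = 0,
                      nni_fraction = 0.05, n_sites = 20000L),
    "null-ils" = list(n_genes = 300L, n_taxa = c(1L, 1L, 1L), t_split = 1,
                      t_internal = 0.5, t_root = 2, gamma = 0,
                      nni_fraction = 0, n_sites = 20000L),
    "introgression" = list(n_genes = 300L, n_taxa = c(1L, 1L, 1L),
                           t_split = 1, t_internal = 0.5, t_root = 2,
                           gamma = 0.3, nni_fraction = 0, n_sites = 20000L)
  )
  if (!preset[1] %in% names(presets))
    stop("unknown preset '", preset[1], "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  preset <- match.arg(preset)
  cfg <- presets[[preset]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  sim <- simulate_gene_trees(
    cfg$n_genes, n_taxa = cfg$n_taxa, t_split = cfg$t_split,
    t_internal = cfg$t_internal, t_root = cfg$t_root, gamma = cfg$gamma,
    donor = "L3", recipient = "L2"
  )
  trees_b <- sim$trees
  n_swap <- round(cfg$nni_fraction * cfg$n_genes)
  if (n_swap > 0 && all(cfg$n_taxa >= 1) && sum(cfg$n_taxa) + 1 >= 4) {
    swap <- sample(names(trees_b), n_swap)
    for (id in swap) trees_b[[id]] <- nni_perturb(trees_b[[id]])
  }
  ga <- simulate_site_patterns(cfg$n_sites, t12 = cfg$t_split,
                               t_internal = cfg$t_internal,
                               t_root = cfg$t_root, gamma = cfg$gamma,
                               direction = "P3->P2")
  sp <- species_tree_from_config(cfg$n_taxa, cfg$t_split, cfg$t_internal,
                                 cfg$t_root)
  paths <- list(
    gene_trees_a = file.path(dir, "gene_trees_a.nwk"),
    gene_trees_b = file.path(dir, "gene_trees_b.nwk"),
    species_tree = file.path(dir, "species_tree.nwk"),
    lineage_map = file.path(dir, "lineage_map.tsv"),
    alignment = file.path(dir, "alignment.fasta"),
    pop_map = file.path(dir, "pop_map.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yml")
  )
  write_gene_trees(sim$trees, paths$gene_trees_a)
  write_gene_trees(trees_b, paths$gene_trees_b)
  writeLines(write_newick(sp), paths$species_tree)
  write_lineage_map(sim$lineage_map, paths$lineage_map)
  write_grouped_alignment(ga, paths$alignment, paths$pop_map)
  readr::write_tsv(sim$truth, paths$truth)
  yaml::write_yaml(c(list(preset = preset, seed = seed), cfg,
                     lapply(paths, normalizePath, mustWork = FALSE)),
                   paths$config)
  invisible(paths)
}

# Ultrametric species tree matching the simulator's times; taxa within a
# lineage are arranged as a ladder with evenly spaced split times below
# t_split (the simulator treats each lineage as panmictic, so within-lineage
# resolution is nominal).
species_tree_from_config <- function(n_taxa, t_split, t_internal, t_root) {
  ladder <- function(tips, heights) {
    # heights: split heights, length(tips) - 1, increasing
    s <- tips[1]
    h_prev <- 0
    if (length(tips) == 1L) return(list(str = s, h = 0))
    for (j in seq_along(heights)) {
      s <- sprintf("(%s:%.8f,%s:%.8f)", s, heights[j] - h_prev,
                   tips[j + 1], heights[j])
      h_prev <- heights[j]
    }
    list(str = s, h = h_prev)
  }
  clade <- function(lin, k) {
    tips <- paste0(lin, "_", seq_len(k))
    hs <- if (k > 1) t_split * seq_len(k - 1) / (2 * k) else numeric(0)
    ladder(tips, hs)
  }
  c1 <- clade("L1", n_taxa[1]); c2 <- clade("L2", n_taxa[2])
  c3 <- clade("L3", n_taxa[3])
  t12 <- t_split; t123 <- t_split + t_internal; troot <- t123 + t_root
  nwk <- sprintf("(((%s:%.8f,%s:%.8f):%.8f,%s:%.8f):%.8f,OUT:%.8f);",
                 c1$str, t12 - c1$h, c2$str, t12 - c2$h, t123 - t12,
                 c3$str, t123 - c3$h, troot - t123, troot)
  parse_newick(nwk)
}
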