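#' Build a lineage map
#'
#' Assigns every taxon to one of the three ingroup lineages (`L1`, `L2`, `L3`)
#' or the outgroup (`OUT`). In the nematode-trapping-fungi setting L1, L2, L3
#' play the roles of *Arthrobotrys*, *Dactylellina* and *Drechslerella*, with
#' a single outgroup taxon, but any three-lineage radiation fits.
#'
#' @param taxon,lineage Character vectors of equal length; `lineage` values
#'   must be `"L1"`, `"L2"`, `"L3"` or `"OUT"`.
#' @param display_names Optional named character vector mapping labels to
#'   display names (e.g. `c(L1 = "Arthrobotrys")`).
#' @return A tibble of class `"lineage_map"` with columns `taxon`, `lineage`.
#' @export
lineage_map <- function(taxon, lineage, display_names = NULL) {
  stopifnot(length(taxon) == length(lineage))
  lineage <- as.character(lineage)
  bad <- setdiff(unique(lineage), c("L1", "L2", "L3", "OUT"))
  if (length(bad))
    stop("unknown lineage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(taxon))
    stop("taxon appears twice: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "),
         call. = FALSE)
  for (lab in c("L1", "L2", "L3", "OUT"))
    if (!any(lineage == lab))
      stop("lineage ", lab, " has no taxon", call. = FALSE)
  out <- tibble::tibble(taxon = as.character(taxon), lineage = lineage)
  class(out) <- c("lineage_map", class(out))
  attr(out, "display_names") <- display_names
  out
}

#' Read a lineage map from TSV
#'
#' Two columns, `taxon<TAB>label`, labels in `L1|L2|L3|OUT`; `#` comment lines
#' of the form `# L1=DisplayName` set display names.
#'
#' @param path File path.
#' @return A `"lineage_map"` tibble.
#' @export
read_lineage_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  com <- lines[startsWith(lines, "#")]
  dn <- NULL
  m <- regmatches(com, regexec("#\\s*(L[123]|OUT)\\s*=\\s*(\\S+)", com))
  m <- m[lengths(m) == 3]
  if (length(m)) dn <- stats::setNames(vapply(m, `[[`, "", 3),
                                       vapply(m, `[[`, "", 2))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("lineage map lines must be 'taxon<TAB>label'", call. = FALSE)
  lineage_map(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2),
              display_names = dn)
}

#' @export
write_lineage_map <- function(lm, path) {
  dn <- attr(lm, "display_names")
  lines <- character(0)
  if (!is.null(dn))
    lines <- sprintf("# %s=%s", names(dn), dn)
  lines <- c(lines, paste(lm$taxon, lm$lineage, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

lineage_taxa <- function(lm, label) lm$taxon[lm$lineage %in% label]

#' Root a tree on the outgroup
#'
#' Re-roots on the outgroup taxon's edge (or the MRCA edge of several
#' outgroup taxa). Returns `NULL` when the outgroup is not monophyletic and
#' the tree therefore cannot be outgroup-rooted.
#' @keywords internal
root_on_outgroup <- function(tree, lm) {
  out <- lineage_taxa(lm, "OUT")
  res <- tryCatch(
    ape::root(tree, outgroup = out, resolve.root = TRUE),
    error = function(e) NULL
  )
  # ape::root leaves NA on the edge created when resolving the new root
  if (!is.null(res) && !is.null(res$edge.length))
    res$edge.length[is.na(res$edge.length)] <- 0
  res
}

#' Classify a gene tree against the three-lineage backbone
#'
#' Re-roots the tree on the outgroup, checks each ingroup lineage for
#' monophyly, and returns which pair of lineages is sister: `"TREE1"` for
#' ((L1,L2),L3) — the species-tree backbone — `"TREE2"` for ((L1,L3),L2),
#' `"TREE3"` for ((L2,L3),L1), and `"UNCLASSIFIED"` when any lineage is
#' non-monophyletic or the backbone is a polytomy. Deterministic, and
#' invariant to child ordering and branch lengths.
#'
#' @param tree A `"phylo"` object whose leaf set equals the lineage map's
#'   taxon set.
#' @param lm A [lineage_map()].
#' @return One of `"TREE1"`, `"TREE2"`, `"TREE3"`, `"UNCLASSIFIED"`.
#' @examples
#' lm <- lineage_map(c("a1", "a2", "d1", "d2", "r1", "r2", "out"),
#'                   c("L1", "L1", "L2", "L2", "L3", "L3", "OUT"))
#' classify_topology(parse_newick("((((a1,a2),(d1,d2)),(r1,r2)),out);"), lm)
#' @export
classify_topology <- function(tree, lm) {
  check_leafset(tree, lm)
  tree <- root_on_outgroup(tree, lm)
  if (is.null(tree)) return("UNCLASSIFIED")
  sides <- lapply(c("L1", "L2", "L3"), function(lab) lineage_taxa(lm, lab))
  mono <- vapply(sides, function(tx) {
    length(tx) == 1L || ape::is.monophyletic(tree, tx)
  }, logical(1))
  if (!all(mono)) return("UNCLASSIFIED")
  ingroup <- unlist(sides)
  node1 <- mrca_node(tree, ingroup)
  pair_mrcas <- c(
    pair12 = mrca_node(tree, c(sides[[1]], sides[[2]])),
    pair13 = mrca_node(tree, c(sides[[1]], sides[[3]])),
    pair23 = mrca_node(tree, c(sides[[2]], sides[[3]]))
  )
  sister <- names(pair_mrcas)[pair_mrcas != node1]
  if (length(sister) != 1L) return("UNCLASSIFIED")  # backbone polytomy
  switch(sister, pair12 = "TREE1", pair13 = "TREE2", pair23 = "TREE3")
}

check_leafset <- function(tree, lm) {
  miss_tree <- setdiff(lm$taxon, tree$tip.label)
  miss_map <- setdiff(tree$tip.label, lm$taxon)
  if (length(miss_tree) || length(miss_map))
    stop("taxon set mismatch; missing from tree: [",
         paste(miss_tree, collapse = ", "), "], missing from map: [",
         paste(miss_map, collapse = ", "), "]", call. = FALSE)
  invisible(TRUE)
}

#' Divergence branch length (node1 to node2)
#'
#' Path length between the ingroup ancestor (node1, the MRCA of all ingroup
#' taxa) and the next divergence node (node2, the MRCA of the two sister
#' lineages' taxa) — the branch whose duration controls how much incomplete
#' lineage sorting the radiation experienced. Defined only for classified
#' trees.
#'
#' @inheritParams classify_topology
#' @param class Optional precomputed [classify_topology()] result.
#' @return Non-negative number.
#' @export
divergence_branch_length <- function(tree, lm, class = NULL) {
  if (is.null(class)) class <- classify_topology(tree, lm)
  if (class == "UNCLASSIFIED")
    stop("divergence branch length undefined for UNCLASSIFIED trees",
         call. = FALSE)
  tree <- root_on_outgroup(tree, lm)
  sides <- lapply(c("L1", "L2", "L3"), function(lab) lineage_taxa(lm, lab))
  pair <- switch(class,
                 TREE1 = c(sides[[1]], sides[[2]]),
                 TREE2 = c(sides[[1]], sides[[3]]),
                 TREE3 = c(sides[[2]], sides[[3]]))
  node1 <- mrca_node(tree, unlist(sides))
  node2 <- mrca_node(tree, pair)
  depths <- ape::node.depth.edgelength(tree)
  unname(depths[node2] - depths[node1])
}

#' Evolutionary rate of a gene tree
#'
#' Total tree length divided by the number of leaves (`method = "mean"`), or
#' the total tree length itself (`method = "total"`). A branch-length-derived
#' rate proxy in substitutions per site.
#'
#' @inheritParams write_newick
#' @param method `"mean"` (default) or `"total"`.
#' @return Non-negative number.
#' @export
evolutionary_rate <- function(tree, method = c("mean", "total")) {
  method <- match.arg(method)
  tot <- total_tree_length(tree)
  if (method == "total") tot else tot / ape::Ntip(tree)
}

#' Cross-strategy consistency filter
#'
#' A gene passes when the trees inferred under the two alignment/trimming
#' strategies have identical unrooted topologies (RF distance zero). A gene
#' with only one tree passes and is marked single-strategy.
#'
#' @param tree_a,tree_b `"phylo"` objects; `tree_b` may be `NULL`.
#' @return Logical flag with attribute `single_strategy`.
#' @export
filter_consistent <- function(tree_a, tree_b = NULL) {
  if (is.null(tree_b)) {
    res <- TRUE
    attr(res, "single_strategy") <- TRUE
    return(res)
  }
  res <- rf_distance(tree_a, tree_b) == 0L
  attr(res, "single_strategy") <- FALSE
  res
}

#' Bootstrap support filter
#'
#' A tree passes when its support statistic is at least `threshold`
#' (boundary kept). The statistic defaults to the mean over internal nodes.
#'
#' @inheritParams node_supports
#' @param threshold Support threshold in \[0, 100\]; default 80.
#' @param statistic `"mean"`, `"median"` or `"min"`.
#' @return Logical flag.
#' @export
filter_support <- function(tree, threshold = 80,
                           statistic = c("mean", "median", "min")) {
  statistic <- match.arg(statistic)
  sup <- node_supports(tree)
  sup[find_root(tree) - ape::Ntip(tree)] <- NA_real_
  if (all(is.na(sup)))
    stop("tree carries no node supports", call. = FALSE)
  stat <- switch(statistic,
                 mean = mean(sup, na.rm = TRUE),
                 median = stats::median(sup, na.rm = TRUE),
                 min = min(sup, na.rm = TRUE))
  stat >= threshold
}

#' Per-gene filtering, classification and branch-length statistics
#'
#' The per-gene record builder: applies the cross-strategy consistency filter
#' and the bootstrap-support filter, classifies each retained tree against
#' the three-lineage backbone, and computes the divergence branch length,
#' cumulative (total) branch length and evolutionary rate. Filters are
#' sequential: a gene removed as inconsistent is not also counted as
#' low-support, mirroring the accounting chain input = inconsistent +
#' low-support + retained.
#'
#' @param trees_a Named list of `"phylo"` gene trees (strategy A).
#' @param trees_b Optional named list for strategy B; matched to `trees_a`
#'   by name.
#' @param lm A [lineage_map()].
#' @param support_threshold,support_statistic Passed to [filter_support()];
#'   set `support_threshold = NULL` to skip the support filter (e.g. for
#'   trees without supports).
#' @param rate_method Passed to [evolutionary_rate()].
#' @return A tibble with one row per gene: `gene_id`, `consistent`,
#'   `single_strategy`, `mean_support`, `passes_support`, `retained`,
#'   `class`, `divergence_branch_length` (NA for unretained/unclassified),
#'   `cumulative_length`, `evolutionary_rate`.
#' @export
classify_gene_trees <- function(trees_a, trees_b = NULL, lm,
                                support_threshold = 80,
                                support_statistic = "mean",
                                rate_method = "mean") {
  stopifnot(is.list(trees_a), length(trees_a) >= 1L)
  ids <- names(trees_a)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(trees_a))
  purrr::map_dfr(seq_along(trees_a), function(i) {
    ta <- trees_a[[i]]
    tb <- if (!is.null(trees_b)) trees_b[[ids[i]]] else NULL
    cons <- filter_consistent(ta, tb)
    ms <- tryCatch(mean_support(ta), error = function(e) NA_real_)
    pass_sup <- if (is.null(support_threshold)) {
      NA
    } else if (is.na(ms)) {
      NA
    } else {
      filter_support(ta, threshold = support_threshold,
                     statistic = support_statistic)
    }
    retained <- isTRUE(cons) && !isFALSE(pass_sup)
    cls <- if (retained) classify_topology(ta, lm) else NA_character_
    dbl <- if (retained && cls %in% c("TREE1", "TREE2", "TREE3")) {
      divergence_branch_length(ta, lm, class = cls)
    } else NA_real_
    tibble::tibble(
      gene_id = ids[i],
      consistent = as.logical(cons),
      single_strategy = attr(cons, "single_strategy"),
      mean_support = ms,
      passes_support = pass_sup,
      retained = retained,
      class = cls,
      divergence_branch_length = dbl,
      cumulative_length = total_tree_length(ta),
      evolutionary_rate = evolutionary_rate(ta, method = rate_method)
    )
  })
}

#' Classification summary
#'
#' Counts and proportions per topology class over retained gene trees, plus
#' the filter accounting (input = removed-inconsistent + removed-low-support
#' + retained).
#'
#' @param records Output of [classify_gene_trees()].
#' @return A list of class `"classification_summary"` with tibbles `classes`
#'   (`class`, `n`, `proportion`) and `filters` (`stage`, `n`).
#' @export
classification_summary <- function(records) {
  if (!nrow(records)) stop("no gene records", call. = FALSE)
  n_input <- nrow(records)
  n_incons <- sum(!records$consistent)
  n_lowsup <- sum(records$consistent & !records$retained)
  kept <- dplyr::filter(records, .data$retained)
  classes <- kept |>
    dplyr::count(class = factor(.data$class,
                                levels = c("TREE1", "TREE2", "TREE3",
                                           "UNCLASSIFIED")),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n),
                  class = as.character(class))
  filters <- tibble::tibble(
    stage = c("input", "removed_inconsistent", "removed_low_support",
              "retained"),
    n = c(n_input, n_incons, n_lowsup, nrow(kept))
  )
  structure(list(classes = classes, filters = filters),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("Gene-tree classification summary\n")
  print(x$filters)
  print(x$classes)
  invisible(x)
}

#' @export
tidy.classification_summary <- function(x, ...) x$classes

#' @export
glance.classification_summary <- function(x, ...) {
  f <- stats::setNames(as.list(x$filters$n), x$filters$stage)
  tibble::as_tibble(f)
}

#' Pairwise Welch t-tests between groups
#'
#' Compares a numeric value (e.g. divergence branch length or cumulative
#' length) between topology classes with two-sided Welch (unequal variance)
#' t-tests on every pair of groups. Pairs with fewer than two observations
#' in a group are skipped with a warning.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) holding the numeric value and
#'   the grouping variable.
#' @param conf_level Confidence level for the group-difference interval.
#' @return A tibble with one row per group pair: group names, sizes, means,
#'   `statistic`, `df`, `p_value`, `conf_low`, `conf_high`.
#' @export
compare_groups <- function(data, value, group, conf_level = 0.95) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  if (is.character(v) && length(v) == 1L && v %in% names(data))
    v <- data[[v]]
  g <- rlang::eval_tidy(group, data)
  if (is.character(g) && length(g) == 1L && g %in% names(data))
    g <- data[[g]]
  g <- as.character(g)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  levels <- sort(unique(g))
  if (length(levels) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    x <- v[g == p[1]]; y <- v[g == p[2]]
    if (length(x) < 2L || length(y) < 2L) {
      warning("skipping ", p[1], " vs ", p[2], ": group with n < 2",
              call. = FALSE)
      return(tibble::tibble())
    }
    tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
    tibble::tibble(
      group1 = p[1], group2 = p[2],
      n1 = length(x), n2 = length(y),
      mean1 = mean(x), mean2 = mean(y),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      conf_low = tt$conf.int[1],
      conf_high = tt$conf.int[2]
    )
  })
}
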