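#' Gene concordance factors
#'
#' For every internal branch of the species tree, the gene concordance factor
#' (gCF) is the percentage of decisive gene trees whose topology contains that
#' branch. A gene tree is decisive for a branch when, after restricting the
#' branch's bipartition to the gene tree's taxa, both sides retain at least
#' two taxa; it is concordant when the restricted bipartition occurs in the
#' gene tree. Branches with gCF above the highlight threshold (strictly
#' greater; default 60) are flagged, matching the convention of colouring
#' well-supported nodes.
#'
#' @param species_tree A `"phylo"` object.
#' @param gene_trees List of `"phylo"` objects; each leaf set must be a
#'   subset of the species tree's.
#' @param highlight_threshold gCF percentage above which `highlight` is set.
#' @return A tibble with one row per internal species-tree branch: `key`
#'   (canonical split string), `side` (list of character vectors),
#'   `n_decisive`, `n_concordant`, `gcf` (percent, NA when no tree is
#'   decisive), `highlight`.
#' @export
gene_concordance_factors <- function(species_tree, gene_trees,
                                     highlight_threshold = 60) {
  stopifnot(inherits(species_tree, "phylo"), is.list(gene_trees))
  sp_taxa <- species_tree$tip.label
  extra <- unique(unlist(lapply(gene_trees, function(g)
    setdiff(g$tip.label, sp_taxa))))
  if (length(extra))
    stop("gene-tree taxa absent from species tree: ",
         paste(extra, collapse = ", "), call. = FALSE)
  sp <- bipartitions(species_tree)
  gene_keysets <- lapply(gene_trees, bipartition_keys)
  gene_taxa <- lapply(gene_trees, function(g) g$tip.label)
  res <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    side <- sp$side[[i]]
    n_dec <- 0L; n_con <- 0L
    for (j in seq_along(gene_trees)) {
      gt <- gene_taxa[[j]]
      a <- intersect(side, gt)
      b <- setdiff(gt, a)
      if (length(a) < 2L || length(b) < 2L) next
      n_dec <- n_dec + 1L
      if (split_key(a, gt) %in% gene_keysets[[j]]) n_con <- n_con + 1L
    }
    tibble::tibble(key = sp$key[i], side = list(side),
                   n_decisive = n_dec, n_concordant = n_con)
  })
  res |>
    dplyr::mutate(
      gcf = ifelse(.data$n_decisive > 0,
                   100 * .data$n_concordant / .data$n_decisive, NA_real_),
      highlight = !is.na(.data$gcf) & .data$gcf > highlight_threshold
    )
}

#' Annotate a species tree with gCF node labels
#'
#' Writes each internal branch's gCF (rounded to one decimal) onto the node
#' labels of the species tree, the form in which concordance is usually
#' displayed on a phylogeny.
#'
#' @inheritParams gene_concordance_factors
#' @param gcf Output of [gene_concordance_factors()].
#' @return The species tree with gCF values as `node.label`.
#' @export
gcf_annotated_tree <- function(species_tree, gcf) {
  n <- ape::Ntip(species_tree)
  taxa <- species_tree$tip.label
  labels <- rep("", species_tree$Nnode)
  # recover which internal node produced each key
  keymap <- stats::setNames(gcf$gcf, gcf$key)
  for (nd in seq_len(species_tree$Nnode)) {
    tips <- taxa[unlist(tip_descendants(species_tree, n + nd))]
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      k <- split_key(tips, taxa)
      if (k %in% names(keymap) && !is.na(keymap[[k]]))
        labels[nd] <- formatC(keymap[[k]], format = "f", digits = 1)
    }
  }
  species_tree$node.label <- labels
  species_tree
}

# Tip indices below a node (own stack-based traversal).
tip_descendants <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  out
}

#' Pairwise Robinson-Foulds distance matrix
#'
#' @param trees Named list of `"phylo"` objects sharing one leaf set (e.g.
#'   gene trees plus the species tree).
#' @return A symmetric integer matrix with zero diagonal and the trees' names
#'   as dimnames.
#' @export
rf_matrix <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 2L)
  nm <- names(trees)
  if (is.null(nm)) nm <- sprintf("tree_%03d", seq_along(trees))
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("leaf set of tree ", nm[i], " differs from the first tree",
           call. = FALSE)
  }
  keys <- lapply(trees, bipartition_keys)
  m <- length(trees)
  d <- matrix(0L, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      dij <- length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `k` Euclidean dimensions by double-centering
#' the squared distances and eigendecomposing (the Torgerson procedure, via
#' [stats::cmdscale()]). Axes are ordered by eigenvalue; dimensions with
#' non-positive eigenvalues are dropped (RF distances are not Euclidean, so
#' negative eigenvalues can occur and are reported). For determinism each
#' axis is reflected so that its largest-magnitude coordinate is positive.
#'
#' @param dist A square symmetric non-negative matrix with zero diagonal.
#' @param k Number of dimensions requested (default 2).
#' @return An object of class `"phylo_mds"`: a list with `points` (tibble of
#'   `label`, `MDS1`, `MDS2`, ...) and `eigenvalues` (all eigenvalues,
#'   descending).
#' @export
classical_mds <- function(dist, k = 2) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || !isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be square and symmetric", call. = FALSE)
  if (any(dist < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(diag(dist)) > 1e-12))
    stop("distance matrix must have zero diagonal", call. = FALSE)
  stopifnot(k >= 1)
  n <- nrow(dist)
  fit <- suppressWarnings(stats::cmdscale(dist, k = min(k, n - 1),
                                          eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  n_pos <- sum(fit$eig > 1e-9)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " dimension(s)", call. = FALSE)
  }
  keep <- seq_len(max(min(k, n_pos), 1L))
  pts <- if (ncol(fit$points) >= length(keep)) {
    fit$points[, keep, drop = FALSE]
  } else {
    matrix(0, n, length(keep))
  }
  if (n_pos == 0L) pts[] <- 0
  # deterministic sign: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  labels <- rownames(dist)
  if (is.null(labels)) labels <- sprintf("item_%03d", seq_len(n))
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  points <- dplyr::bind_cols(tibble::tibble(label = labels),
                             tibble::as_tibble(pts))
  structure(list(points = points, eigenvalues = eig), class = "phylo_mds")
}

#' @export
print.phylo_mds <- function(x, ...) {
  cat("Classical MDS embedding (", ncol(x$points) - 1L, " dimensions, ",
      nrow(x$points), " points)\n", sep = "")
  print(x$points, n = 6)
  invisible(x)
}

#' @export
tidy.phylo_mds <- function(x, ...) x$points

#' @export
glance.phylo_mds <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble::tibble(
    n_points = nrow(x$points),
    n_dimensions = ncol(x$points) - 1L,
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    prop_variance_2d = sum(pos[seq_len(min(2, length(pos)))]) / sum(pos)
  )
}

#' RF distances + MDS of gene trees against the species tree
#'
#' Convenience wrapper: computes the pairwise Robinson-Foulds matrix over the
#' gene trees and the species tree, embeds it with [classical_mds()], and
#' marks the species tree's row — the coordinates behind an "MDS cloud of
#' gene trees around the species tree" figure.
#'
#' @inheritParams gene_concordance_factors
#' @param k Embedding dimensions.
#' @return A tibble: `label`, `MDS1`, ..., `is_species_tree`; the full
#'   `"phylo_mds"` object is attached as attribute `"mds"`.
#' @export
rf_mds <- function(gene_trees, species_tree, k = 2) {
  trees <- c(gene_trees, list(species_tree = species_tree))
  d <- rf_matrix(trees)
  mds <- classical_mds(d, k = k)
  out <- dplyr::mutate(mds$points,
                       is_species_tree = .data$label == "species_tree")
  attr(out, "mds") <- mds
  out
}
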