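#' Parse a Newick tree
#'
#' Reads a single rooted Newick statement into an [ape::read.tree()] `"phylo"`
#' object and validates it: leaf labels must be unique and non-empty, branch
#' lengths non-negative. By convention (the IQ-TREE default) internal-node
#' labels that parse as numbers in \[0, 100\] are interpreted as bootstrap
#' supports; see [node_supports()].
#'
#' @param text A Newick string ending in `";"`.
#' @param supports_from_labels Interpret numeric internal-node labels as
#'   supports (the default). Setting this to `FALSE` only affects accessors
#'   such as [mean_support()] via the attribute recorded on the tree; the
#'   labels themselves are always kept verbatim.
#' @param support_split Optional character on which composite labels such as
#'   `"87.2/95"` are split before the support field is extracted.
#' @param support_field Which field of a split label holds the support
#'   (default 1).
#' @return A `"phylo"` object.
#' @examples
#' tr <- parse_newick("((a:1,b:2)95:0.5,c:3);")
#' node_supports(tr)
#' @seealso [write_newick()], [node_supports()]
#' @export
parse_newick <- function(text, supports_from_labels = TRUE,
                         support_split = NULL, support_field = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string", call. = FALSE)
  validate_phylo(tree)
  attr(tree, "support_dialect") <- list(
    enabled = isTRUE(supports_from_labels),
    split = support_split, field = as.integer(support_field)
  )
  tree
}

# Cheap structural pre-check so malformed input gets an error with a character
# offset instead of whatever ape makes of it.
check_newick_syntax <- function(text) {
  if (!nzchar(text) || substring(text, nchar(text)) != ";")
    stop("Newick string must end in ';'", call. = FALSE)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at character %d", i), call. = FALSE)
    }
  }
  if (quoted) stop("unterminated quote in Newick string", call. = FALSE)
  if (depth != 0L)
    stop(sprintf("unbalanced '(' (depth %d at end of string)", depth),
         call. = FALSE)
  invisible(TRUE)
}

validate_phylo <- function(tree) {
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length", call. = FALSE)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad))
    stop("support outside [0, 100]: ", paste(sup[bad], collapse = ", "),
         call. = FALSE)
  invisible(tree)
}

#' Write a tree as Newick
#'
#' Serializes with up to 10 significant digits on branch lengths so that
#' parse/write round-trips preserve topology, lengths and supports.
#'
#' @param tree A `"phylo"` object.
#' @param include_supports Keep internal-node labels (supports) in the output.
#' @return A Newick string.
#' @export
write_newick <- function(tree, include_supports = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!include_supports) tree$node.label <- NULL
  ape::write.tree(tree, digits = 10)
}

#' Node supports of a tree
#'
#' Internal-node labels that parse as numbers in \[0, 100\] are returned as
#' supports; others (including the root label, by position one) give `NA`.
#'
#' @inheritParams write_newick
#' @param split,field Dialect for composite labels (e.g. `"sh-aLRT/ufboot"`):
#'   labels are split on `split` and field `field` is used. Defaults come from
#'   the dialect recorded by [parse_newick()], else no splitting.
#' @return Numeric vector of length `tree$Nnode` (ordered as
#'   `tree$node.label`), `NA` where no support is present.
#' @export
node_supports <- function(tree, split = NULL, field = NULL) {
  stopifnot(inherits(tree, "phylo"))
  dialect <- attr(tree, "support_dialect")
  if (is.null(split) && !is.null(dialect)) split <- dialect$split
  if (is.null(field)) field <- if (!is.null(dialect)) dialect$field else 1L
  labs <- tree$node.label
  if (is.null(labs)) return(rep(NA_real_, tree$Nnode))
  if (!is.null(dialect) && !isTRUE(dialect$enabled))
    return(rep(NA_real_, tree$Nnode))
  if (!is.null(split))
    labs <- vapply(strsplit(labs, split, fixed = TRUE), function(x) {
      if (length(x) >= field) x[[field]] else NA_character_
    }, character(1))
  sup <- suppressWarnings(as.numeric(labs))
  sup[!is.na(sup) & (sup < 0 | sup > 100)] <- NA_real_
  sup
}

#' Mean bootstrap support
#'
#' Arithmetic mean of the supports on internal nodes, excluding the root.
#' Errors when the tree carries no supports at all (such a tree cannot be
#' support-filtered).
#'
#' @inheritParams node_supports
#' @return A number in \[0, 100\].
#' @export
mean_support <- function(tree, split = NULL, field = NULL) {
  sup <- node_supports(tree, split = split, field = field)
  root <- find_root(tree) - ape::Ntip(tree)
  sup[root] <- NA_real_
  if (all(is.na(sup)))
    stop("tree carries no node supports", call. = FALSE)
  mean(sup, na.rm = TRUE)
}

find_root <- function(tree) {
  # the node that never appears as a child
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# --- bipartitions ------------------------------------------------------------

# Canonical key of one side of a split over `taxa`: the side NOT containing
# the reference taxon (alphabetically first), sorted and collapsed.
split_key <- function(side, taxa, ref = min(taxa)) {
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "\x1f")
}

# Character keys of all non-trivial splits of the unrooted topology.
# Own postorder accumulation; ape::prop.part stays free for use as an
# independent oracle in the tests.
bipartition_keys <- function(tree) {
  n <- ape::Ntip(tree)
  taxa <- tree$tip.label
  if (n < 4L) return(character(0))
  ref <- min(taxa)
  edge <- tree$edge
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- taxa[i]
  # accumulate descendant sets bottom-up; repeated passes keep it free of any
  # assumption about edge ordering
  done <- c(rep(TRUE, n), rep(FALSE, tree$Nnode))
  parents <- edge[, 1]; children <- edge[, 2]
  while (!all(done)) {
    for (nd in which(!done)) {
      ch <- children[parents == nd]
      if (all(done[ch])) {
        desc[[nd]] <- unlist(desc[ch], use.names = FALSE)
        done[nd] <- TRUE
      }
    }
  }
  root <- find_root(tree)
  keys <- character(0)
  for (nd in setdiff((n + 1L):nn, root)) {
    side <- desc[[nd]]
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, split_key(side, taxa, ref))
  }
  unique(keys)
}

#' Non-trivial bipartitions of a tree
#'
#' One row per internal edge of the unrooted topology; the `side` column holds
#' the taxa on the canonical side of the split (the side not containing the
#' alphabetically first taxon). Trees with fewer than four leaves have no
#' non-trivial splits and yield zero rows.
#'
#' @inheritParams write_newick
#' @return A tibble with columns `key` (canonical string), `side` (list of
#'   character vectors) and `size`.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  keys <- bipartition_keys(tree)
  sides <- strsplit(keys, "\x1f", fixed = TRUE)
  tibble::tibble(
    key = keys,
    side = sides,
    size = lengths(sides)
  )
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the bipartition sets of two trees
#' on the same leaf set; 0 iff the unrooted topologies are identical.
#'
#' @param t1,t2 `"phylo"` objects sharing one leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) || length(only2))
    stop("leaf sets differ; only in first: [",
         paste(only1, collapse = ", "), "], only in second: [",
         paste(only2, collapse = ", "), "]", call. = FALSE)
  b1 <- bipartition_keys(t1)
  b2 <- bipartition_keys(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Canonical topology identifier
#'
#' Two trees get the same id iff they share the same unrooted topology;
#' branch lengths and supports are ignored.
#'
#' @inheritParams write_newick
#' @return A string.
#' @export
topology_id <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  keys <- sort(bipartition_keys(tree))
  paste(c(paste(sort(tree$tip.label), collapse = "\x1f"), keys),
        collapse = "\x1e")
}

#' Most recent common ancestor
#'
#' @inheritParams write_newick
#' @param taxa Non-empty subset of the leaf labels.
#' @return The ape node number (a tip number for a singleton set).
#' @export
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1L)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Total tree length
#'
#' Sum of all branch lengths. Errors when any branch length is missing.
#'
#' @inheritParams write_newick
#' @return Non-negative number.
#' @export
total_tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  miss <- which(is.na(tree$edge.length))
  if (length(miss))
    stop("missing branch length on edge(s) to node(s): ",
         paste(tree$edge[miss, 2], collapse = ", "), call. = FALSE)
  sum(tree$edge.length)
}

#' Read gene trees from a file
#'
#' One Newick statement per line. Lines may optionally carry a gene id as
#' `"id<TAB>newick"`; bare files fall back to `gene_0001`-style ids in line
#' order (with a message, since pairing across strategy files then relies on
#' order).
#'
#' @param path File path.
#' @param ... Passed to [parse_newick()].
#' @return A named list of `"phylo"` objects.
#' @export
read_gene_trees <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no trees in ", path, call. = FALSE)
  has_id <- grepl("\t", lines, fixed = TRUE)
  if (all(has_id)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[[`, character(1), 1L)
    nwk <- vapply(parts, `[[`, character(1), 2L)
  } else {
    if (any(has_id))
      stop("mixed id-prefixed and bare Newick lines in ", path, call. = FALSE)
    ids <- sprintf("gene_%04d", seq_along(lines))
    nwk <- lines
    message("no gene ids in ", basename(path), "; using line order")
  }
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, call. = FALSE)
  trees <- lapply(nwk, parse_newick, ...)
  names(trees) <- ids
  trees
}

#' Write gene trees to a file
#'
#' Inverse of [read_gene_trees()]: one `"id<TAB>newick"` line per tree.
#'
#' @param trees Named list of `"phylo"` objects.
#' @param path File path.
#' @param include_supports Keep node supports.
#' @export
write_gene_trees <- function(trees, path, include_supports = TRUE) {
  stopifnot(is.list(trees), !is.null(names(trees)))
  lines <- vapply(seq_along(trees), function(i) {
    paste0(names(trees)[i], "\t",
           write_newick(trees[[i]], include_supports = include_supports))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
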