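#' Read a pipeline configuration
#'
#' YAML file (or a named list) with paths and stage parameters. Recognized
#' fields: `gene_trees_a`, `gene_trees_b` (optional), `species_tree`,
#' `lineage_map`, `alignment` + `pop_map` (optional), `support_threshold`
#' (default 80), `support_statistic` (`mean`), `quartet_alpha` (default
#' 1e-4), `quartet_trees` (`discordant` or `all`), `test_mode` (`chi2` or
#' `exact`), `jackknife_blocks` (50), `mds_k` (2), `gcf_threshold` (60),
#' `outdir`, `seed`. Unknown fields are ignored.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A config list with defaults filled in.
#' @export
read_pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  defaults <- list(
    gene_trees_b = NULL, alignment = NULL, pop_map = NULL,
    support_threshold = 80, support_statistic = "mean",
    quartet_alpha = 1e-4, quartet_trees = "discordant",
    test_mode = "chi2", jackknife_blocks = 50, mds_k = 2,
    gcf_threshold = 60, outdir = NULL, seed = 1L
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[nm] <- list(defaults[[nm]])
  stopifnot(cfg$quartet_alpha > 0, cfg$quartet_alpha < 1,
            cfg$support_threshold >= 0, cfg$support_threshold <= 100)
  cfg
}

#' Validate pipeline inputs without running the analysis
#'
#' Returns every detectable problem (missing files, unreadable trees,
#' taxon-set mismatches, gene-count differences between strategy files) as a
#' tibble; zero rows means [run_conflict_pipeline()]'s preconditions hold.
#'
#' @param cfg A config (list or YAML path), see [read_pipeline_config()].
#' @return A tibble with columns `stage`, `issue`.
#' @export
validate_inputs <- function(cfg) {
  cfg <- read_pipeline_config(cfg)
  issues <- list()
  add <- function(stage, msg)
    issues[[length(issues) + 1L]] <<- tibble::tibble(stage = stage,
                                                     issue = msg)
  need <- c("gene_trees_a", "species_tree", "lineage_map")
  for (nm in need) {
    if (is.null(cfg[[nm]])) {
      add("paths", paste0("missing required path '", nm, "'"))
    } else if (!file.exists(cfg[[nm]])) {
      add("paths", paste0(nm, " file not found: ", cfg[[nm]]))
    }
  }
  if (nrow_issues(issues) > 0L)
    return(dplyr::bind_rows(issues))
  trees_a <- tryCatch(read_gene_trees(cfg$gene_trees_a),
                      error = function(e) {
                        add("gene_trees_a", conditionMessage(e)); NULL
                      })
  lm <- tryCatch(read_lineage_map(cfg$lineage_map),
                 error = function(e) {
                   add("lineage_map", conditionMessage(e)); NULL
                 })
  sp <- tryCatch(parse_newick(paste(readLines(cfg$species_tree,
                                              warn = FALSE),
                                    collapse = "")),
                 error = function(e) {
                   add("species_tree", conditionMessage(e)); NULL
                 })
  if (!is.null(trees_a) && !is.null(lm)) {
    taxa_trees <- sort(unique(unlist(lapply(trees_a, `[[`, "tip.label"))))
    miss_map <- setdiff(taxa_trees, lm$taxon)
    if (length(miss_map))
      add("lineage_map", paste0("gene-tree taxa missing from lineage map: ",
                                paste(miss_map, collapse = ", ")))
    miss_trees <- setdiff(lm$taxon, taxa_trees)
    if (length(miss_trees))
      add("gene_trees_a", paste0("lineage-map taxa absent from gene trees: ",
                                 paste(miss_trees, collapse = ", ")))
  }
  if (!is.null(sp) && !is.null(lm)) {
    d1 <- setdiff(lm$taxon, sp$tip.label)
    d2 <- setdiff(sp$tip.label, lm$taxon)
    if (length(d1) || length(d2))
      add("species_tree",
          paste0("species tree / lineage map taxon diff; map-only: [",
                 paste(d1, collapse = ", "), "], tree-only: [",
                 paste(d2, collapse = ", "), "]"))
  }
  if (!is.null(cfg$gene_trees_b)) {
    if (!file.exists(cfg$gene_trees_b)) {
      add("gene_trees_b", paste0("file not found: ", cfg$gene_trees_b))
    } else if (!is.null(trees_a)) {
      trees_b <- tryCatch(read_gene_trees(cfg$gene_trees_b),
                          error = function(e) {
                            add("gene_trees_b", conditionMessage(e)); NULL
                          })
      if (!is.null(trees_b) && length(trees_b) != length(trees_a))
        add("gene_trees_b",
            sprintf("gene count differs: %d in strategy A, %d in strategy B",
                    length(trees_a), length(trees_b)))
    }
  }
  if (!is.null(cfg$alignment)) {
    for (nm in c("alignment", "pop_map"))
      if (is.null(cfg[[nm]]) || !file.exists(cfg[[nm]]))
        add("dstat", paste0(nm, " missing or not found"))
  }
  if (nrow_issues(issues) == 0L)
    return(tibble::tibble(stage = character(0), issue = character(0)))
  dplyr::bind_rows(issues)
}

nrow_issues <- function(issues) {
  if (!length(issues)) 0L else sum(vapply(issues, nrow, integer(1)))
}

#' Run the full discordance pipeline
#'
#' Executes, in order: cross-strategy and support filtering with topology
#' classification; gene concordance factors on the species tree; the RF
#' distance matrix and its MDS embedding; the quartet multispecies-coalescent
#' tests; the ABBA-BABA D-statistic (when an alignment is configured); and
#' the divergence/cumulative branch-length group comparisons. Every stage's
#' tables are written to `outdir` (TSV, deterministic) before the next stage
#' begins; the run is reproducible from the config and seed.
#'
#' @param cfg A config (list or YAML path), see [read_pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return An object of class `"conflict_report"`: a list with `records`,
#'   `class_summary`, `gcf`, `mds`, `quartets`, `quartet_summary`, `dstat`
#'   (or NULL), `branch_length_tests`, `filters`, `config`.
#' @export
run_conflict_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- read_pipeline_config(cfg)
  issues <- validate_inputs(cfg)
  if (nrow(issues))
    stop("invalid inputs:\n",
         paste0("  [", issues$stage, "] ", issues$issue, collapse = "\n"),
         call. = FALSE)
  say <- function(...) if (!quiet) message("[phyloconflict] ", ...)
  set.seed(cfg$seed)
  outdir <- cfg$outdir
  emit <- function(tbl, name) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      readr::write_tsv(tbl, file.path(outdir, paste0(name, ".tsv")))
    }
  }
  trees_a <- read_gene_trees(cfg$gene_trees_a)
  trees_b <- if (!is.null(cfg$gene_trees_b))
    read_gene_trees(cfg$gene_trees_b) else NULL
  lm <- read_lineage_map(cfg$lineage_map)
  sp <- parse_newick(paste(readLines(cfg$species_tree, warn = FALSE),
                           collapse = ""))

  say("classifying ", length(trees_a), " gene trees")
  has_support <- any(!is.na(node_supports(trees_a[[1]])))
  records <- classify_gene_trees(
    trees_a, trees_b, lm,
    support_threshold = if (has_support) cfg$support_threshold else NULL,
    support_statistic = cfg$support_statistic
  )
  summ <- classification_summary(records)
  if (!sum(records$retained))
    stop("no gene trees retained after filtering (",
         paste(summ$filters$stage, summ$filters$n, sep = "=",
               collapse = ", "), ")", call. = FALSE)
  emit(dplyr::mutate(records, single_strategy = NULL), "gene_records")
  emit(summ$classes, "class_summary")
  emit(summ$filters, "filter_summary")

  say("gene concordance factors")
  retained_trees <- trees_a[records$gene_id[records$retained]]
  gcf <- gene_concordance_factors(sp, retained_trees,
                                  highlight_threshold = cfg$gcf_threshold)
  emit(dplyr::mutate(gcf, side = vapply(side, paste, "", collapse = ",")),
       "gcf")
  if (!is.null(outdir))
    writeLines(write_newick(gcf_annotated_tree(sp, gcf)),
               file.path(outdir, "species_tree_gcf.nwk"))

  say("RF matrix and MDS")
  mds_tbl <- rf_mds(retained_trees, sp, k = cfg$mds_k)
  emit(mds_tbl, "mds_coordinates")
  if (!is.null(outdir)) {
    d <- rf_matrix(c(retained_trees, list(species_tree = sp)))
    utils::write.table(d, file.path(outdir, "rf_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }

  say("quartet MSC tests")
  qtrees <- if (identical(cfg$quartet_trees, "all")) {
    retained_trees
  } else {
    disc <- records$gene_id[records$retained & records$class != "TREE1"]
    trees_a[disc]
  }
  quartets <- quartet_analysis(qtrees, lm, alpha = cfg$quartet_alpha,
                               mode = cfg$test_mode)
  qsumm <- quartet_summary(quartets)
  emit(quartets, "quartets")
  emit(qsumm, "quartet_summary")

  dst <- NULL
  if (!is.null(cfg$alignment)) {
    say("ABBA-BABA D statistic")
    ga <- read_grouped_alignment(cfg$alignment, cfg$pop_map)
    dst <- abba_baba(ga, n_blocks = cfg$jackknife_blocks)
    emit(tidy(dst), "dstat")
  } else {
    say("no alignment configured; skipping D statistic")
  }

  say("branch-length comparisons")
  classified <- dplyr::filter(records, !is.na(.data$class))
  try_compare <- function(value_col) {
    out <- tryCatch(
      compare_groups(classified, value_col, "class"),
      error = function(e) tibble::tibble()
    )
    if (nrow(out)) dplyr::mutate(out, value = value_col, .before = 1) else out
  }
  blt <- dplyr::bind_rows(try_compare("divergence_branch_length"),
                          try_compare("cumulative_length"))
  emit(blt, "branch_length_tests")

  report <- structure(list(
    records = records, class_summary = summ$classes, gcf = gcf,
    mds = mds_tbl, quartets = quartets, quartet_summary = qsumm,
    dstat = dst, branch_length_tests = blt, filters = summ$filters,
    config = cfg
  ), class = "conflict_report")
  if (!is.null(outdir)) {
    yaml::write_yaml(
      list(package_version = as.character(utils::packageVersion("phyloconflict")),
           seed = cfg$seed,
           config = cfg[!vapply(cfg, is.null, logical(1))],
           filters = stats::setNames(as.list(summ$filters$n),
                                     summ$filters$stage)),
      file.path(outdir, "run_report.yml"))
  }
  report
}

#' @export
print.conflict_report <- function(x, ...) {
  cat("Phylogenetic conflict report\n")
  f <- x$filters
  cat(sprintf("  genes: %d input, %d inconsistent, %d low support, %d retained\n",
              f$n[1], f$n[2], f$n[3], f$n[4]))
  cs <- x$class_summary
  cat("  classes: ",
      paste(sprintf("%s %d (%.1f%%)", cs$class, cs$n, 100 * cs$proportion),
            collapse = ", "), "\n", sep = "")
  qs <- x$quartet_summary
  cat("  quartets: ",
      paste(sprintf("%s %.1f%%", qs$verdict, 100 * qs$fraction),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$dstat))
    cat(sprintf("  D = %.4f, Z = %.3f (%d informative sites)\n",
                x$dstat$D, x$dstat$Z, x$dstat$n_informative_sites))
  invisible(x)
}

#' @export
glance.conflict_report <- function(x, ...) {
  f <- stats::setNames(as.list(x$filters$n), x$filters$stage)
  qs <- x$quartet_summary
  tibble::tibble(
    n_input = f$input, n_retained = f$retained,
    prop_tree1 = x$class_summary$proportion[x$class_summary$class == "TREE1"],
    prop_quartets_ils = qs$fraction[qs$verdict == "ILS_consistent"],
    D = if (is.null(x$dstat)) NA_real_ else x$dstat$D,
    Z = if (is.null(x$dstat)) NA_real_ else x$dstat$Z
  )
}
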