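#' Enumerate four-taxon sets with a fixed outgroup
#'
#' All `choose(n, 3)` unordered triples of ingroup taxa, each paired with the
#' fixed outgroup, in deterministic sorted order. With the study design of 23
#' ingroup taxa this yields 1,771 quartets.
#'
#' @param taxa Character vector of ingroup taxa (at least 3).
#' @param outgroup Single outgroup taxon, not among `taxa`.
#' @return A tibble with columns `t1`, `t2`, `t3` (sorted within and across
#'   rows) and `outgroup`.
#' @export
enumerate_quartets <- function(taxa, outgroup) {
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 3L) stop("need at least 3 ingroup taxa", call. = FALSE)
  if (outgroup %in% taxa) stop("outgroup must not be an ingroup taxon",
                               call. = FALSE)
  m <- utils::combn(taxa, 3)
  tibble::tibble(t1 = m[1, ], t2 = m[2, ], t3 = m[3, ],
                 outgroup = outgroup)
}

# Sister pair of one tree restricted to {t1,t2,t3,outgroup}:
# "pair12"/"pair13"/"pair23" keyed by sorted ingroup taxa, "unresolved" for a
# star quartet, NA when a quartet taxon is missing from the tree.
quartet_class_one <- function(tree, trio, outgroup) {
  four <- c(trio, outgroup)
  if (!all(four %in% tree$tip.label)) return(NA_character_)
  sub <- if (ape::Ntip(tree) > 4L) {
    ape::keep.tip(tree, four)
  } else {
    tree
  }
  keys <- bipartition_keys(sub)
  if (!length(keys)) return("unresolved")
  side <- strsplit(keys[1], "\x1f", fixed = TRUE)[[1]]
  pair <- if (outgroup %in% side) setdiff(four, side) else side
  ing <- sort(trio)
  idx <- sort(match(pair, ing))
  paste0("pair", idx[1], idx[2])
}

#' Quartet topology counts over gene trees
#'
#' Restricts each gene tree to the four quartet taxa and tallies which
#' ingroup pair appears as sister (i.e. on the opposite side of the internal
#' edge from the outgroup). Star quartets are excluded from the counts and
#' tallied as unresolved; trees lacking a quartet taxon are skipped.
#'
#' @param gene_trees List of `"phylo"` objects.
#' @param trio Character vector of the three ingroup taxa.
#' @param outgroup The outgroup taxon.
#' @return A one-row tibble: `n1`, `n2`, `n3` (counts keyed `pair12`,
#'   `pair13`, `pair23` on the sorted ingroup taxa), `n_total`,
#'   `n_unresolved`, `n_skipped`.
#' @export
quartet_counts <- function(gene_trees, trio, outgroup) {
  stopifnot(length(trio) == 3L, length(outgroup) == 1L)
  cls <- vapply(gene_trees, quartet_class_one, character(1),
                trio = trio, outgroup = outgroup)
  tibble::tibble(
    n1 = sum(cls == "pair12", na.rm = TRUE),
    n2 = sum(cls == "pair13", na.rm = TRUE),
    n3 = sum(cls == "pair23", na.rm = TRUE),
    n_unresolved = sum(cls == "unresolved", na.rm = TRUE),
    n_skipped = sum(is.na(cls))
  ) |>
    dplyr::mutate(n_total = .data$n1 + .data$n2 + .data$n3,
                  .after = "n3")
}

#' Multispecies-coalescent quartet test
#'
#' Tests the ILS-only null for one quartet's topology counts. Under the
#' multispecies coalescent the two minor (discordant) topologies are
#' equiprobable, so with minor counts m1 and m2 the statistic
#' `X^2 = (m1 - m2)^2 / (m1 + m2)` is chi-square with one degree of freedom
#' under the null (`mode = "chi2"`); `mode = "exact"` uses the two-sided
#' binomial test of m1 successes in m1 + m2 trials at p = 1/2. When both
#' minors are zero the data cannot reject (p = 1). Ties for the major
#' topology are resolved conservatively: each admissible major choice is
#' tested and the largest p-value reported.
#'
#' @param n1,n2,n3 Topology counts (see [quartet_counts()]).
#' @param alpha Significance level (default 1e-4, the study convention).
#' @param mode `"chi2"` or `"exact"`.
#' @return A one-row tibble: `statistic` (NA in exact mode), `p_value`,
#'   `verdict` (`"ILS_consistent"`, `"rejected"` or `"undetermined"`).
#' @examples
#' msc_test(60, 30, 0)  # X^2 = 30, rejected at alpha = 1e-4
#' @export
msc_test <- function(n1, n2, n3, alpha = 1e-4, mode = c("chi2", "exact")) {
  mode <- match.arg(mode)
  counts <- c(n1, n2, n3)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0)
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          verdict = "undetermined"))
  majors <- which(counts == max(counts))
  one <- function(major) {
    minors <- counts[-major]
    m1 <- minors[1]; m2 <- minors[2]
    if (m1 + m2 == 0)
      return(list(statistic = 0, p_value = 1))
    if (mode == "chi2") {
      x2 <- (m1 - m2)^2 / (m1 + m2)
      list(statistic = x2,
           p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
    } else {
      bt <- stats::binom.test(m1, m1 + m2, p = 0.5)
      list(statistic = NA_real_, p_value = bt$p.value)
    }
  }
  res <- lapply(majors, one)
  best <- res[[which.max(vapply(res, `[[`, numeric(1), "p_value"))]]
  tibble::tibble(
    statistic = best$statistic,
    p_value = best$p_value,
    verdict = ifelse(best$p_value < alpha, "rejected", "ILS_consistent")
  )
}

#' Barycentric simplex coordinates of quartet proportions
#'
#' Places the topology proportions inside an equilateral reference triangle
#' with vertices v1 = (0, 0), v2 = (1, 0), v3 = (1/2, sqrt(3)/2) keyed to
#' `pair12`, `pair13`, `pair23`; equal counts map to the centroid.
#'
#' @inheritParams msc_test
#' @return A one-row tibble with `x`, `y` (NA when all counts are zero).
#' @export
simplex_coords <- function(n1, n2, n3) {
  tot <- n1 + n2 + n3
  if (tot == 0) return(tibble::tibble(x = NA_real_, y = NA_real_))
  w <- c(n1, n2, n3) / tot
  vx <- c(0, 1, 0.5)
  vy <- c(0, 0, sqrt(3) / 2)
  tibble::tibble(x = sum(w * vx), y = sum(w * vy))
}

#' Quartet MSC analysis over all four-taxon sets
#'
#' Enumerates quartets from a lineage map (outgroup fixed, every ingroup
#' triple), counts gene-tree quartet topologies and applies [msc_test()] to
#' each. The gene-tree set is configurable: the study design feeds only the
#' trees discordant with the species tree.
#'
#' @param gene_trees Named list of `"phylo"` objects.
#' @param lm A [lineage_map()] (ingroup = L1/L2/L3 taxa, outgroup = OUT).
#' @param alpha Significance level.
#' @param mode Test mode, see [msc_test()].
#' @param p_adjust Optional multiple-testing correction across quartets
#'   (`"none"`, `"bonferroni"`, `"holm"`); default none, matching per-quartet
#'   verdicts at fixed alpha.
#' @return A tibble with one row per quartet: taxa, counts, `statistic`,
#'   `p_value`, `verdict`, simplex `x`, `y`.
#' @export
quartet_analysis <- function(gene_trees, lm, alpha = 1e-4,
                             mode = c("chi2", "exact"),
                             p_adjust = c("none", "bonferroni", "holm")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  ingroup <- lineage_taxa(lm, c("L1", "L2", "L3"))
  outg <- lineage_taxa(lm, "OUT")[1]
  qs <- enumerate_quartets(ingroup, outg)
  res <- purrr::map_dfr(seq_len(nrow(qs)), function(i) {
    trio <- c(qs$t1[i], qs$t2[i], qs$t3[i])
    cnt <- quartet_counts(gene_trees, trio, qs$outgroup[i])
    dplyr::bind_cols(
      qs[i, ], cnt,
      msc_test(cnt$n1, cnt$n2, cnt$n3, alpha = alpha, mode = mode),
      simplex_coords(cnt$n1, cnt$n2, cnt$n3)
    )
  })
  if (p_adjust != "none") {
    res <- res |>
      dplyr::mutate(
        p_value = stats::p.adjust(.data$p_value, method = p_adjust),
        verdict = dplyr::case_when(
          .data$verdict == "undetermined" ~ "undetermined",
          .data$p_value < alpha ~ "rejected",
          TRUE ~ "ILS_consistent"
        )
      )
  }
  res
}

#' Summary of quartet verdicts
#'
#' Fractions of quartets whose topology counts are consistent with the
#' ILS-only null, reject it, or are undetermined; the headline
#' "share of four-taxon scenarios explained by ILS".
#'
#' @param results Output of [quartet_analysis()].
#' @return A tibble: `verdict`, `n`, `fraction` (fractions sum to 1).
#' @export
quartet_summary <- function(results) {
  if (!nrow(results)) stop("no quartet results", call. = FALSE)
  results |>
    dplyr::count(verdict = factor(.data$verdict,
                                  levels = c("ILS_consistent", "rejected",
                                             "undetermined")),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  verdict = as.character(.data$verdict))
}
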