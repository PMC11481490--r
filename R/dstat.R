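#' Grouped alignment
#'
#' An aligned set of sequences with each sequence assigned to population
#' `P1`, `P2`, `P3` or `O` (outgroup) — the input of the ABBA-BABA test. In
#' the nematode-trapping-fungi design P1 = *Arthrobotrys*, P2 =
#' *Dactylellina*, P3 = *Drechslerella* and O the outgroup.
#'
#' @param seqs Character matrix (rows = sequences with rownames, columns =
#'   aligned sites) over `A,C,G,T` plus gap/ambiguity codes, or a named
#'   character vector of equal-length strings.
#' @param populations Named character vector mapping sequence name to
#'   `"P1"|"P2"|"P3"|"O"`.
#' @return An object of class `"grouped_alignment"`.
#' @export
grouped_alignment <- function(seqs, populations) {
  if (!is.matrix(seqs)) {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    if (length(unique(nchar(seqs))) != 1L)
      stop("sequences differ in length", call. = FALSE)
    nm <- names(seqs)
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- nm
  }
  seqs[] <- toupper(seqs)
  if (is.null(rownames(seqs))) stop("sequences must be named", call. = FALSE)
  pops <- populations[rownames(seqs)]
  if (any(is.na(pops)))
    stop("no population for sequence(s): ",
         paste(rownames(seqs)[is.na(pops)], collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(pops), c("P1", "P2", "P3", "O"))
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (p in c("P1", "P2", "P3", "O"))
    if (!any(pops == p)) stop("population ", p, " is empty", call. = FALSE)
  structure(list(seqs = seqs, populations = pops),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("Grouped alignment: ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " sites\n", sep = "")
  print(table(x$populations))
  invisible(x)
}

#' Read a grouped alignment from FASTA + population map
#'
#' @param fasta Path to an aligned FASTA file.
#' @param popmap Path to a two-column TSV `sequence<TAB>P1|P2|P3|O`.
#' @return A [grouped_alignment()].
#' @export
read_grouped_alignment <- function(fasta, popmap) {
  dna <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.matrix(dna)
  pm <- readLines(popmap, warn = FALSE)
  pm <- pm[nzchar(trimws(pm)) & !startsWith(pm, "#")]
  parts <- strsplit(pm, "\t", fixed = TRUE)
  pops <- stats::setNames(vapply(parts, `[[`, "", 2),
                          vapply(parts, `[[`, "", 1))
  grouped_alignment(seqs, pops)
}

#' Write a grouped alignment
#'
#' @param ga A [grouped_alignment()].
#' @param fasta,popmap Output paths.
#' @export
write_grouped_alignment <- function(ga, fasta, popmap) {
  dna <- Biostrings::DNAStringSet(apply(ga$seqs, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(dna, fasta)
  writeLines(paste(names(ga$populations), ga$populations, sep = "\t"),
             popmap)
  invisible(fasta)
}

#' Per-site ABBA/BABA weights
#'
#' Polarizes each site by the outgroup and computes frequency-weighted
#' ABBA/BABA pattern weights. A site is informative when the outgroup is
#' monomorphic and unambiguous, the site is biallelic across non-missing
#' bases, and every ingroup population has at least one called base. With
#' derived-allele frequencies p1, p2, p3 in P1-P3 the weights are
#' `ABBA = (1 - p1) * p2 * p3` and `BABA = p1 * (1 - p2) * p3`; with one
#' sequence per population these reduce to 0/1 indicators of the classic
#' ABBA and BABA patterns (P2 and P3, resp. P1 and P3, sharing the derived
#' allele).
#'
#' @param ga A [grouped_alignment()].
#' @param region Optional half-open 0-based site range `c(start, end)`
#'   restricting the alignment.
#' @return A tibble with one row per site: `site`, `informative`, `abba`,
#'   `baba` (weights are 0 at non-informative sites).
#' @export
count_patterns <- function(ga, region = NULL) {
  stopifnot(inherits(ga, "grouped_alignment"))
  m <- ga$seqs
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 0, region[2] <= ncol(m))
    m <- m[, (region[1] + 1L):region[2], drop = FALSE]
  }
  pops <- ga$populations
  acgt <- c("A", "C", "G", "T")
  L <- ncol(m)
  called <- matrix(m %in% acgt, nrow = nrow(m))
  o_rows <- which(pops == "O")
  anc <- m[o_rows[1], ]
  ok_out <- called[o_rows[1], ]
  if (length(o_rows) > 1L)
    for (r in o_rows[-1]) ok_out <- ok_out & called[r, ] & m[r, ] == anc
  # allele presence per base across all called sequences
  pres <- vapply(acgt, function(b) colSums(m == b & called) > 0, logical(L))
  if (!is.matrix(pres)) pres <- matrix(pres, nrow = L, dimnames = list(NULL, acgt))
  n_alleles <- rowSums(pres)                     # pres is L x 4
  biallelic <- n_alleles == 2L
  # derived allele: the non-ancestral one of the two
  derived <- rep(NA_character_, L)
  for (b in acgt) {
    pick <- biallelic & ok_out & pres[, b] & anc != b
    derived[pick] <- b
  }
  freq <- function(pop) {
    rows <- which(pops == pop)
    der <- colSums(matrix(
      m[rows, , drop = FALSE] == rep(derived, each = length(rows)) &
        called[rows, , drop = FALSE], nrow = length(rows)))
    nm <- colSums(called[rows, , drop = FALSE])
    list(p = ifelse(nm > 0, der / nm, NA_real_), n = nm)
  }
  f1 <- freq("P1"); f2 <- freq("P2"); f3 <- freq("P3")
  informative <- ok_out & biallelic & !is.na(derived) &
    f1$n > 0 & f2$n > 0 & f3$n > 0
  abba <- ifelse(informative, (1 - f1$p) * f2$p * f3$p, 0)
  baba <- ifelse(informative, f1$p * (1 - f2$p) * f3$p, 0)
  abba[is.na(abba)] <- 0
  baba[is.na(baba)] <- 0
  tibble::tibble(site = seq_len(L), informative = informative,
                 abba = abba, baba = baba)
}

#' D statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; `NA` with a message when the
#' denominator is zero.
#'
#' @param abba_sum,baba_sum Summed pattern weights.
#' @return A number in \[-1, 1\], or `NA`.
#' @export
d_statistic <- function(abba_sum, baba_sum) {
  denom <- abba_sum + baba_sum
  if (denom <= 0) {
    message("no informative ABBA/BABA signal; D undefined")
    return(NA_real_)
  }
  (abba_sum - baba_sum) / denom
}

#' Block-jackknife D statistic and Z score
#'
#' Splits the sites into contiguous equal-size blocks, recomputes D leaving
#' each block out, and derives the delete-one jackknife standard error
#' `SE^2 = ((m - 1)/m) * sum_i (D_(-i) - mean(D_(-i)))^2` and `Z = D / SE`.
#' The block resampling makes the standard error robust to linkage between
#' nearby sites. When fewer informative sites than blocks are available the
#' block count is reduced with a warning; when all leave-one-out values
#' coincide the SE is zero and Z is flagged undefined.
#'
#' @param weights Per-site weights from [count_patterns()].
#' @param n_blocks Number of contiguous blocks (default 50).
#' @return A one-row tibble of class `"dstat_result"`: `abba_sum`,
#'   `baba_sum`, `D`, `n_blocks`, `block_size_sites`, `jackknife_SE`, `Z`,
#'   `n_informative_sites`, `significant` (|Z| >= 3 convention).
#' @export
jackknife_z <- function(weights, n_blocks = 50) {
  stopifnot(is.data.frame(weights),
            all(c("abba", "baba", "informative") %in% names(weights)))
  L <- nrow(weights)
  n_inf <- sum(weights$informative)
  if (n_inf < n_blocks) {
    n_blocks <- max(2L, n_inf)
    warning("fewer informative sites than blocks; reduced to ", n_blocks,
            " blocks", call. = FALSE)
  }
  abba_sum <- sum(weights$abba)
  baba_sum <- sum(weights$baba)
  D <- d_statistic(abba_sum, baba_sum)
  block <- pmin(ceiling(seq_len(L) / (L / n_blocks)), n_blocks)
  a_blk <- as.numeric(rowsum(weights$abba, block))
  b_blk <- as.numeric(rowsum(weights$baba, block))
  m <- length(a_blk)
  d_loo <- (abba_sum - a_blk - (baba_sum - b_blk)) /
    (abba_sum - a_blk + baba_sum - b_blk)
  se <- if (anyNA(d_loo) || is.na(D)) {
    NA_real_
  } else {
    sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))
  }
  z <- if (is.na(se) || se == 0) NA_real_ else D / se
  if (!is.na(se) && se == 0)
    warning("jackknife SE is zero; Z undefined", call. = FALSE)
  out <- tibble::tibble(
    abba_sum = abba_sum, baba_sum = baba_sum, D = D,
    n_blocks = m, block_size_sites = ceiling(L / m),
    jackknife_SE = se, Z = z,
    n_informative_sites = n_inf,
    significant = !is.na(z) & abs(z) >= 3
  )
  class(out) <- c("dstat_result", class(out))
  out
}

#' ABBA-BABA test on a grouped alignment
#'
#' End-to-end D-statistic: per-site pattern weights, genome-wide D, and the
#' block-jackknife Z score.
#'
#' @inheritParams count_patterns
#' @inheritParams jackknife_z
#' @return A `"dstat_result"` tibble, see [jackknife_z()].
#' @examples
#' \dontrun{
#' ga <- simulate_site_patterns(10000, gamma = 0.3, seed = 1)
#' abba_baba(ga)
#' }
#' @export
abba_baba <- function(ga, n_blocks = 50, region = NULL) {
  w <- count_patterns(ga, region = region)
  jackknife_z(w, n_blocks = n_blocks)
}

#' @export
tidy.dstat_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.dstat_result <- function(x, ...) {
  tibble::tibble(D = x$D, Z = x$Z, n_informative_sites = x$n_informative_sites,
                 significant = x$significant)
}
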