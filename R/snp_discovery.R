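# SNP discovery: classify alignment columns, screen indels and ambiguous
# base calls, and compute SNP counts and densities.
#
# A column is usable for genotyping only when every selected accession has
# a confident diploid call: any gap makes the column an In/Del candidate,
# any 'N' or 3-base code (impossible for a diploid consensus) makes it
# ambiguous, and both are excluded from the SNP set for that comparison.

#' Classify the columns of one marker alignment
#'
#' For the selected accessions every column is assigned to exactly one of
#' four classes: `indel` (any `-`), `ambiguous` (any `N`/`B`/`D`/`H`/`V`;
#' gap takes precedence), `snp` (union of expanded IUB states across
#' accessions has two or more bases) or `monomorphic`. The four counts
#' always sum to the aligned length.
#'
#' @param marker A `marker_alignment` (element of an `snp_dataset`).
#' @param accessions Accession ids to consider (default: all in the
#'   marker). Exclusion is subset-wide: one ambiguous call in one selected
#'   accession removes the column for this comparison.
#' @param maf_filter If `TRUE`, additionally require the most common
#'   allele to have frequency below `maf_threshold` (computed from diploid
#'   allele counts). Off by default: clonally propagated cultivar panels
#'   are not population samples, so every variable site counts. Filtered
#'   sites are tallied as monomorphic in the audit.
#' @param maf_threshold Most-common-allele frequency cutoff used when
#'   `maf_filter` is `TRUE`.
#' @return A list with `sites` (list of `snp_site` objects: `marker_name`,
#'   0-based `position`, per-accession `states`, `allele_set`,
#'   `het_accessions`) and `audit` (named integer vector `monomorphic`,
#'   `snp`, `indel`, `ambiguous`).
#' @export
classify_columns <- function(marker, accessions = NULL, maf_filter = FALSE,
                             maf_threshold = 0.95) {
  stopifnot(inherits(marker, "marker_alignment"))
  seqs <- marker$sequences
  if (!is.null(accessions)) {
    if (length(accessions) == 0) {
      stop("empty accession subset")
    }
    absent <- setdiff(accessions, names(seqs))
    if (length(absent) > 0) {
      stop("marker '", marker$marker_name, "': accession(s) not in ",
           "alignment: ", paste(absent, collapse = ", "))
    }
    seqs <- seqs[accessions]
  }
  M <- seq_matrix(seqs)
  n <- nrow(M)
  L <- ncol(M)

  gap_col <- colSums(M == "-") > 0
  amb_col <- !gap_col &
    colSums(matrix(M %in% AMBIGUOUS_CODES, nrow = n)) > 0
  clean <- !gap_col & !amb_col

  pres <- vapply(BASES, function(b) {
    colSums(matrix(M %in% SYMS_WITH_BASE[[b]], nrow = n)) > 0
  }, logical(L))
  if (L == 1L) pres <- matrix(pres, nrow = 1L)  # vapply drops to vector
  allele_n <- rowSums(pres)

  snp_col <- clean & allele_n >= 2

  if (maf_filter && any(snp_col)) {
    counts <- vapply(BASES, function(b) {
      2 * colSums(matrix(M == b, nrow = n)) +
        colSums(matrix(M %in% intersect(HET_CODES, SYMS_WITH_BASE[[b]]),
                       nrow = n))
    }, numeric(L))
    if (L == 1L) counts <- matrix(counts, nrow = 1L)
    max_freq <- apply(counts, 1, max) / (2 * n)
    snp_col <- snp_col & max_freq < maf_threshold
  }

  sites <- lapply(which(snp_col), function(j) {
    states <- M[, j]
    structure(
      list(marker_name = marker$marker_name,
           position = j - 1L,
           states = states,
           allele_set = sort(unique(unlist(IUB_CODES[states],
                                           use.names = FALSE))),
           het_accessions = names(states)[states %in% HET_CODES]),
      class = "snp_site"
    )
  })

  audit <- c(monomorphic = sum(clean & !snp_col),
             snp = sum(snp_col),
             indel = sum(gap_col),
             ambiguous = sum(amb_col))
  stopifnot(sum(audit) == L)
  list(sites = sites, audit = audit)
}

#' Discover SNPs across all markers of a dataset
#'
#' Runs [classify_columns()] on every marker (in marker order) for one
#' accession scope and aggregates sites, the per-marker audit and the
#' overall SNP density.
#'
#' @inheritParams classify_columns
#' @param dataset An `snp_dataset`.
#' @return An object of class `snp_discovery`: `sites` (ordered list of
#'   `snp_site`), `audit` (per-marker data frame whose four class counts
#'   sum to the aligned length), `n_snps`, `total_length`, and `density`
#'   (an [snp_density()] object for the combined target).
#' @export
discover_snps <- function(dataset, accessions = NULL, maf_filter = FALSE,
                          maf_threshold = 0.95) {
  stopifnot(inherits(dataset, "snp_dataset"))
  per_marker <- lapply(dataset$markers[dataset$marker_order],
                       classify_columns, accessions = accessions,
                       maf_filter = maf_filter,
                       maf_threshold = maf_threshold)
  audit <- do.call(rbind, lapply(seq_along(per_marker), function(i) {
    m <- dataset$markers[[dataset$marker_order[i]]]
    data.frame(marker = m$marker_name,
               aligned_length = m$aligned_length,
               t(per_marker[[i]]$audit))
  }))
  sites <- unlist(lapply(per_marker, `[[`, "sites"), recursive = FALSE)
  total_length <- sum(audit$aligned_length)
  structure(
    list(sites = sites,
         audit = audit,
         n_snps = length(sites),
         total_length = total_length,
         density = snp_density(length(sites), total_length,
                               label = "Combined")),
    class = "snp_discovery"
  )
}

#' @export
print.snp_discovery <- function(x, ...) {
  cat("snp_discovery:", x$n_snps, "SNP site(s) over", x$total_length,
      "bp")
  if (!is.na(x$density$bp_per_snp)) {
    cat(" (1 SNP/", format(x$density$bp_per_snp, nsmall = 2), " bp)",
        sep = "")
  }
  cat("\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}

#' SNP density (bp per SNP)
#'
#' The published convention reports marker informativeness as "1 SNP per
#' so-many nucleotides": the aligned length divided by the SNP count,
#' rounded half-up to two decimals. Zero SNPs yields an undefined density
#' (`NA`), which is distinct from a density of zero.
#'
#' @param n_snps Number of SNPs (non-negative integer).
#' @param length_bp Aligned target length in bp (positive).
#' @param label Optional label (marker name or "Combined").
#' @return An object of class `snp_density` with fields `label`, `n_snps`,
#'   `length_bp`, `bp_per_snp`.
#' @examples
#' snp_density(29, 919)$bp_per_snp   # 31.69
#' snp_density(96, 3317)$bp_per_snp  # 34.55
#' @export
snp_density <- function(n_snps, length_bp, label = NULL) {
  if (length(n_snps) != 1 || length(length_bp) != 1 ||
      is.na(n_snps) || is.na(length_bp) || n_snps < 0 || length_bp <= 0) {
    stop("n_snps must be >= 0 and length_bp > 0")
  }
  structure(
    list(label = label,
         n_snps = as.integer(n_snps),
         length_bp = as.integer(length_bp),
         bp_per_snp = if (n_snps == 0) NA_real_ else
           round_half_up(length_bp / n_snps, 2)),
    class = "snp_density"
  )
}

#' Per-marker SNP density table for one or more accession scopes
#'
#' @param dataset An `snp_dataset`.
#' @param scopes Named list of accession-id vectors (e.g. all accessions
#'   vs. ingroup only); `NULL` entries mean all accessions.
#' @return Data frame with one row per marker (plus "Combined") per scope:
#'   scope, marker, n_snps, length_bp, bp_per_snp.
#' @export
density_table <- function(dataset, scopes = list(all = NULL)) {
  rows <- lapply(names(scopes), function(sc) {
    disc <- discover_snps(dataset, accessions = scopes[[sc]])
    per <- disc$audit
    marker_rows <- data.frame(
      scope = sc, marker = per$marker, n_snps = per$snp,
      length_bp = per$aligned_length,
      bp_per_snp = vapply(seq_len(nrow(per)), function(i) {
        snp_density(max(per$snp[i], 0), per$aligned_length[i])$bp_per_snp
      }, numeric(1)))
    rbind(marker_rows,
          data.frame(scope = sc, marker = "Combined", n_snps = disc$n_snps,
                     length_bp = disc$total_length,
                     bp_per_snp = disc$density$bp_per_snp))
  })
  do.call(rbind, rows)
}
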