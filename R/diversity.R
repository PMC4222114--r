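# Per-subgroup diversity statistics over SNP loci, POPGENE-style.
#
# Allele counts come from 2N chromosomes: a homozygous call contributes
# two copies of its base, a heterozygous IUB call one copy of each of its
# two bases. Per locus:
#   na = number of alleles with frequency > 0
#   ne = 1 / sum(p_i^2)               (effective number of alleles)
#   I  = -sum(p_i log p_i)            (Shannon information index)
#   H  = He = 1 - sum(p_i^2)          (Nei gene diversity, no small-sample
#                                      correction)
#   Ho = fraction of heterozygous individuals
#   Fis = 1 - Ho / He                 (only where He > 0)
# Table values are means across all loci; monomorphic loci contribute
# na = 1, ne = 1, I = 0, H = 0, while Fis averages only loci with He > 0.

locus_diversity <- function(states) {
  if (anyNA(states)) {
    stop("missing state(s) at a locus")
  }
  n_ind <- length(states)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in BASES) {
    counts[b] <- 2 * sum(states == b) +
      sum(states %in% intersect(HET_CODES, SYMS_WITH_BASE[[b]]))
  }
  total <- sum(counts)
  stopifnot(total == 2 * n_ind)
  p <- counts / total
  pp <- p[p > 0]
  He <- 1 - sum(p^2)
  Ho <- mean(states %in% HET_CODES)
  list(na = length(pp),
       ne = 1 / sum(p^2),
       I = -sum(pp * log(pp)),
       He = He,
       Ho = Ho,
       Fis = if (He > 0) 1 - Ho / He else NA_real_)
}

#' Diversity statistics for one accession subgroup over SNP loci
#'
#' @param sites List of `snp_site` objects (the valid SNP loci for the
#'   full comparison set, from [discover_snps()]).
#' @param meta Metadata data frame.
#' @param subgroup Subgroup label to summarize, or `NULL` together with
#'   `accessions` for an explicit accession set.
#' @param accessions Optional explicit accession ids (overrides
#'   `subgroup`).
#' @param label Row label; defaults to the subgroup name.
#' @return One-row data frame: `subgroup`, `n_individuals`, `sample_size`
#'   (allele count, 2N), `n_loci`, `n_polymorphic`, `P_pct`, `na`, `ne`,
#'   `I`, `H`, `Ho`, `He`, `Fis`.
#' @export
diversity_stats <- function(sites, meta, subgroup = NULL,
                            accessions = NULL, label = NULL) {
  if (is.null(accessions)) {
    if (is.null(subgroup)) {
      stop("supply 'subgroup' or 'accessions'")
    }
    accessions <- meta$accession_id[meta$subgroup == subgroup]
  }
  if (length(accessions) == 0) {
    stop("empty subgroup")
  }
  if (length(sites) == 0) {
    stop("no SNP loci supplied")
  }
  per <- lapply(sites, function(s) locus_diversity(s$states[accessions]))
  get <- function(f) vapply(per, `[[`, numeric(1), f)
  He <- get("He")
  Fis <- get("Fis")
  data.frame(
    subgroup = label %||% subgroup %||% "custom",
    n_individuals = length(accessions),
    sample_size = 2L * length(accessions),
    n_loci = length(sites),
    n_polymorphic = sum(get("na") >= 2),
    P_pct = 100 * mean(get("na") >= 2),
    na = mean(get("na")),
    ne = mean(get("ne")),
    I = mean(get("I")),
    H = mean(He),
    Ho = mean(get("Ho")),
    He = mean(He),
    Fis = if (all(is.na(Fis))) NA_real_ else mean(Fis, na.rm = TRUE),
    row.names = NULL
  )
}

#' Diversity table over all subgroups plus a total row
#'
#' @param sites List of `snp_site` objects for the full comparison set.
#' @param meta Metadata data frame.
#' @return Data frame, one row per subgroup (in order of appearance) and
#'   a final `Total` row over all accessions with metadata-covered states.
#' @export
diversity_table <- function(sites, meta) {
  subgroups <- unique(meta$subgroup)
  all_acc <- intersect(meta$accession_id, names(sites[[1L]]$states))
  rows <- lapply(subgroups, function(sg) {
    acc <- intersect(meta$accession_id[meta$subgroup == sg], all_acc)
    diversity_stats(sites, meta, accessions = acc, label = sg)
  })
  rows[[length(rows) + 1L]] <-
    diversity_stats(sites, meta, accessions = all_acc, label = "Total")
  do.call(rbind, rows)
}
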