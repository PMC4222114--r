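# Character-based genotyping: concatenate per-site diploid states (IUB
# codes kept unsplit, i.e. unphased) into one genotype string per
# accession, then partition accessions by exact string equality.
#
# 'A' and 'R' are different genotype states even though they share an
# allele: homozygous and heterozygous calls are distinct characters.

#' Build the concatenated multi-marker genotype matrix
#'
#' One character per valid SNP site per accession, ordered by marker order
#' then ascending position. Heterozygous states keep their two-base IUB
#' symbol; nothing is phased or split.
#'
#' @param sites List of `snp_site` objects (from [discover_snps()] run on
#'   the same accession scope; sites must be valid, i.e. re-filtered, for
#'   the chosen subset).
#' @param accessions Accession ids (rows). Defaults to the accessions of
#'   the first site. Required when `sites` is empty.
#' @param marker_order Optional explicit marker order; defaults to order
#'   of first appearance in `sites`.
#' @return An object of class `genotype_profile`: `matrix` (accession x
#'   site character matrix, columns labelled `marker:pos` with 1-based
#'   positions), `sites` (data frame of marker and 0-based position) and
#'   `strings` (named character vector of concatenated genotypes).
#' @export
build_genotype_matrix <- function(sites, accessions = NULL,
                                  marker_order = NULL) {
  if (length(sites) == 0) {
    if (is.null(accessions)) {
      stop("'accessions' is required when 'sites' is empty")
    }
    mat <- matrix(character(0), nrow = length(accessions), ncol = 0,
                  dimnames = list(accessions, NULL))
    return(structure(
      list(matrix = mat,
           sites = data.frame(marker = character(0), position = integer(0)),
           strings = stats::setNames(rep("", length(accessions)),
                                     accessions)),
      class = "genotype_profile"
    ))
  }
  markers <- vapply(sites, `[[`, character(1), "marker_name")
  positions <- vapply(sites, `[[`, integer(1), "position")
  if (is.null(marker_order)) {
    marker_order <- unique(markers)
  }
  ord <- order(match(markers, marker_order), positions)
  sites <- sites[ord]
  markers <- markers[ord]
  positions <- positions[ord]
  if (is.null(accessions)) {
    accessions <- names(sites[[1L]]$states)
  }
  cols <- lapply(seq_along(sites), function(i) {
    st <- sites[[i]]$states[accessions]
    if (anyNA(st)) {
      miss <- accessions[is.na(st)][1L]
      stop("accession '", miss, "' has no state at site ",
           markers[i], ":", positions[i] + 1L,
           " (re-filter sites for this accession subset)")
    }
    unname(st)
  })
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(accessions,
                        paste0(markers, ":", positions + 1L))
  structure(
    list(matrix = mat,
         sites = data.frame(marker = markers, position = positions),
         strings = stats::setNames(apply(mat, 1, paste, collapse = ""),
                                   accessions)),
    class = "genotype_profile"
  )
}

#' Collapse accessions into genotype groups
#'
#' Exact-string-equality partition of the genotype strings. Group ids are
#' assigned by descending size, ties broken by first appearance. The
#' number of groups is the genotype count (Hn) and group sizes are the
#' per-genotype accession numerosities (Nh).
#'
#' @param profile A `genotype_profile` from [build_genotype_matrix()].
#' @return An object of class `genotype_groups`: `groups` (list of
#'   `group_id`, `members`, `size`, `genotype`), `assignment` (named
#'   integer vector accession -> group id) and `n_groups`.
#' @export
collapse_genotypes <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  strings <- profile$strings
  f <- factor(strings, levels = unique(strings))
  members <- split(names(strings), f)
  sizes <- lengths(members)
  ord <- order(-sizes, seq_along(members))
  groups <- lapply(seq_along(ord), function(g) {
    k <- ord[g]
    list(group_id = g, members = members[[k]],
         size = unname(sizes[k]), genotype = levels(f)[k])
  })
  assignment <- integer(length(strings))
  names(assignment) <- names(strings)
  for (g in groups) assignment[g$members] <- g$group_id
  structure(
    list(groups = groups, assignment = assignment,
         n_groups = length(groups)),
    class = "genotype_groups"
  )
}

#' @export
print.genotype_groups <- function(x, ...) {
  cat("genotype_groups:", x$n_groups, "distinct genotype(s) among",
      length(x$assignment), "accession(s)\n")
  sizes <- vapply(x$groups, `[[`, numeric(1), "size")
  cat("  group sizes (Nh):", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Synonymy / homonymy / clone-consistency report
#'
#' Re-derivable from the genotype partition and metadata alone:
#' * synonymy candidates — groups whose members carry two or more distinct
#'   cultivar names (genetically identical material under different names);
#' * homonymy candidates — cultivar names whose accessions fall into two
#'   or more groups (one name on genetically distinct material, including
#'   labeling mistakes);
#' * clone checks — cultivars with multiple accessions, flagged consistent
#'   when all replicates share one genotype group.
#'
#' @param groups A `genotype_groups` object.
#' @param meta Metadata data frame (see [read_metadata()]).
#' @return An object of class `naming_report` with elements `synonymy`
#'   (list of `group_id` + `names`), `homonymy` (list of `cultivar_name` +
#'   `group_ids`) and `clone_checks` (data frame).
#' @export
naming_report <- function(groups, meta) {
  stopifnot(inherits(groups, "genotype_groups"))
  acc <- names(groups$assignment)
  absent <- setdiff(acc, meta$accession_id)
  if (length(absent) > 0) {
    stop("accession(s) lack metadata: ", paste(absent, collapse = ", "))
  }
  name_of <- stats::setNames(meta$cultivar_name, meta$accession_id)

  synonymy <- Filter(Negate(is.null), lapply(groups$groups, function(g) {
    nm <- sort(unique(unname(name_of[g$members])))
    if (length(nm) >= 2) list(group_id = g$group_id, names = nm) else NULL
  }))

  by_name <- split(unname(groups$assignment[acc]), unname(name_of[acc]))
  multi <- Filter(function(v) length(unique(v)) >= 2, by_name)
  homonymy <- lapply(names(multi), function(nm) {
    list(cultivar_name = nm, group_ids = sort(unique(multi[[nm]])))
  })

  reps <- Filter(function(v) length(v) >= 2, by_name)
  clone_checks <- data.frame(
    cultivar_name = names(reps),
    n_accessions = vapply(reps, length, integer(1)),
    n_groups = vapply(reps, function(v) length(unique(v)), integer(1)),
    row.names = NULL
  )
  clone_checks$consistent <- clone_checks$n_groups == 1L

  structure(
    list(synonymy = synonymy, homonymy = homonymy,
         clone_checks = clone_checks),
    class = "naming_report"
  )
}

#' @export
print.naming_report <- function(x, ...) {
  cat("naming_report\n")
  cat("  synonymy candidates:", length(x$synonymy), "\n")
  for (s in x$synonymy) {
    cat("    group", s$group_id, "=", paste(s$names, collapse = " / "), "\n")
  }
  cat("  homonymy candidates:", length(x$homonymy), "\n")
  for (h in x$homonymy) {
    cat("    ", h$cultivar_name, "-> groups",
        paste(h$group_ids, collapse = ", "), "\n")
  }
  n_bad <- sum(!x$clone_checks$consistent)
  cat("  clone checks:", nrow(x$clone_checks), "replicated cultivar(s),",
      n_bad, "inconsistent\n")
  invisible(x)
}

#' Genotype groups differing at exactly one site
#'
#' Near-identical genotype pairs (one substitution apart) are of direct
#' interest for ancestry questions: a local variety one nucleotide away
#' from a reference cultivar is a candidate derived clone or offspring.
#'
#' @param groups A `genotype_groups` object.
#' @param profile The `genotype_profile` the groups were collapsed from.
#' @return Data frame with `group_a`, `group_b` and `site` (the
#'   `marker:pos` label of the single differing site).
#' @export
one_off_pairs <- function(groups, profile) {
  stopifnot(inherits(groups, "genotype_groups"),
            inherits(profile, "genotype_profile"))
  k <- groups$n_groups
  out <- list()
  if (k < 2 || ncol(profile$matrix) == 0) {
    return(data.frame(group_a = integer(0), group_b = integer(0),
                      site = character(0)))
  }
  reps <- do.call(rbind, lapply(groups$groups, function(g) {
    profile$matrix[g$members[1L], , drop = TRUE]
  }))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      diff <- which(reps[i, ] != reps[j, ])
      if (length(diff) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          group_a = i, group_b = j,
          site = colnames(profile$matrix)[diff])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(group_a = integer(0), group_b = integer(0),
                      site = character(0)))
  }
  do.call(rbind, out)
}
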