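# Diagnostic characteristic attributes (CAs).
#
# A CA for a genotype group is a set of (site, state) pairs such that
# every member of the group matches all of them and no accession outside
# the group does ("pure" diagnostics). A single-position CA is
# "pure-simple"; a multi-position one is "compound" and must be minimal
# (no proper subset is itself diagnostic). Because groups are
# exact-string classes, all members share the full genotype string, so
# every site is a candidate position.

new_ca <- function(group_id, profile, idx, category) {
  structure(
    list(group_id = group_id,
         sites = colnames(profile$matrix)[idx],
         positions = profile$sites[idx, , drop = FALSE],
         states = unname(profile$matrix[1L, idx]),  # overwritten below
         category = category,
         site_index = idx),
    class = "character_attribute"
  )
}

#' Find diagnostic characteristic attributes for one genotype group
#'
#' Returns all pure-simple CAs (single sites whose group state occurs in
#' no outside accession). When none exist, minimal compound CAs are found
#' by exhaustive subset search up to `max_exhaustive` positions; beyond
#' that a greedy set-cover heuristic (each position "covers" the outsiders
#' it excludes) is used, followed by subset-deletion pruning so the
#' emitted CA is still minimal. Ties are broken by smaller cardinality,
#' then lexicographically in site order.
#'
#' @param group_id Integer id of the target group.
#' @param groups A `genotype_groups` object (at least two groups).
#' @param profile The `genotype_profile` the groups came from.
#' @param max_exhaustive Largest subset size searched exhaustively
#'   (default 3).
#' @return List of `character_attribute` objects (all pure-simple CAs, or
#'   the minimal compound CAs found at the smallest cardinality).
#' @export
diagnose_group <- function(group_id, groups, profile, max_exhaustive = 3) {
  stopifnot(inherits(groups, "genotype_groups"),
            inherits(profile, "genotype_profile"))
  if (groups$n_groups < 2) {
    stop("diagnosis needs at least two genotype groups")
  }
  g <- NULL
  for (gg in groups$groups) if (gg$group_id == group_id) g <- gg
  if (is.null(g)) {
    stop("no group with id ", group_id)
  }
  S <- ncol(profile$matrix)
  if (S == 0) {
    stop("genotype profile has no sites")
  }
  g_chars <- strsplit(g$genotype, "")[[1L]]
  outsiders <- setdiff(rownames(profile$matrix), g$members)
  n_out <- length(outsiders)
  # M[o, s]: does outsider o match the group state at site s?
  M <- profile$matrix[outsiders, , drop = FALSE] ==
    matrix(g_chars, nrow = n_out, ncol = S, byrow = TRUE)

  make_ca <- function(idx, category) {
    ca <- new_ca(group_id, profile, idx, category)
    ca$states <- g_chars[idx]
    ca
  }

  pure <- which(colSums(M) == 0)
  if (length(pure) > 0) {
    return(lapply(pure, make_ca, category = "pure-simple"))
  }

  max_k <- min(max_exhaustive, S)
  if (max_k >= 2) {
    # size 2: co-match counts; a pair is diagnostic iff no outsider
    # matches both positions
    CC <- crossprod(M * 1L)
    pairs <- which(CC == 0 & upper.tri(CC), arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
      return(lapply(seq_len(nrow(pairs)), function(r) {
        make_ca(as.integer(pairs[r, ]), "compound")
      }))
    }
    if (max_k >= 3) {
      found <- list()
      for (a in seq_len(S - 2)) {
        rows_a <- which(M[, a])
        M2 <- M[rows_a, , drop = FALSE]
        C2 <- crossprod(M2 * 1L)
        cand <- which(C2 == 0 & upper.tri(C2), arr.ind = TRUE)
        cand <- cand[cand[, 1L] > a & cand[, 2L] > a, , drop = FALSE]
        if (nrow(cand) > 0) {
          cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
          for (r in seq_len(nrow(cand))) {
            found[[length(found) + 1L]] <-
              c(a, as.integer(cand[r, ]))
          }
        }
      }
      if (length(found) > 0) {
        return(lapply(found, make_ca, category = "compound"))
      }
    }
    if (max_k >= 4) {
      for (k in seq(4, max_k)) {
        combos <- utils::combn(S, k)
        hits <- list()
        for (ci in seq_len(ncol(combos))) {
          idx <- combos[, ci]
          if (!any(rowSums(M[, idx, drop = FALSE]) == k)) {
            hits[[length(hits) + 1L]] <- idx
          }
        }
        if (length(hits) > 0) {
          return(lapply(hits, make_ca, category = "compound"))
        }
      }
    }
  }

  # Greedy set cover over outsiders, then subset-deletion minimality.
  uncovered <- rep(TRUE, n_out)
  sel <- integer(0)
  while (any(uncovered)) {
    coverage <- colSums(!M[uncovered, , drop = FALSE])
    best <- which.max(coverage)
    if (coverage[best] == 0) {
      stop("internal consistency error: an outsider matches the group ",
           "at every site")  # impossible after collapse
    }
    sel <- c(sel, best)
    uncovered <- uncovered & M[, best]
  }
  sel <- sort(sel)
  repeat {
    dropped <- FALSE
    for (p in sel) {
      cand <- setdiff(sel, p)
      if (length(cand) > 0 &&
          !any(rowSums(M[, cand, drop = FALSE]) == length(cand))) {
        sel <- cand
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  # Greedy covers are minimal (irredundant) but not always minimum;
  # refine with a budgeted exact pass over the cardinalities between the
  # exhaustive cap and the greedy solution so small instances always get
  # the true minimum.
  budget <- 2e5
  for (k in seq_len(length(sel) - 1L)) {
    if (k <= max_k) next  # already searched exhaustively
    if (choose(S, k) > budget) break
    combos <- utils::combn(S, k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      if (!any(rowSums(M[, idx, drop = FALSE]) == k)) {
        return(list(make_ca(idx, "compound")))
      }
    }
  }
  list(make_ca(sel, if (length(sel) == 1L) "pure-simple" else "compound"))
}

#' Verify a characteristic attribute by brute force
#'
#' Re-checks the diagnostic predicate directly against the genotype
#' matrix: every member of the target group matches all (site, state)
#' pairs and no non-member matches all of them.
#'
#' @param ca A `character_attribute`.
#' @param groups The `genotype_groups` object.
#' @param profile The `genotype_profile`.
#' @return `TRUE` or `FALSE`.
#' @export
check_ca <- function(ca, groups, profile) {
  g <- NULL
  for (gg in groups$groups) if (gg$group_id == ca$group_id) g <- gg
  if (is.null(g)) return(FALSE)
  sub <- profile$matrix[, ca$site_index, drop = FALSE]
  match_all <- apply(sub, 1, function(row) all(row == ca$states))
  all(match_all[g$members]) &&
    !any(match_all[setdiff(rownames(sub), g$members)])
}

#' Diagnostic key for every genotype group
#'
#' @param groups A `genotype_groups` object.
#' @param profile The matching `genotype_profile`.
#' @param max_exhaustive Passed to [diagnose_group()].
#' @return Named list (by group id) of CA lists.
#' @export
ca_key <- function(groups, profile, max_exhaustive = 3) {
  stats::setNames(
    lapply(seq_len(groups$n_groups), diagnose_group, groups = groups,
           profile = profile, max_exhaustive = max_exhaustive),
    paste0("group", seq_len(groups$n_groups))
  )
}

#' @export
print.character_attribute <- function(x, ...) {
  cat("CA for group ", x$group_id, " [", x$category, "]: ",
      paste(paste0(x$sites, "=", x$states), collapse = " & "), "\n",
      sep = "")
  invisible(x)
}
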