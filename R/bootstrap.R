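# Nonparametric bootstrap over alignment columns. All columns of the
# concatenated target regions are resampled (not only SNP columns):
# monomorphic columns change nothing topologically but keep resampling
# proportions honest. Support for each internal bipartition of the
# point-estimate NJ tree is the percentage of replicate trees containing
# that bipartition.

#' Bootstrap supports for the NJ tree of a set of consensus sequences
#'
#' Deterministic for a fixed seed. Replicates whose resampled K2P matrix
#' contains an undefined distance are dropped (and counted); supports are
#' percentages over the valid replicates.
#'
#' @param sequences Named character vector of aligned IUB strings (the
#'   concatenated multi-marker alignment).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param root_on Optional leaf labels to root the returned tree on
#'   (supports stay attached to the correct edges).
#' @return A list with `tree` (point-estimate NJ tree, integer percent
#'   supports as node labels), `supports` (integer vector, one per
#'   internal node), `n_valid` and `n_dropped`.
#' @export
bootstrap_supports <- function(sequences, n_reps = 1000, seed = 1,
                               root_on = NULL) {
  if (n_reps < 1) {
    stop("'n_reps' must be >= 1")
  }
  X <- seq_matrix(sequences)
  L <- ncol(X)
  if (L < 2) {
    stop("alignment must have at least two columns to resample")
  }
  Xc <- matrix(encode_acgt(X), nrow = nrow(X))
  rownames(Xc) <- names(sequences)

  point_D <- k2p_matrix_from_codes(Xc, length(sequences))
  dimnames(point_D) <- list(names(sequences), names(sequences))
  point <- nj_tree(point_D)

  idx <- with_seed(seed,
                   matrix(sample.int(L, L * n_reps, replace = TRUE),
                          nrow = n_reps))
  boot_trees <- list()
  n_dropped <- 0L
  for (r in seq_len(n_reps)) {
    Dr <- k2p_matrix_from_codes(Xc[, idx[r, ], drop = FALSE],
                                nrow(Xc))
    if (anyNA(Dr)) {
      n_dropped <- n_dropped + 1L
      next
    }
    dimnames(Dr) <- list(names(sequences), names(sequences))
    boot_trees[[length(boot_trees) + 1L]] <- nj_tree(Dr)
  }
  n_valid <- length(boot_trees)
  if (n_valid == 0) {
    stop("all bootstrap replicates produced undefined distances")
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- as.integer(round(100 * counts / n_valid))
  point$node.label <- as.character(supports)
  if (!is.null(root_on)) {
    point <- ape::root(point, outgroup = root_on, resolve.root = TRUE,
                       edgelabel = TRUE)
  }
  list(tree = point, supports = supports, n_valid = n_valid,
       n_dropped = n_dropped)
}

#' Support for the bipartition separating one leaf set from the rest
#'
#' Convenience accessor: looks up the internal edge whose bipartition is
#' exactly `leaves` vs. everything else in a supported tree and returns
#' its percent support, or `NA` when the split is absent from the tree.
#'
#' @param result A list returned by [bootstrap_supports()].
#' @param leaves Character vector of leaf labels on one side of the split.
#' @return Integer percent support, or `NA` if the tree does not contain
#'   that bipartition.
#' @export
split_support <- function(result, leaves) {
  tree <- result$tree
  tips <- tree$tip.label
  target <- sort(match(leaves, tips))
  if (anyNA(target)) {
    stop("leaf label(s) not in tree: ",
         paste(leaves[is.na(match(leaves, tips))], collapse = ", "))
  }
  other <- sort(setdiff(seq_along(tips), target))
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    clade <- sort(parts[[k]])
    if (identical(clade, target) || identical(clade, other)) {
      return(result$supports[k])
    }
  }
  NA_integer_
}
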