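# Neighbor-joining (Saitou & Nei) with the rate-corrected Q criterion.
#
# NJ is exact on additive distance matrices. Negative estimated branch
# lengths (sampling noise on near-zero edges) are clamped to zero with
# the deficit moved to the sibling edge so path lengths are preserved,
# which is standard practice in distance-tree software.

check_newick_safe <- function(labels) {
  bad <- grepl("[(),:;'\"\\[\\]]|[[:space:]]", labels)
  if (any(bad)) {
    stop("labels contain Newick metacharacters or whitespace: ",
         paste(labels[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (m - 2) d(i,j) - r(i) - r(j) is joined (first minimum in
#' column-major order on ties, so the result is deterministic). Undefined
#' or non-finite distances are refused before construction - a silently
#' substituted distance would corrupt the whole tree.
#'
#' @param D Symmetric distance matrix with labels (or a `dist`).
#' @param root_on Optional character vector of leaf labels to root on
#'   (e.g. the outgroup accessions); default keeps the tree unrooted.
#' @return An `ape` `phylo` tree.
#' @export
nj_tree <- function(D, root_on = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("'D' must be a square matrix")
  }
  n <- nrow(D)
  if (n < 3) {
    stop("need at least three labels to build a tree")
  }
  labs <- rownames(D)
  if (is.null(labs)) {
    stop("'D' must carry row names (accession ids)")
  }
  check_newick_safe(labs)
  if (any(!is.finite(D))) {
    stop("distance matrix contains undefined or non-finite entries; ",
         "refusing to build a tree")
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric")
  }

  d <- D
  strs <- labs
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    if (bi < 0) bi <- 0
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    du <- du[-c(i, j)]
    newstr <- sprintf("(%s:%.17g,%s:%.17g)", strs[i], bi, strs[j], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    strs <- c(strs[keep], newstr)
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 strs[1], b1, strs[2], b2, strs[3], b3)
  tr <- ape::read.tree(text = nwk)
  if (!is.null(root_on)) {
    absent <- setdiff(root_on, tr$tip.label)
    if (length(absent) > 0) {
      stop("root_on label(s) not in tree: ", paste(absent, collapse = ", "))
    }
    tr <- ape::root(tr, outgroup = root_on, resolve.root = TRUE)
  }
  tr
}
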