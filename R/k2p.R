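# Kimura two-parameter (K2P) distances on IUB-coded consensus sequences.
#
# K2P is defined on fixed bases, so any site where either sequence is not
# a plain A/C/G/T (heterozygote codes, N, 3-base codes, gaps) is deleted
# pairwise before counting. Transitions (A<->G, C<->T) and transversions
# are corrected separately:
#   d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
# When a logarithm argument is non-positive (saturation) or no sites
# survive deletion, the distance is flagged undefined rather than
# silently set to zero or infinity.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
IS_PURINE <- c(TRUE, FALSE, TRUE, FALSE)  # A, C, G, T

encode_acgt <- function(chars) {
  unname(BASE_CODE[chars])  # NA for every non-ACGT symbol
}

k2p_from_codes <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) {
    return(list(n_sites_used = 0L, P = NA_real_, Q = NA_real_,
                d = NA_real_, defined = FALSE))
  }
  xs <- x[ok]
  ys <- y[ok]
  diff <- xs != ys
  ti <- sum(diff & (IS_PURINE[xs] == IS_PURINE[ys]))
  tv <- sum(diff) - ti
  P <- ti / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(n_sites_used = n, P = P, Q = Q, d = NA_real_,
                defined = FALSE))
  }
  list(n_sites_used = n, P = P, Q = Q,
       d = -0.5 * log(w1) - 0.25 * log(w2), defined = TRUE)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' @param seq_a,seq_b Aligned IUB strings (or character vectors) of equal
#'   length.
#' @return An object of class `k2p_result`: `n_sites_used` (after
#'   pairwise deletion of non-ACGT sites), transition proportion `P`,
#'   transversion proportion `Q`, distance `d` (substitutions/site, `NA`
#'   when undefined) and `defined`.
#' @examples
#' k2p_distance("ACGT", "ACGT")$d  # 0
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(seq_a, "")[[1L]] else seq_a
  b <- if (length(seq_b) == 1L) strsplit(seq_b, "")[[1L]] else seq_b
  if (length(a) != length(b)) {
    stop("sequences have different lengths (", length(a), " vs ",
         length(b), ")")
  }
  structure(k2p_from_codes(encode_acgt(a), encode_acgt(b)),
            class = "k2p_result")
}

k2p_matrix_from_codes <- function(X, n_labels) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  undef <- 0L
  for (i in seq_len(n - 1)) {
    xi <- X[i, ]
    for (j in seq(i + 1, n)) {
      r <- k2p_from_codes(xi, X[j, ])
      d <- if (r$defined) r$d else NA_real_
      if (!r$defined) undef <- undef + 1L
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  attr(D, "n_undefined") <- undef
  D
}

#' Pairwise K2P distance matrix
#'
#' @param sequences Named character vector of aligned IUB strings (one per
#'   accession).
#' @return Symmetric matrix with zero diagonal; undefined pairs are `NA`
#'   and their count is stored in `attr(, "n_undefined")`.
#' @export
k2p_matrix <- function(sequences) {
  if (length(sequences) < 2) {
    stop("need at least two sequences")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names")
  }
  X <- seq_matrix(sequences)
  Xc <- matrix(encode_acgt(X), nrow = nrow(X))
  D <- k2p_matrix_from_codes(Xc, length(sequences))
  dimnames(D) <- list(names(sequences), names(sequences))
  D
}

#' Within- and between-subgroup distance summaries
#'
#' Mean and standard deviation of pairwise distances over all unordered
#' member pairs (within a subgroup) or all cross pairs (between two
#' subgroups). Undefined (`NA`) pairs are excluded and counted.
#'
#' @param D Distance matrix from [k2p_matrix()] (labels = accession ids).
#' @param meta Metadata data frame.
#' @param group_col Metadata column holding the subgroup label.
#' @return Data frame with `group_a`, `group_b` (equal for within-group
#'   rows), `mean`, `sd`, `n_pairs`, `n_undefined`.
#' @export
group_distance_summary <- function(D, meta, group_col = "subgroup") {
  labels <- rownames(D)
  grp <- meta[[group_col]][match(labels, meta$accession_id)]
  if (anyNA(grp)) {
    stop("accession(s) lack metadata: ",
         paste(labels[is.na(grp)], collapse = ", "))
  }
  levels <- unique(grp)
  rows <- list()
  for (i in seq_along(levels)) {
    for (j in seq(i, length(levels))) {
      a <- labels[grp == levels[i]]
      b <- labels[grp == levels[j]]
      if (i == j) {
        if (length(a) < 2) next
        sub <- D[a, a, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(D[a, b, drop = FALSE])
      }
      ok <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = levels[i], group_b = levels[j],
        mean = if (length(ok) > 0) mean(ok) else NA_real_,
        sd = if (length(ok) >= 2) stats::sd(ok)
             else if (length(ok) == 1) 0 else NA_real_,
        n_pairs = length(vals),
        n_undefined = sum(is.na(vals)))
    }
  }
  do.call(rbind, rows)
}
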