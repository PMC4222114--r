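test_that("K2P closed forms and pairwise deletion behave as defined", {
  r <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
  expect_equal(r$d, 0)
  expect_true(r$defined)

  # 100 bp with exactly 10 transitions: d = -1/2 ln(0.8)
  a <- strsplit(random_acgt(0), "")[[1]]
  a <- rep(c("A", "C"), 50)
  b <- a
  b[seq_len(10)] <- ifelse(a[seq_len(10)] == "A", "G", "T")
  r <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8), tolerance = 1e-12)

  # heterozygote codes are deleted pairwise
  r <- k2p_distance("ACGR", "ACGT")
  expect_equal(r$n_sites_used, 3L)
  expect_equal(r$d, 0)

  expect_error(k2p_distance("ACG", "AC"), "different lengths")

  # saturation is flagged, never silently zeroed
  r <- k2p_distance("AAAA", "CCCC")
  expect_false(r$defined)
  expect_true(is.na(r$d))
  # no overlapping sites: undefined too
  r <- k2p_distance("NNNN", "ACGT")
  expect_false(r$defined)
})

test_that("K2P is symmetric, zero on self, and bounded below by P+Q", {
  set.seed(13)
  for (rep in 1:30) {
    a <- random_acgt(80)
    b <- paste(sample(c("A", "C", "G", "T", "R", "N"), 80, replace = TRUE,
                      prob = c(5, 5, 5, 5, 1, 1)), collapse = "")
    r_ab <- k2p_distance(a, b)
    r_ba <- k2p_distance(b, a)
    expect_identical(r_ab, r_ba)
    expect_equal(k2p_distance(a, a)$d, 0)
    if (r_ab$defined) {
      expect_gte(r_ab$d, r_ab$P + r_ab$Q - 1e-12)
    }
  }
})

test_that("k2p_matrix agrees with ape's K80 distances (independent oracle)", {
  set.seed(17)
  n <- 8; L <- 200
  base <- strsplit(random_acgt(L), "")[[1]]
  seqs <- vapply(1:n, function(i) {
    mut <- sample(L, 12)
    s <- base
    s[mut] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", 1:n)
  D <- k2p_matrix(seqs)
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  D_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(D, D_ape[rownames(D), colnames(D)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cp, D, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NJ recovers additive four-taxon trees exactly", {
  src <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:2):0.25);")
  D <- ape::cophenetic.phylo(src)
  tr <- nj_tree(D)
  cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cp, D, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("NJ agrees with ape::nj on noisy (non-additive) matrices", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr0)
    noise <- matrix(runif(n * n, 0, 0.05), n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dn <- D + noise
    mine <- nj_tree(Dn)
    theirs <- ape::nj(as.dist(Dn))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)),
                 0, ignore_attr = TRUE)
  }
})

test_that("NJ refuses undefined distances and unlabeled input", {
  D <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D), "undefined")
  D2 <- matrix(0, 3, 3)
  expect_error(nj_tree(D2), "row names")
  expect_error(nj_tree(matrix(0, 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "at least three")
})

test_that("rooting on a named outgroup places it basally", {
  src <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1,OG:2);")
  D <- ape::cophenetic.phylo(src)
  tr <- nj_tree(D, root_on = "OG")
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.monophyletic(tr, c("A", "B", "C", "D")))
  expect_error(nj_tree(D, root_on = "nope"), "not in tree")
})

test_that("subgroup distance summaries average the right pair sets", {
  D <- matrix(0, 4, 4, dimnames = list(paste0("a", 1:4), paste0("a", 1:4)))
  D["a1", "a2"] <- D["a2", "a1"] <- 0.4
  D["a3", "a4"] <- D["a4", "a3"] <- 0.2
  D["a1", "a3"] <- D["a3", "a1"] <- 0.3
  D["a1", "a4"] <- D["a4", "a1"] <- 0.3
  D["a2", "a3"] <- D["a3", "a2"] <- 0.1
  D["a2", "a4"] <- D["a4", "a2"] <- 0.5
  meta <- simple_meta(paste0("a", 1:4),
                      subgroup = c("X", "X", "Y", "Z"))
  sm <- group_distance_summary(D, meta)
  wx <- sm[sm$group_a == "X" & sm$group_b == "X", ]
  expect_equal(wx$mean, 0.4)
  expect_equal(wx$sd, 0)
  yz <- sm[sm$group_a == "Y" & sm$group_b == "Z", ]
  expect_equal(yz$mean, 0.2)
  expect_equal(yz$n_pairs, 1)
  # within-group rows need two members: no Y-Y or Z-Z row
  expect_false(any(sm$group_a == "Y" & sm$group_b == "Y"))
})

test_that("diversity statistics respect their analytic bounds", {
  set.seed(29)
  ids <- paste0("a", 1:12)
  meta <- simple_meta(ids)
  for (rep in 1:15) {
    sites <- lapply(1:6, function(j) {
      make_site("M1", j - 1,
                setNames(sample(c("A", "C", "G", "T", "R", "M"), 12,
                                replace = TRUE), ids))
    })
    row <- diversity_stats(sites, meta, accessions = ids, label = "all")
    expect_gte(row$na, 1)
    expect_gte(row$ne, 1)
    expect_lte(row$ne, row$na + 1e-12)
    expect_gte(row$I, 0)
    expect_gte(row$H, 0)
    expect_lt(row$H, 1)
    if (!is.na(row$Fis)) {
      expect_gte(row$Fis, -1)
      expect_lte(row$Fis, 1)
    }
  }
})
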