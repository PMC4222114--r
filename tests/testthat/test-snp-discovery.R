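test_that("expand_iub implements the IUPAC definitions", {
  expect_equal(expand_iub("R"), c("A", "G"))
  expect_equal(expand_iub("Y"), c("C", "T"))
  expect_equal(expand_iub("S"), c("C", "G"))
  expect_equal(expand_iub("W"), c("A", "T"))
  expect_equal(expand_iub("K"), c("G", "T"))
  expect_equal(expand_iub("M"), c("A", "C"))
  expect_equal(expand_iub("A"), "A")
  expect_equal(expand_iub("N"), c("A", "C", "G", "T"))
  expect_equal(expand_iub("-"), character(0))
  expect_equal(expand_iub("B"), c("C", "G", "T"))
  expect_error(expand_iub("X"), "not in the IUPAC alphabet")
  expect_error(expand_iub(c("A", "C")), "single character")
})

test_that("column classification matches a hand-audited toy alignment", {
  # 10 columns: col2 has a gap, col5 an N, col3 and col8 are SNPs,
  # the remaining six are monomorphic
  m <- make_marker(c(x1 = "A-AGNTACGT",
                     x2 = "AAGGCTACGT",
                     x3 = "AARGCTAYGT"))
  res <- classify_columns(m)
  expect_equal(res$audit,
               c(monomorphic = 6L, snp = 2L, indel = 1L, ambiguous = 1L))
  expect_equal(sum(res$audit), m$aligned_length)
  expect_equal(vapply(res$sites, `[[`, integer(1), "position"), c(2L, 7L))

  # {A, A, R} column: allele set from IUB expansion, het accession listed
  s <- res$sites[[1]]
  expect_equal(s$allele_set, c("A", "G"))
  expect_equal(s$het_accessions, "x3")
  expect_equal(unname(s$states), c("A", "G", "R"))
})

test_that("audit conservation holds on random alignments with all codes", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(5:40, 1)
    n <- sample(2:8, 1)
    chars <- sample(vitisnp:::SEQ_ALPHABET, n * L, replace = TRUE,
                    prob = c(rep(10, 4), rep(2, 6), rep(0.5, 5), 0.5))
    seqs <- apply(matrix(chars, nrow = n), 1, paste, collapse = "")
    names(seqs) <- paste0("a", seq_len(n))
    res <- classify_columns(make_marker(seqs))
    expect_equal(sum(res$audit), L)
    expect_true(all(res$audit >= 0))
  }
})

test_that("SNP sets are monotone under accession supersets", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 6
    L <- 30
    chars <- sample(c("A", "C", "G", "T", "R", "Y"), n * L, replace = TRUE,
                    prob = c(rep(10, 4), 1, 1))
    seqs <- apply(matrix(chars, nrow = n), 1, paste, collapse = "")
    names(seqs) <- paste0("a", seq_len(n))
    m <- make_marker(seqs)
    sub <- names(seqs)[1:3]
    pos_sub <- vapply(classify_columns(m, sub)$sites, `[[`, integer(1),
                      "position")
    pos_all <- vapply(classify_columns(m)$sites, `[[`, integer(1),
                      "position")
    expect_true(all(pos_sub %in% pos_all))
  }
})

test_that("classification is deterministic and rejects bad subsets", {
  m <- make_marker(c(a = "ACGT", b = "ACGA"))
  expect_identical(classify_columns(m), classify_columns(m))
  expect_error(classify_columns(m, character(0)), "empty accession subset")
  expect_error(classify_columns(m, c("a", "zz")), "zz")
})

test_that("snp_density reports bp-per-SNP with half-up rounding", {
  expect_equal(snp_density(1, 100)$bp_per_snp, 100.00)
  expect_equal(snp_density(3, 100)$bp_per_snp, 33.33)
  # half-up, not banker's rounding
  expect_equal(snp_density(8, 100)$bp_per_snp, 12.5)
  expect_equal(snp_density(16, 202)$bp_per_snp, 12.63)
  # zero SNPs: undefined, not zero
  expect_true(is.na(snp_density(0, 500)$bp_per_snp))
  expect_error(snp_density(-1, 100), "n_snps")
  expect_error(snp_density(5, 0), "length_bp")
})

test_that("the optional MAF filter drops near-fixed sites only when on", {
  # 20 accessions, one heterozygote: most common allele at 39/40 = 0.975
  states <- c(rep("A", 19), "R")
  seqs <- setNames(paste0(states, "C"), paste0("a", 1:20))
  m <- make_marker(seqs)
  expect_equal(classify_columns(m)$audit[["snp"]], 1L)
  filtered <- classify_columns(m, maf_filter = TRUE)
  expect_equal(filtered$audit[["snp"]], 0L)
  expect_equal(sum(filtered$audit), 2L)
  # a balanced site survives the filter
  states2 <- c(rep("A", 10), rep("G", 10))
  m2 <- make_marker(setNames(paste0(states2, "C"), paste0("a", 1:20)))
  expect_equal(classify_columns(m2, maf_filter = TRUE)$audit[["snp"]], 1L)
})

test_that("discover_snps aggregates markers in order", {
  sim <- simulate_dataset(sim_config(seed = 3, n_cultivars = 6,
                                     n_synonym_pairs = 0, n_mislabels = 0,
                                     n_outgroups = 0,
                                     marker_lengths = c(B1 = 100,
                                                        A2 = 150)))
  disc <- discover_snps(sim$dataset)
  expect_equal(disc$audit$marker, c("B1", "A2"))
  expect_equal(disc$total_length, 250)
  expect_equal(disc$n_snps, sum(disc$audit$snp))
  markers_seen <- unique(vapply(disc$sites, `[[`, character(1),
                                "marker_name"))
  expect_equal(markers_seen, intersect(c("B1", "A2"), markers_seen))
})
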