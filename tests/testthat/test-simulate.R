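test_that("the generator is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 7, n_cultivars = 10, n_synonym_pairs = 2,
                    n_mislabels = 1, n_outgroups = 2,
                    marker_lengths = c(M1 = 150, M2 = 100))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1))
  expect_setequal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a degenerate config yields no SNPs and one genotype", {
  sim <- simulate_dataset(sim_config(seed = 2, n_cultivars = 1,
                                     clones_per_cultivar = c(CV001 = 3),
                                     n_synonym_pairs = 0, n_mislabels = 0,
                                     n_outgroups = 0, ingroup_snp_rate = 0,
                                     marker_lengths = c(M1 = 50)))
  disc <- discover_snps(sim$dataset)
  expect_equal(disc$n_snps, 0)
  expect_true(is.na(disc$density$bp_per_snp))
  prof <- build_genotype_matrix(disc$sites,
                                accessions = sim$dataset$accessions)
  expect_equal(collapse_genotypes(prof)$n_groups, 1)
})

test_that("heterozygous truth states render as the correct IUB code", {
  sim <- simulate_dataset(sim_config(seed = 9, n_cultivars = 12,
                                     n_synonym_pairs = 0, n_mislabels = 0,
                                     n_outgroups = 0,
                                     marker_lengths = c(M1 = 400)))
  gs <- sim$truth$genotype_states$M1
  meta <- sim$dataset$meta
  seqs <- sim$dataset$markers$M1$sequences
  part <- sim$truth$partition
  checked <- 0L
  for (acc in names(part)) {
    gi <- match(as.character(part[[acc]]), rownames(gs$states))
    for (k in seq_along(gs$seg)) {
      got <- substr(seqs[[acc]], gs$seg[k], gs$seg[k])
      want <- switch(as.character(gs$states[gi, k]),
                     "0" = gs$ref[k],
                     "2" = gs$alt[k],
                     "1" = vitisnp:::iub_from_pair(gs$ref[k], gs$alt[k]))
      expect_identical(got, want)
      if (gs$states[gi, k] == 1L) checked <- checked + 1L
    }
  }
  expect_gt(checked, 0)  # heterozygous sites were actually exercised
})

test_that("unsatisfiable configurations are refused", {
  expect_error(sim_config(n_cultivars = 5, n_synonym_pairs = 3),
               "synonym pairs")
  expect_error(sim_config(n_cultivars = 4, n_synonym_pairs = 1,
                          n_mislabels = 2), "mislabel")
  expect_error(sim_config(het_fraction = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(marker_lengths = c(100, 200)), "named")
})

test_that("outgroup K2P distances track the configured divergence", {
  sim <- simulate_dataset(sim_config(seed = 21, n_cultivars = 10,
                                     n_synonym_pairs = 0, n_mislabels = 0,
                                     n_outgroups = 3,
                                     marker_lengths = c(M1 = 2000),
                                     outgroup_divergence = 0.2))
  D <- k2p_matrix(concat_sequences(sim$dataset))
  og <- sim$truth$outgroups
  ing <- setdiff(rownames(D), og)
  d_between <- mean(D[og, ing])
  expect_gt(d_between, 0.2 * 0.7)
  expect_lt(d_between, 0.2 * 1.3)
  # outgroup species are mutually diverged on the same scale
  d_within_og <- mean(D[og, og][upper.tri(D[og, og])])
  expect_gt(d_within_og, 0.2 * 0.7)
  expect_lt(d_within_og, 0.2 * 1.3)
  # and every within-ingroup distance is far below the between mean
  expect_gt(d_between, max(D[ing, ing]))
})

test_that("planted ambiguous and indel columns are screened, not called", {
  cfg <- sim_config(seed = 33, n_cultivars = 8, n_synonym_pairs = 0,
                    n_mislabels = 0, n_outgroups = 0,
                    marker_lengths = c(M1 = 300),
                    ambiguous_site_rate = 0.05, indel_site_rate = 0.05)
  sim <- simulate_dataset(cfg)
  res <- classify_columns(sim$dataset$markers$M1)
  expect_equal(res$audit[["ambiguous"]],
               length(sim$truth$planted_ambiguous$M1))
  expect_equal(res$audit[["indel"]], length(sim$truth$planted_indel$M1))
  snp_pos <- vapply(res$sites, `[[`, integer(1), "position") + 1L
  expect_length(intersect(snp_pos, sim$truth$planted_ambiguous$M1), 0)
  expect_length(intersect(snp_pos, sim$truth$planted_indel$M1), 0)
})

test_that("ground-truth bookkeeping matches the emitted metadata", {
  sim <- simulate_dataset(sim_config(seed = 13, n_cultivars = 15,
                                     n_synonym_pairs = 2, n_mislabels = 1,
                                     n_outgroups = 2,
                                     marker_lengths = c(M1 = 200)))
  meta <- sim$dataset$meta
  expect_setequal(names(sim$truth$partition), meta$accession_id)
  expect_equal(sort(sim$truth$outgroups),
               sort(meta$accession_id[meta$is_outgroup]))
  expect_length(sim$truth$synonym_pairs, 2)
  expect_equal(nrow(sim$truth$mislabels), 1)
  # the mislabel is a homonymy case by construction
  expect_true(sim$truth$mislabels$labeled_as %in%
                sim$truth$expected_homonymy)
  # planted synonym pairs appear among the expected multi-name genotypes
  for (p in sim$truth$synonym_pairs) {
    expect_true(any(vapply(sim$truth$expected_synonymy,
                           function(s) all(p %in% s), logical(1))))
  }
})
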