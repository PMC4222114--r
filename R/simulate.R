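# Ground-truthed synthetic diploid Sanger-consensus data generator.
#
# The generator emulates the structure of a germplasm panel of clonally
# propagated diploid cultivars genotyped at five single-copy nuclear
# amplicons: an ancestral sequence per marker, segregating sites at a
# configured rate, per-cultivar diploid states rendered as one consensus
# sequence (heterozygote -> two-base IUB code), exact clonal replicates,
# planted synonym pairs (two names, one genotype), planted mislabels (one
# name, someone else's genotype) and deeply diverged outgroup species.
#
# Outgroups share an ancestor placed at divergence/2 from the ingroup
# ancestor and radiate a further divergence/2 each, so both the mean
# outgroup-vs-ingroup and the mean outgroup-vs-outgroup distances sit
# near the configured divergence while the outgroup/ingroup split edge
# carries divergence/2 of shared substitutions - the geometry a rooted
# tree with a supported basal split needs. Substitutions accumulate as a
# per-site Poisson process with a 2:1 transition:transversion bias, so
# K2P's separate transition/transversion correction is actually
# exercised.

TRANSITION_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

#' Configuration for the synthetic dataset generator
#'
#' Defaults reproduce the structure of the motivating study panel: five
#' nuclear markers of 761/419/418/800/919 bp, 150 cultivars in eight
#' geographic subgroups (six of them with clonal replicates), three
#' synonym pairs, one mislabel, five outgroup species, about one SNP per
#' 34.5 bp in the ingroup and outgroups diverged by 0.2
#' substitutions/site.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param marker_lengths Named integer vector of aligned marker lengths.
#' @param n_cultivars Number of distinct cultivar names in the ingroup.
#' @param clones_per_cultivar Named integer vector mapping cultivar names
#'   (`CV001`, ...) to accession copies. Default: first six cultivars get
#'   2, 2, 3, 2, 2, 2 copies, everyone else 1.
#' @param n_synonym_pairs Pairs of distinct names sharing one genotype.
#' @param n_mislabels Accessions carrying another cultivar's genotype
#'   under their own (wrong) name.
#' @param n_outgroups Number of outgroup species (one accession each).
#' @param ingroup_snp_rate Expected segregating sites per bp.
#' @param het_fraction Probability a cultivar is heterozygous at a
#'   segregating site (remaining mass split equally between the two
#'   homozygotes).
#' @param outgroup_divergence Expected substitutions/site between an
#'   outgroup and the ingroup ancestor.
#' @param ambiguous_site_rate,indel_site_rate Per-column probabilities of
#'   planting an `N` (failed base call) or `-` (indel) in one random
#'   accession. Both 0 by default.
#' @param subgroups Labels for the ingroup subgroups (assigned
#'   round-robin); outgroups always get subgroup `"Outgroup"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       marker_lengths = c(GAI = 761, ID04 = 419,
                                          IIC08 = 418, ATP = 800,
                                          UFGT = 919),
                       n_cultivars = 150,
                       clones_per_cultivar = NULL,
                       n_synonym_pairs = 3,
                       n_mislabels = 1,
                       n_outgroups = 5,
                       ingroup_snp_rate = 1 / 34.5,
                       het_fraction = 0.3,
                       outgroup_divergence = 0.2,
                       ambiguous_site_rate = 0,
                       indel_site_rate = 0,
                       subgroups = c("Local", "Italy", "Central Europe",
                                     "Spain", "Portugal",
                                     "Eastern Europe", "Near East",
                                     "Balkan Peninsula")) {
  cultivar_names <- sprintf("CV%03d", seq_len(n_cultivars))
  if (is.null(clones_per_cultivar)) {
    clones_per_cultivar <- stats::setNames(rep(1L, n_cultivars),
                                           cultivar_names)
    if (n_cultivars >= 6) {
      clones_per_cultivar[1:6] <- c(2L, 2L, 3L, 2L, 2L, 2L)
    }
  } else {
    full <- stats::setNames(rep(1L, n_cultivars), cultivar_names)
    full[names(clones_per_cultivar)] <- as.integer(clones_per_cultivar)
    clones_per_cultivar <- full
  }
  cfg <- list(seed = as.integer(seed),
              marker_lengths = marker_lengths,
              n_cultivars = as.integer(n_cultivars),
              cultivar_names = cultivar_names,
              clones_per_cultivar = clones_per_cultivar,
              n_synonym_pairs = as.integer(n_synonym_pairs),
              n_mislabels = as.integer(n_mislabels),
              n_outgroups = as.integer(n_outgroups),
              ingroup_snp_rate = ingroup_snp_rate,
              het_fraction = het_fraction,
              outgroup_divergence = outgroup_divergence,
              ambiguous_site_rate = ambiguous_site_rate,
              indel_site_rate = indel_site_rate,
              subgroups = subgroups)
  probs <- c(ingroup_snp_rate, het_fraction, ambiguous_site_rate,
             indel_site_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates and fractions must lie in [0, 1]")
  }
  if (any(marker_lengths < 1) || is.null(names(marker_lengths))) {
    stop("'marker_lengths' must be a named vector of positive lengths")
  }
  counts <- c(n_cultivars, n_synonym_pairs, n_mislabels, n_outgroups)
  if (any(counts < 0) || n_cultivars < 1) {
    stop("counts must be non-negative (and n_cultivars >= 1)")
  }
  if (2 * n_synonym_pairs > n_cultivars) {
    stop("more synonym pairs than cultivar pairs available")
  }
  if (n_mislabels > 0 &&
      n_cultivars - 2 * n_synonym_pairs < n_mislabels + 1) {
    stop("not enough cultivars outside synonym pairs to plant ",
         n_mislabels, " mislabel(s)")
  }
  if (outgroup_divergence < 0) {
    stop("'outgroup_divergence' must be non-negative")
  }
  structure(cfg, class = "sim_config")
}

# Poisson substitution process with 2:1 ti:tv bias.
evolve_sequence <- function(seq, t) {
  if (t <= 0) return(seq)
  k <- stats::rpois(length(seq), t)
  for (pos in which(k > 0)) {
    base <- seq[pos]
    for (h in seq_len(k[pos])) {
      if (stats::runif(1) < 2 / 3) {
        base <- TRANSITION_PARTNER[[base]]
      } else {
        base <- sample(setdiff(BASES, c(base, TRANSITION_PARTNER[[base]])),
                       1L)
      }
    }
    seq[pos] <- base
  }
  seq
}

render_state <- function(state, ref, alt) {
  # 0 = hom-ref, 1 = het, 2 = hom-alt
  if (state == 0L) ref else if (state == 2L) alt else iub_from_pair(ref, alt)
}

#' Simulate a ground-truthed dataset
#'
#' See [sim_config()] for the generating model. The emitted dataset has
#' exactly the input format of [read_dataset()]; the ground truth records
#' the planted genotype partition, synonym pairs, mislabels, diagnostic
#' site states and outgroup membership so every downstream stage can be
#' checked against it.
#'
#' @param config A `sim_config`.
#' @param dir Optional directory; when given, per-marker FASTA files,
#'   `metadata.tsv` and `ground_truth.yaml` are written there.
#' @return A list of class `sim_result`: `dataset` (an `snp_dataset`),
#'   `truth` (see below) and `config`. `truth` holds `partition` (named
#'   vector accession -> true genotype id), `synonym_pairs`,
#'   `mislabels`, `outgroups`, `expected_synonymy` (name sets of every
#'   multi-name genotype, mislabel-induced ones included),
#'   `expected_homonymy` (names attached to more than one genotype),
#'   `seg_sites` and `genotype_states` per marker, and any planted
#'   ambiguous/indel columns.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config, dir))
}

simulate_dataset_impl <- function(config, dir) {
  n <- config$n_cultivars
  cultivars <- config$cultivar_names
  h <- config$het_fraction

  # --- underlying genotype id per cultivar (synonyms share one) -------
  gid <- seq_len(n)
  syn_pairs <- list()
  syn_members <- integer(0)
  if (config$n_synonym_pairs > 0) {
    picked <- sample(n, 2 * config$n_synonym_pairs)
    for (p in seq_len(config$n_synonym_pairs)) {
      a <- picked[2 * p - 1]
      b <- picked[2 * p]
      gid[b] <- gid[a]
      syn_pairs[[p]] <- sort(c(cultivars[a], cultivars[b]))
    }
    syn_members <- picked
  }

  # --- mislabels: accession named A carrying B's genotype -------------
  mislabels <- data.frame(accession_id = character(0),
                          labeled_as = character(0),
                          true_cultivar = character(0))
  mislabel_plan <- list()
  if (config$n_mislabels > 0) {
    cand <- setdiff(seq_len(n), syn_members)
    src <- sample(cand, config$n_mislabels)
    for (m in seq_len(config$n_mislabels)) {
      a <- src[m]
      donors <- setdiff(seq_len(n), which(gid == gid[a]))
      b <- donors[sample(length(donors), 1L)]
      mislabel_plan[[m]] <- c(a, b)
    }
  }

  # --- accession table ------------------------------------------------
  rows <- list()
  add_row <- function(cultivar, subgroup, genotype, is_outgroup,
                      clone_of) {
    i <- length(rows) + 1L
    rows[[i]] <<- data.frame(
      accession_id = sprintf("acc%03d_%s", i, gsub(" ", "", cultivar)),
      cultivar_name = cultivar, subgroup = subgroup,
      is_outgroup = is_outgroup, clone_of = clone_of,
      genotype_id = genotype, stringsAsFactors = FALSE)
  }
  subgroup_of <- config$subgroups[(seq_len(n) - 1L) %%
                                    length(config$subgroups) + 1L]
  for (i in seq_len(n)) {
    copies <- config$clones_per_cultivar[[cultivars[i]]]
    for (cc in seq_len(copies)) {
      add_row(cultivars[i], subgroup_of[i], gid[i], FALSE,
              if (cc > 1) cultivars[i] else NA_character_)
    }
  }
  for (m in seq_along(mislabel_plan)) {
    a <- mislabel_plan[[m]][1]
    b <- mislabel_plan[[m]][2]
    add_row(cultivars[a], subgroup_of[a], gid[b], FALSE, cultivars[a])
  }
  og_gids <- integer(0)
  if (config$n_outgroups > 0) {
    og_gids <- n + seq_len(config$n_outgroups)
    for (o in seq_len(config$n_outgroups)) {
      add_row(sprintf("Wild%02d", o), "Outgroup", og_gids[o], TRUE,
              NA_character_)
    }
  }
  acc <- do.call(rbind, rows)
  if (length(mislabel_plan) > 0) {
    mis_rows <- acc[acc$clone_of %in%
                      cultivars[vapply(mislabel_plan, `[`, integer(1), 1)] &
                      acc$genotype_id !=
                      gid[match(acc$cultivar_name, cultivars)], ]
    mislabels <- data.frame(
      accession_id = mis_rows$accession_id,
      labeled_as = mis_rows$cultivar_name,
      true_cultivar = cultivars[match(mis_rows$genotype_id, gid)])
  }

  # --- sequences per marker -------------------------------------------
  unique_gids <- sort(unique(gid))
  markers <- list()
  seg_sites <- list()
  geno_states <- list()
  planted_ambiguous <- list()
  planted_indel <- list()
  for (mk in names(config$marker_lengths)) {
    L <- config$marker_lengths[[mk]]
    anc <- sample(BASES, L, replace = TRUE)
    seg <- which(stats::runif(L) < config$ingroup_snp_rate)
    alt <- vapply(seg, function(p) sample(setdiff(BASES, anc[p]), 1L),
                  character(1))
    st <- matrix(sample(c(0L, 1L, 2L), length(unique_gids) * length(seg),
                        replace = TRUE,
                        prob = c((1 - h) / 2, h, (1 - h) / 2)),
                 nrow = length(unique_gids))
    rownames(st) <- as.character(unique_gids)
    seg_sites[[mk]] <- seg
    geno_states[[mk]] <- list(seg = seg, ref = anc[seg], alt = alt,
                              states = st)

    og_seqs <- NULL
    if (config$n_outgroups > 0) {
      og_anc <- evolve_sequence(anc, config$outgroup_divergence / 2)
      og_seqs <- vapply(seq_len(config$n_outgroups), function(o) {
        paste(evolve_sequence(og_anc, config$outgroup_divergence / 2),
              collapse = "")
      }, character(1))
    }

    seqs <- character(nrow(acc))
    for (r in seq_len(nrow(acc))) {
      g <- acc$genotype_id[r]
      if (g > n) {
        seqs[r] <- og_seqs[g - n]
      } else {
        s <- anc
        if (length(seg) > 0) {
          gi <- match(as.character(g), rownames(st))
          s[seg] <- vapply(seq_along(seg), function(k) {
            render_state(st[gi, k], anc[seg[k]], alt[k])
          }, character(1))
        }
        seqs[r] <- paste(s, collapse = "")
      }
    }
    names(seqs) <- acc$accession_id

    amb_cols <- which(stats::runif(L) < config$ambiguous_site_rate)
    for (p in amb_cols) {
      victim <- sample(nrow(acc), 1L)
      substr(seqs[victim], p, p) <- "N"
    }
    ind_cols <- which(stats::runif(L) < config$indel_site_rate)
    ind_cols <- setdiff(ind_cols, amb_cols)
    for (p in ind_cols) {
      victim <- sample(nrow(acc), 1L)
      substr(seqs[victim], p, p) <- "-"
    }
    planted_ambiguous[[mk]] <- amb_cols
    planted_indel[[mk]] <- ind_cols

    markers[[mk]] <- new_marker_alignment(mk, seqs)
  }

  # --- guarantee distinct underlying genotypes ------------------------
  # Distinct genotype ids must carry distinct state vectors, or the
  # planted partition would silently disagree with what any analysis can
  # recover. Collisions are vanishingly rare at realistic site counts
  # but common in tiny test configurations, so colliding genotypes are
  # redrawn (deterministically, on the seeded stream) until unique.
  seg_markers <- names(markers)[vapply(geno_states,
                                       function(x) length(x$seg) > 0,
                                       logical(1))]
  total_seg <- sum(vapply(geno_states, function(x) length(x$seg),
                          integer(1)))
  geno_key <- function(g) {
    paste(vapply(seg_markers, function(mk) {
      gs <- geno_states[[mk]]
      gi <- match(as.character(g), rownames(gs$states))
      paste(gs$states[gi, ], collapse = "")
    }, character(1)), collapse = "|")
  }
  if (length(seg_markers) > 0 && length(unique_gids) > 1) {
    if (3^min(total_seg, 30) < length(unique_gids)) {
      stop("only ", total_seg, " segregating site(s) for ",
           length(unique_gids), " distinct genotypes; raise ",
           "'ingroup_snp_rate' or the marker lengths")
    }
    attempt <- 0L
    repeat {
      key <- vapply(unique_gids, geno_key, character(1))
      dup <- which(duplicated(key))
      if (length(dup) == 0) break
      attempt <- attempt + 1L
      if (attempt > 1000L) {
        stop("could not assign distinct genotypes after 1000 redraws")
      }
      g <- unique_gids[dup[1L]]
      for (mk in seg_markers) {
        gs <- geno_states[[mk]]
        gi <- match(as.character(g), rownames(gs$states))
        gs$states[gi, ] <- sample(c(0L, 1L, 2L), length(gs$seg),
                                  replace = TRUE,
                                  prob = c((1 - h) / 2, h, (1 - h) / 2))
        geno_states[[mk]] <- gs
        seqs <- markers[[mk]]$sequences
        for (r in which(acc$genotype_id == g)) {
          s <- strsplit(seqs[[acc$accession_id[r]]], "")[[1L]]
          s[gs$seg] <- vapply(seq_along(gs$seg), function(k) {
            render_state(gs$states[gi, k], gs$ref[k], gs$alt[k])
          }, character(1))
          seqs[[acc$accession_id[r]]] <- paste(s, collapse = "")
        }
        markers[[mk]] <- new_marker_alignment(mk, seqs)
      }
    }
  }

  meta <- acc[, c("accession_id", "cultivar_name", "subgroup",
                  "is_outgroup", "clone_of")]
  dataset <- new_dataset(unname(markers), meta)

  partition <- stats::setNames(acc$genotype_id, acc$accession_id)
  names_by_gid <- split(acc$cultivar_name, acc$genotype_id)
  expected_synonymy <- unname(Filter(function(x) length(x) >= 2,
                                     lapply(names_by_gid,
                                            function(x) sort(unique(x)))))
  gids_by_name <- split(acc$genotype_id, acc$cultivar_name)
  expected_homonymy <-
    sort(names(Filter(function(x) length(unique(x)) >= 2, gids_by_name)))

  truth <- list(partition = partition,
                synonym_pairs = syn_pairs,
                mislabels = mislabels,
                outgroups = acc$accession_id[acc$is_outgroup],
                expected_synonymy = expected_synonymy,
                expected_homonymy = expected_homonymy,
                seg_sites = seg_sites,
                genotype_states = geno_states,
                planted_ambiguous = planted_ambiguous,
                planted_indel = planted_indel)

  if (!is.null(dir)) {
    paths <- write_dataset(dataset, dir)
    truth_out <- truth
    truth_out$partition <- as.list(truth_out$partition)
    truth_out$genotype_states <- lapply(truth_out$genotype_states,
                                        function(x) {
      list(seg = x$seg, ref = x$ref, alt = x$alt,
           states = apply(x$states, 1, paste, collapse = ""))
    })
    yaml::write_yaml(truth_out, file.path(dir, "ground_truth.yaml"))
  }

  structure(list(dataset = dataset, truth = truth, config = config),
            class = "sim_result")
}
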