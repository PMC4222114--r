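# End-to-end orchestration: simulate/load -> discover -> genotype ->
# diagnose -> distances -> tree (+bootstrap) -> stats -> naming report,
# with every output written as delimited text or Newick and listed in a
# checksummed manifest. Identical config + seed => identical manifest.

#' Read a pipeline run configuration
#'
#' A single YAML file with either a `simulate:` block (arguments for
#' [sim_config()]) or an `inputs:` block (`fasta`: list of paths,
#' `metadata`: path), plus optional `seed`, `bootstrap_reps`,
#' `max_exhaustive` and `out_dir`.
#'
#' @param path Path to the YAML configuration.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  yaml::read_yaml(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_phylip_square <- function(D, path) {
  n <- nrow(D)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(rownames(D)[i], width = -12),
                      paste(sprintf("%.6f", D[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  path
}

pipeline_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(paste0("stage '", name, "': ", conditionMessage(e)), marker)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

sites_report <- function(sites) {
  if (length(sites) == 0) {
    return(data.frame(marker = character(0), position = integer(0),
                      alleles = character(0), n_het = integer(0)))
  }
  data.frame(
    marker = vapply(sites, `[[`, character(1), "marker_name"),
    position = vapply(sites, `[[`, integer(1), "position") + 1L,
    alleles = vapply(sites, function(s) paste(s$allele_set, collapse = "/"),
                     character(1)),
    n_het = vapply(sites, function(s) length(s$het_accessions),
                   integer(1)))
}

#' Run the complete analysis pipeline
#'
#' @param config Configuration list (see [read_run_config()]), or a path
#'   to a YAML file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @param stages Which stages to write output for; prerequisites are
#'   always computed in memory. Default: all of `discover`, `genotype`,
#'   `diagnose`, `distances`, `tree`, `stats`, `report`.
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (data frame of files with md5 checksums).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("discover", "genotype", "diagnose",
                                    "distances", "tree", "stats",
                                    "report")) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    stop("an output directory is required ('out_dir')")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed %||% 1L
  n_reps <- config$bootstrap_reps %||% 1000L
  max_exhaustive <- config$max_exhaustive %||% 3L

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    if (!is.null(sim_args$marker_lengths)) {
      sim_args$marker_lengths <- unlist(sim_args$marker_lengths)
    }
    sim <- pipeline_stage("simulate", out_dir,
                          simulate_dataset(do.call(sim_config, sim_args),
                                           dir = file.path(out_dir,
                                                           "simulated")))
    dataset <- sim$dataset
    truth <- sim$truth
  } else if (!is.null(config$inputs)) {
    dataset <- pipeline_stage("load", out_dir,
                              read_dataset(unlist(config$inputs$fasta),
                                           config$inputs$metadata))
  } else {
    stop("config needs a 'simulate' or an 'inputs' block")
  }

  meta <- dataset$meta
  ingroup <- meta$accession_id[!meta$is_outgroup]
  scopes <- list(all = NULL)
  if (length(ingroup) > 0 && length(ingroup) < length(meta$accession_id)) {
    scopes$ingroup <- ingroup
  }

  # ---- discover ------------------------------------------------------
  disc <- pipeline_stage("discover", out_dir, {
    lapply(scopes, function(sc) discover_snps(dataset, accessions = sc))
  })
  if ("discover" %in% stages) {
    for (sc in names(disc)) {
      write_tsv(disc[[sc]]$audit,
                file.path(out_dir, paste0("audit_", sc, ".tsv")))
      write_tsv(sites_report(disc[[sc]]$sites),
                file.path(out_dir, paste0("snp_report_", sc, ".tsv")))
    }
    write_tsv(density_table(dataset, scopes),
              file.path(out_dir, "snp_density.tsv"))
  }

  # ---- genotype ------------------------------------------------------
  geno <- pipeline_stage("genotype", out_dir, {
    profile <- build_genotype_matrix(disc$all$sites,
                                     accessions = dataset$accessions,
                                     marker_order = dataset$marker_order)
    list(profile = profile, groups = collapse_genotypes(profile))
  })
  if ("genotype" %in% stages) {
    gm <- data.frame(accession_id = rownames(geno$profile$matrix),
                     group_id = unname(geno$groups$assignment),
                     geno$profile$matrix, check.names = FALSE)
    write_tsv(gm, file.path(out_dir, "genotype_matrix.tsv"))
    write_tsv(data.frame(
      group_id = vapply(geno$groups$groups, `[[`, numeric(1), "group_id"),
      size = vapply(geno$groups$groups, `[[`, numeric(1), "size"),
      members = vapply(geno$groups$groups,
                       function(g) paste(g$members, collapse = ","),
                       character(1)),
      genotype = vapply(geno$groups$groups, `[[`, character(1),
                        "genotype")),
      file.path(out_dir, "genotype_groups.tsv"))
  }

  # ---- diagnose ------------------------------------------------------
  cas <- NULL
  if ("diagnose" %in% stages) {
    cas <- pipeline_stage("diagnose", out_dir, {
      if (geno$groups$n_groups >= 2 && ncol(geno$profile$matrix) > 0) {
        ca_key(geno$groups, geno$profile,
               max_exhaustive = max_exhaustive)
      } else {
        list()
      }
    })
    ca_rows <- do.call(rbind, lapply(unlist(cas, recursive = FALSE),
                                     function(ca) {
      data.frame(group_id = ca$group_id, category = ca$category,
                 sites = paste(ca$sites, collapse = "&"),
                 states = paste(ca$states, collapse = "&"))
    }))
    if (is.null(ca_rows)) {
      ca_rows <- data.frame(group_id = integer(0), category = character(0),
                            sites = character(0), states = character(0))
    }
    write_tsv(ca_rows, file.path(out_dir, "ca_key.tsv"))
  }

  # ---- distances -----------------------------------------------------
  concat <- vapply(dataset$accessions, function(a) {
    paste(vapply(dataset$markers[dataset$marker_order],
                 function(m) unname(m$sequences[a]), character(1)),
          collapse = "")
  }, character(1))
  dist_res <- pipeline_stage("distances", out_dir, {
    D <- k2p_matrix(concat)
    list(D = D, summary = group_distance_summary(D, meta))
  })
  if ("distances" %in% stages) {
    dd <- data.frame(accession_id = rownames(dist_res$D), dist_res$D,
                     check.names = FALSE)
    write_tsv(dd, file.path(out_dir, "k2p_matrix.tsv"))
    write_phylip_square(dist_res$D, file.path(out_dir, "k2p_matrix.phy"))
    write_tsv(dist_res$summary,
              file.path(out_dir, "distance_summary.tsv"))
  }

  # ---- tree ----------------------------------------------------------
  boot <- NULL
  if ("tree" %in% stages) {
    boot <- pipeline_stage("tree", out_dir, {
      og <- meta$accession_id[meta$is_outgroup]
      bootstrap_supports(concat, n_reps = n_reps, seed = seed,
                         root_on = if (length(og) > 0) og else NULL)
    })
    write_newick(boot$tree, file.path(out_dir, "nj_tree.nwk"))
  }

  # ---- stats ---------------------------------------------------------
  divers <- NULL
  if ("stats" %in% stages) {
    divers <- pipeline_stage("stats", out_dir, {
      if (length(disc$all$sites) > 0) {
        diversity_table(disc$all$sites, meta)
      } else {
        NULL
      }
    })
    if (!is.null(divers)) {
      write_tsv(divers, file.path(out_dir, "diversity.tsv"))
    }
  }

  # ---- naming report -------------------------------------------------
  naming <- NULL
  if ("report" %in% stages) {
    naming <- pipeline_stage("report", out_dir,
                             naming_report(geno$groups, meta))
    lines <- c("[synonymy]",
               vapply(naming$synonymy, function(s) {
                 paste0("group", s$group_id, "\t",
                        paste(s$names, collapse = ","))
               }, character(1)),
               "[homonymy]",
               vapply(naming$homonymy, function(h) {
                 paste0(h$cultivar_name, "\tgroups:",
                        paste(h$group_ids, collapse = ","))
               }, character(1)),
               "[clone_checks]",
               paste0(naming$clone_checks$cultivar_name, "\t",
                      naming$clone_checks$n_accessions, " accessions\t",
                      naming$clone_checks$n_groups, " group(s)\t",
                      ifelse(naming$clone_checks$consistent, "OK",
                             "INCONSISTENT")))
    writeLines(lines, file.path(out_dir, "naming_report.txt"))
    one_off <- one_off_pairs(geno$groups, geno$profile)
    write_tsv(one_off, file.path(out_dir, "one_off_pairs.tsv"))
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.tsv$", files)]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(dataset = dataset, truth = truth, discovery = disc,
                 profile = geno$profile, groups = geno$groups, cas = cas,
                 distances = dist_res, bootstrap = boot,
                 diversity = divers, naming = naming,
                 manifest = manifest, out_dir = out_dir))
}
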