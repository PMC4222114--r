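# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive loops / enumerations so they cannot share a bug with
# the vectorized implementation paths they check.

make_marker <- function(sequences, name = "M1") {
  vitisnp:::new_marker_alignment(name, sequences)
}

write_toy_dataset <- function(dir, markers, meta) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- vapply(names(markers), function(nm) {
    path <- file.path(dir, paste0(nm, ".fasta"))
    writeLines(as.vector(rbind(paste0(">", names(markers[[nm]])),
                               markers[[nm]])), path)
    path
  }, character(1))
  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, metadata = meta_path)
}

simple_meta <- function(ids, cultivars = ids, subgroup = "Local",
                        is_outgroup = FALSE) {
  data.frame(accession_id = ids, cultivar_name = cultivars,
             subgroup = subgroup, is_outgroup = is_outgroup,
             stringsAsFactors = FALSE)
}

# one snp_site object, as discovery would emit it
make_site <- function(marker, position, states) {
  structure(
    list(marker_name = marker, position = as.integer(position),
         states = states,
         allele_set = sort(unique(unlist(vitisnp:::IUB_CODES[states]))),
         het_accessions =
           names(states)[states %in% vitisnp:::HET_CODES]),
    class = "snp_site")
}

# profile straight from a character matrix (rows = accessions)
profile_from_matrix <- function(mat, marker = "M1") {
  sites <- lapply(seq_len(ncol(mat)), function(j) {
    make_site(marker, j - 1L, setNames(mat[, j], rownames(mat)))
  })
  build_genotype_matrix(sites, accessions = rownames(mat))
}

# independent K2P oracle: naive per-site loop, transition table lookup
k2p_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- 0L; ti <- 0L; tv <- 0L
  for (k in seq_along(av)) {
    x <- av[k]; y <- bv[k]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (x != y) {
        pair <- paste0(sort(c(x, y)), collapse = "")
        if (pair %in% c("AG", "CT")) ti <- ti + 1L else tv <- tv + 1L
      }
    }
  }
  if (n == 0L) return(NA_real_)
  P <- ti / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# exhaustive minimum-cardinality diagnostic search (brute force)
brute_force_min_ca <- function(mat, members) {
  outsiders <- setdiff(rownames(mat), members)
  g_chars <- mat[members[1], ]
  S <- ncol(mat)
  is_diag <- function(idx) {
    for (o in outsiders) {
      if (all(mat[o, idx] == g_chars[idx])) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(S)) {
    combos <- utils::combn(S, k)
    for (ci in seq_len(ncol(combos))) {
      if (is_diag(combos[, ci])) {
        return(list(size = k, idx = combos[, ci]))
      }
    }
  }
  NULL
}

ca_is_diagnostic <- function(mat, members, idx, states) {
  outsiders <- setdiff(rownames(mat), members)
  member_ok <- all(vapply(members, function(m) {
    all(mat[m, idx] == states)
  }, logical(1)))
  outsider_ok <- !any(vapply(outsiders, function(o) {
    all(mat[o, idx] == states)
  }, logical(1)))
  member_ok && outsider_ok
}

# canonical representation of a partition for equality checks
partition_sets <- function(assignment) {
  parts <- split(names(assignment), assignment)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

concat_sequences <- function(dataset) {
  vapply(dataset$accessions, function(a) {
    paste(vapply(dataset$markers[dataset$marker_order],
                 function(m) unname(m$sequences[a]), character(1)),
          collapse = "")
  }, character(1))
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
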