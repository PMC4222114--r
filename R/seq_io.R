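# Reading/writing the dataset: pre-aligned per-marker multi-FASTA files
# plus a delimited accession metadata table. No alignment is performed
# here; input consensus sequences must already be aligned per marker.

REQUIRED_META_COLS <- c("accession_id", "cultivar_name", "subgroup")

#' Read accession metadata
#'
#' Delimited text (tab or comma, auto-detected from the header line) with
#' named columns. `accession_id`, `cultivar_name` and `subgroup` are
#' required; `is_outgroup` (logical) and `clone_of` (cultivar name for
#' replicate clones) are optional and filled with `FALSE`/`NA` when absent.
#' Extra columns are preserved but ignored by the pipeline.
#'
#' @param path Path to the metadata file.
#' @return A `data.frame`, one row per accession.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "", check.names = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(REQUIRED_META_COLS, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$accession_id)) {
    dup <- unique(meta$accession_id[duplicated(meta$accession_id)])
    stop("duplicated accession_id in metadata: ", paste(dup, collapse = ", "))
  }
  if ("is_outgroup" %in% names(meta)) {
    meta$is_outgroup <- tolower(meta$is_outgroup) %in%
      c("true", "t", "yes", "1")
  } else {
    meta$is_outgroup <- FALSE
  }
  if ("clone_of" %in% names(meta)) {
    meta$clone_of[!nzchar(meta$clone_of) | meta$clone_of == "NA"] <- NA
  } else {
    meta$clone_of <- NA_character_
  }
  meta
}

new_marker_alignment <- function(marker_name, sequences) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    off <- names(sequences)[lens != lens[1L]][1L]
    stop("marker '", marker_name, "': aligned sequences have unequal ",
         "lengths (record '", off, "' has ", nchar(sequences[off]),
         " bp, first record has ", lens[1L], " bp)")
  }
  structure(
    list(marker_name = marker_name,
         aligned_length = unname(lens[1L]),
         sequences = sequences),
    class = "marker_alignment"
  )
}

normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

validate_alphabet <- function(sequences, marker_name) {
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop("marker '", marker_name, "', record '", names(sequences)[i],
         "': symbol '", substr(sequences[i], bad[i], bad[i]),
         "' at position ", bad[i], " is not in the IUPAC alphabet")
  }
  invisible(TRUE)
}

read_marker_fasta <- function(path, marker_name) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("marker '", marker_name, "': duplicated accession id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- stats::setNames(normalize_sequence(as.character(x)), ids)
  validate_alphabet(seqs, marker_name)
  new_marker_alignment(marker_name, seqs)
}

new_dataset <- function(markers, meta) {
  marker_order <- vapply(markers, `[[`, character(1), "marker_name")
  names(markers) <- marker_order
  accessions <- unique(unlist(lapply(markers, function(m) names(m$sequences)),
                              use.names = FALSE))
  absent <- setdiff(accessions, meta$accession_id)
  if (length(absent) > 0) {
    stop("accession(s) present in alignments but absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  missing_per_marker <- lapply(markers, function(m) {
    setdiff(accessions, names(m$sequences))
  })
  structure(
    list(markers = markers, meta = meta, marker_order = unname(marker_order),
         accessions = accessions, missing = missing_per_marker),
    class = "snp_dataset"
  )
}

#' Read a multi-marker aligned dataset
#'
#' Each FASTA file holds one pre-aligned marker (one consensus sequence per
#' accession, IUPAC alphabet). Sequences are uppercased and `U` is
#' normalized to `T` on load; any symbol outside the 16-letter IUPAC
#' alphabet is a load error, as is a within-marker length mismatch or an
#' accession without a metadata row. Marker order is taken from the order
#' of `fasta_paths` and drives genotype-string concatenation downstream.
#'
#' @param fasta_paths Character vector of per-marker FASTA paths; names (or
#'   file basenames) become marker names.
#' @param meta_path Path to the metadata table (see [read_metadata()]).
#' @return An object of class `snp_dataset` with elements `markers`
#'   (named list of alignments), `meta`, `marker_order`, `accessions`, and
#'   `missing` (accessions absent from each marker, normally empty).
#' @export
read_dataset <- function(fasta_paths, meta_path) {
  if (length(fasta_paths) == 0) {
    stop("no FASTA paths supplied")
  }
  marker_names <- names(fasta_paths)
  if (is.null(marker_names) || any(!nzchar(marker_names))) {
    marker_names <- sub("\\.[^.]*$", "", basename(fasta_paths))
  }
  if (anyDuplicated(marker_names)) {
    stop("duplicated marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  }
  absent <- fasta_paths[!file.exists(fasta_paths)]
  if (length(absent) > 0) {
    stop("FASTA file not found: ", paste(absent, collapse = ", "))
  }
  meta <- read_metadata(meta_path)
  markers <- Map(read_marker_fasta, fasta_paths, marker_names)
  new_dataset(unname(markers), meta)
}

#' Write a dataset back to per-marker FASTA files plus metadata
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(d))` returns an
#' identical dataset.
#'
#' @param dataset An `snp_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `fasta` (named vector of paths) and
#'   `metadata` (path).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "snp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- vapply(dataset$markers, function(m) {
    path <- file.path(dir, paste0(m$marker_name, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(m$sequences), path)
    path
  }, character(1))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- dataset$meta
  meta$clone_of[is.na(meta$clone_of)] <- ""
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, metadata = meta_path))
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("snp_dataset:", length(x$markers), "marker(s),",
      length(x$accessions), "accession(s),",
      sum(vapply(x$markers, `[[`, numeric(1), "aligned_length")),
      "aligned bp total\n")
  for (m in x$markers) {
    cat("  ", m$marker_name, ": ", m$aligned_length, " bp, ",
        length(m$sequences), " sequences\n", sep = "")
  }
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written with enough digits for a 6-decimal
#' round-trip; integer bootstrap supports stored as node labels are kept.
#'
#' @param tree An `ape` `phylo` object with unique leaf labels.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
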