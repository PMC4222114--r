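# Small internal helpers shared across modules.

# round() in base R rounds half to even; printed tables in the field round
# half up, so bp-per-SNP values use this explicit rule.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic operations in the package take an
# explicit seed and funnel through here.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Explode aligned sequences (named character vector of equal-length strings)
# into an accession x position character matrix.
seq_matrix <- function(sequences) {
  stopifnot(length(sequences) > 0)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  m <- matrix(unlist(strsplit(sequences, "", fixed = FALSE), use.names = FALSE),
              nrow = length(sequences), byrow = TRUE)
  rownames(m) <- names(sequences)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
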