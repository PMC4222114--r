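# IUPAC/IUB ambiguity alphabet. In diploid Sanger consensus data a 2-base
# code records a heterozygous position; 3/4-base codes and 'N' can only
# arise from ambiguous base calling and are screened out downstream.

IUB_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  `-` = character(0)
)

SEQ_ALPHABET <- names(IUB_CODES)
BASES <- c("A", "C", "G", "T")
HET_CODES <- c("R", "Y", "S", "W", "K", "M")
AMBIGUOUS_CODES <- c("B", "D", "H", "V", "N")

# symbols whose expansion contains a given base (used for vectorized
# column classification)
SYMS_WITH_BASE <- lapply(stats::setNames(BASES, BASES), function(b) {
  names(Filter(function(x) b %in% x, IUB_CODES))
})

# unordered base pair -> heterozygote code
IUB_PAIR <- c(
  AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
  AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M"
)

iub_from_pair <- function(a, b) {
  unname(IUB_PAIR[paste0(a, b)])
}

#' Expand an IUB/IUPAC symbol into its underlying bases
#'
#' Two-base codes (R, Y, S, W, K, M) are the heterozygote codes used to
#' record diploid consensus sequences; `N` expands to all four bases and
#' the alignment gap `-` expands to the empty set.
#'
#' @param symbol A single character from the 16-symbol IUPAC alphabet
#'   (`A C G T R Y S W K M B D H V N -`).
#' @return Character vector of underlying bases (possibly empty for `-`).
#' @examples
#' expand_iub("R")  # A G
#' expand_iub("N")  # A C G T
#' @export
expand_iub <- function(symbol) {
  if (length(symbol) != 1L || is.na(symbol)) {
    stop("'symbol' must be a single character")
  }
  out <- IUB_CODES[[symbol]]
  if (is.null(out)) {
    stop("symbol '", symbol, "' is not in the IUPAC alphabet (",
         paste(SEQ_ALPHABET, collapse = ""), ")")
  }
  out
}
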