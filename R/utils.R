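# Internal sequence helpers shared across modules.

SITE_LEN <- 28L
XERC_ARM <- 1:11
CENTRAL <- 12:17
XERD_ARM <- 18:28

#' Reverse complement of nucleotide strings
#'
#' Vectorised over a character vector; `N` is preserved.
#'
#' @param x character vector of nucleotide strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and collapse any non-ACGT IUPAC character to N.
normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Run code with a temporarily seeded RNG, restoring prior state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Random nucleotide string with given GC content.
random_sequence <- function(n, gc = 0.40) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Global-alignment nucleotide identity: matches / alignment columns,
# orientation-normalised when revcomp = TRUE.
alignment_identity <- function(a, b, revcomp_best = TRUE, type = "global") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  one <- function(p, s) {
    aln <- Biostrings::pairwiseAlignment(p, s, type = type,
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
  }
  id <- one(a, b)
  if (revcomp_best) id <- max(id, one(a, revcomp(b)))
  id
}

# Local-alignment identity of a query against a subject, scaled by query length
# (coverage-weighted); used for cargo-catalog matching.
local_query_identity <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  list(identity = Biostrings::nmatch(aln) / nchar(query),
       subject_start = Biostrings::start(Biostrings::subject(aln)))
}

# Half-up rounding to one decimal (printed-table style).
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10
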