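#' Find open reading frames on all six frames
#'
#' Codon-scan ORF finder: start codons ATG/GTG/TTG, stop codons TAA/TAG/TGA,
#' reporting the longest ORF per stop (i.e. from the earliest in-frame start
#' after the previous stop). Coordinates are 1-based inclusive on the forward
#' strand; for minus-strand ORFs `start < end` still holds and `strand` is
#' `"-"`. With `wrap = TRUE` (circular replicons) ORFs may cross the origin,
#' in which case `end` exceeds the replicon length.
#'
#' @param replicon a `replicon` object, or a plain nucleotide string (treated
#'   as linear unless `wrap` is forced).
#' @param min_len minimum ORF length in bp, stop codon included; must be
#'   >= 60. Default 150.
#' @param wrap allow ORFs across the circular origin; defaults to the
#'   replicon's topology.
#' @return data.frame: `start`, `end`, `strand`, `length`, `translation`.
#' @export
find_orfs <- function(replicon, min_len = 150L, wrap = NULL) {
  if (min_len < 60L) stop("min_len must be >= 60")
  if (inherits(replicon, "replicon")) {
    seq <- replicon$sequence
    if (is.null(wrap)) wrap <- replicon$topology == "circular"
  } else {
    seq <- normalize_sequence(replicon)
    if (is.null(wrap)) wrap <- FALSE
  }
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      translation = character(0), stringsAsFactors = FALSE)
  if (L < min_len) return(empty)
  # For wrapped scanning, extend the sequence by (almost) one full copy so an
  # ORF crossing the origin appears contiguously; candidates are then
  # de-duplicated by start position modulo L.
  scan_seq <- if (wrap) paste0(seq, substr(seq, 1L, L - 1L)) else seq
  fwd <- orfs_one_strand(scan_seq, min_len)
  if (nrow(fwd)) fwd$strand <- "+"
  rc <- revcomp(scan_seq)
  rev_ <- orfs_one_strand(rc, min_len)
  if (nrow(rev_)) {
    Ls <- nchar(scan_seq)
    tmp_start <- Ls - rev_$end + 1L
    rev_$end <- Ls - rev_$start + 1L
    rev_$start <- tmp_start
    rev_$strand <- "-"
  }
  orfs <- rbind(fwd, rev_)
  if (nrow(orfs) == 0L) return(empty)
  if (wrap) {
    orfs <- orfs[orfs$start <= L & orfs$length <= L, , drop = FALSE]
    # An ORF wholly inside the first copy also appears shifted by L; starts
    # are already restricted to <= L so only true origin-crossers keep end > L.
    orfs <- orfs[!duplicated(orfs[c("start", "strand", "length")]), , drop = FALSE]
  }
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs$translation <- translate_orfs(orfs$nt)
  orfs$nt <- NULL
  orfs
}

# ORFs on the forward strand of one sequence string (plus-strand coordinates).
orfs_one_strand <- function(seq, min_len) {
  L <- nchar(seq)
  res <- list()
  starts_set <- c("ATG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < min_len %/% 3L) next
    pos <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_stop <- codons %in% stops_set
    is_start <- codons %in% starts_set
    prev_stop <- 0L
    stop_idx <- which(is_stop)
    for (si in stop_idx) {
      # earliest start codon strictly after the previous stop
      lo <- prev_stop + 1L
      prev_stop <- si
      if (lo > si - 1L) next
      rng <- lo:(si - 1L)
      cand <- rng[is_start[rng]]
      if (length(cand) == 0L) next
      st <- cand[1]
      len <- (si - st + 1L) * 3L
      if (len < min_len) next
      res[[length(res) + 1L]] <- data.frame(
        start = pos[st], end = pos[si] + 2L, length = len,
        nt = substring(seq, pos[st], pos[si] + 2L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      nt = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

translate_orfs <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAStringSet(nt), if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}
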