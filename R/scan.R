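#' Ungapped identity between two 28-bp windows
#'
#' Fraction of the 28 positions carrying equal non-`N` characters. `N` never
#' counts as a match, so draft-contig gaps cannot inflate a site's score.
#'
#' @param window,ref 28-bp strings over `{A,C,G,T,N}`.
#' @return fraction in `[0, 1]` (matches / 28).
#' @examples
#' refs <- reference_sites()
#' identity28(refs$CD, refs$CD)  # 1
#' @export
identity28 <- function(window, ref) {
  if (nchar(window) != SITE_LEN || nchar(ref) != SITE_LEN)
    stop("identity28 requires two 28-bp strings")
  a <- strsplit(window, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  sum(a == b & a != "N" & b != "N") / SITE_LEN
}

# Per-window match counts of a sequence (as a raw vector) against one 28-bp
# reference: m[i] = matches of window starting at i. N in the sequence can
# never equal an ACGT reference byte, so N-mismatching is automatic.
window_matches <- function(seq_raw, ref) {
  L <- length(seq_raw)
  n <- L - SITE_LEN + 1L
  if (n < 1L) return(integer(0))
  r <- charToRaw(ref)
  m <- integer(n)
  for (j in seq_len(SITE_LEN)) m <- m + (seq_raw[j:(n + j - 1L)] == r[j])
  m
}

#' Scan a replicon for dif sites
#'
#' Exhaustive fixed-length scan: every 28-bp forward-strand window is scored
#' by ungapped identity against the CD reference, the DC reference and their
#' reverse complements (the reverse complement of one arrangement presents
#' the other arm order, so all four comparisons together make the scan
#' strand-symmetric). Windows at or above `min_identity` are collected,
#' overlapping hits are resolved to the single best call, and results are
#' returned sorted by start.
#'
#' @param replicon a `replicon` object.
#' @param refs reference pair from [reference_sites()].
#' @param min_identity minimum identity fraction in `[0.5, 1]`; default 0.75.
#' @param wrap scan across the origin of circular replicons by virtually
#'   appending the first 27 bases; default `TRUE` (only applies when
#'   `topology == "circular"`).
#' @return data.frame with one row per site: `replicon_id`, `start`, `end`
#'   (1-based inclusive; `end` may exceed the replicon length for a wrapped
#'   site), `orientation` (`CD`/`DC` as read on the forward strand),
#'   `identity`, `matched_reference`, `sequence` (forward strand), and the
#'   site-intrinsic arm decomposition `xerC_arm` (11 bp), `central` (6 bp),
#'   `xerD_arm` (11 bp); DC hits are reverse-complemented before arm
#'   decomposition.
#' @export
scan_replicon <- function(replicon, refs = reference_sites(),
                          min_identity = 0.75, wrap = TRUE) {
  stopifnot(inherits(replicon, "replicon"))
  if (min_identity < 0.5 || min_identity > 1)
    stop("min_identity must be in [0.5, 1]")
  L <- replicon$length
  empty <- data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      identity = numeric(0), matched_reference = character(0),
                      sequence = character(0), xerC_arm = character(0),
                      central = character(0), xerD_arm = character(0),
                      stringsAsFactors = FALSE)
  if (L < SITE_LEN) return(empty)
  do_wrap <- wrap && replicon$topology == "circular"
  seq_str <- if (do_wrap)
    paste0(replicon$sequence, substr(replicon$sequence, 1L, SITE_LEN - 1L))
  else replicon$sequence
  s_raw <- charToRaw(seq_str)

  # Variant order fixes the tie-break: forward references first, CD before DC.
  variants <- list(
    list(seq = refs$CD,          orientation = "CD", matched = "CD"),
    list(seq = refs$DC,          orientation = "DC", matched = "DC"),
    list(seq = revcomp(refs$DC), orientation = "CD", matched = "DC"),
    list(seq = revcomp(refs$CD), orientation = "DC", matched = "CD"))
  M <- vapply(variants, function(v) window_matches(s_raw, v$seq),
              integer(length(s_raw) - SITE_LEN + 1L))
  if (do_wrap) M <- M[seq_len(L), , drop = FALSE]
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)

  min_matches <- ceiling(SITE_LEN * min_identity - 1e-9)
  best <- apply(M, 1L, max)
  hit_idx <- which(best >= min_matches)
  if (length(hit_idx) == 0L) return(empty)
  which_var <- apply(M[hit_idx, , drop = FALSE], 1L, which.max)

  starts <- hit_idx
  ends <- starts + SITE_LEN - 1L
  ori <- vapply(which_var, function(k) variants[[k]]$orientation, "")
  matched <- vapply(which_var, function(k) variants[[k]]$matched, "")
  seqs <- substring(seq_str, starts, ends)
  hits <- data.frame(replicon_id = replicon$id, start = starts, end = ends,
                     orientation = ori, identity = best[hit_idx] / SITE_LEN,
                     matched_reference = matched, sequence = seqs,
                     stringsAsFactors = FALSE)

  hits <- resolve_overlaps(hits, L = L, circular = do_wrap)

  intr <- ifelse(hits$orientation == "CD", hits$sequence, revcomp(hits$sequence))
  hits$xerC_arm <- substr(intr, 1L, 11L)
  hits$central <- substr(intr, 12L, 17L)
  hits$xerD_arm <- substr(intr, 18L, 28L)
  hits[order(hits$start), , drop = FALSE]
}

# Keep the best call among mutually overlapping hits: highest identity, then
# leftmost, then CD before DC. Overlap is circular-aware.
resolve_overlaps <- function(hits, L, circular) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$identity, hits$start, hits$orientation != "CD")
  keep <- integer(0)
  overlaps <- function(s1, s2) {
    d <- abs(s1 - s2)
    if (circular) d <- pmin(d, L - d)
    d < SITE_LEN
  }
  for (i in ord) {
    if (!length(keep) || !any(overlaps(hits$start[i], hits$start[keep])))
      keep <- c(keep, i)
  }
  hits[sort(keep), , drop = FALSE]
}

#' Count sites by orientation
#'
#' @param sites site table for one replicon.
#' @return named integer vector `c(n_CD = ..., n_DC = ...)`.
#' @export
count_by_orientation <- function(sites) {
  c(n_CD = sum(sites$orientation == "CD"),
    n_DC = sum(sites$orientation == "DC"))
}

#' Separate the main chromosomal dif site from additional sites
#'
#' On a chromosome the single site most similar to the dif1 reference is
#' called the main site (`dif1`); everything else is "additional". Ties on
#' identity go to the lowest start coordinate. If no site reaches
#' `dif1_min_identity` the main site is absent (with a warning) and all
#' sites are additional.
#'
#' @param sites site table from [scan_replicon()] on a chromosome.
#' @param dif1_ref 28-bp dif1 reference sequence; default the packaged one.
#' @param dif1_min_identity minimum identity for a credible dif1 call.
#' @return list with elements `main_dif1` (one-row data.frame or `NULL`) and
#'   `additional_sites` (data.frame).
#' @export
classify_chromosomal_sites <- function(sites, dif1_ref = dif1_reference(),
                                       dif1_min_identity = 0.75) {
  if (nrow(sites) == 0L)
    return(list(main_dif1 = NULL, additional_sites = sites))
  intr <- ifelse(sites$orientation == "CD", sites$sequence, revcomp(sites$sequence))
  id1 <- vapply(intr, identity28, 0, ref = dif1_ref, USE.NAMES = FALSE)
  best <- max(id1)
  if (best < dif1_min_identity) {
    warning("no site reaches dif1 identity ", dif1_min_identity,
            "; main dif1 absent")
    return(list(main_dif1 = NULL, additional_sites = sites))
  }
  cand <- which(id1 == best)
  main_i <- cand[which.min(sites$start[cand])]
  list(main_dif1 = sites[main_i, , drop = FALSE],
       additional_sites = sites[-main_i, , drop = FALSE])
}

#' Scan a set of replicons
#'
#' Convenience wrapper applying [scan_replicon()] to each replicon and
#' binding the results.
#'
#' @inheritParams scan_replicon
#' @param replicons list of `replicon` objects.
#' @return combined site data.frame.
#' @export
scan_replicons <- function(replicons, refs = reference_sites(),
                           min_identity = 0.75, wrap = TRUE) {
  do.call(rbind, c(lapply(replicons, scan_replicon, refs = refs,
                          min_identity = min_identity, wrap = wrap),
                   list(make.row.names = FALSE)))
}
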