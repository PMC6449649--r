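#' Global-alignment identity between two modules
#'
#' Matches divided by alignment columns, orientation-normalised: the better
#' of the forward and reverse-complement alignments is reported.
#'
#' @param a,b one-row module data.frames (or plain nucleotide strings).
#' @return identity fraction in `[0, 1]`.
#' @export
module_identity <- function(a, b) {
  sa <- if (is.character(a)) a else a$module_sequence[[1]]
  sb <- if (is.character(b)) b else b$module_sequence[[1]]
  if (!nzchar(sa) || !nzchar(sb)) stop("empty module sequence")
  alignment_identity(sa, sb, revcomp_best = TRUE, type = "global")
}

#' Build module occurrences with flanking context
#'
#' Attaches the sequence immediately outside each module span (`flank_len`
#' bp on each side, truncated at the ends of linear replicons, wrapped on
#' circular ones) for context comparison.
#'
#' @param modules module table from [call_modules()] / [label_modules()].
#' @param replicons list of `replicon` objects covering all module replicons.
#' @param flank_len flank length in bp; default 500.
#' @return the module table with added columns `left_flank`, `right_flank`
#'   and `species_label`.
#' @export
module_occurrences <- function(modules, replicons, flank_len = 500L) {
  if (nrow(modules) == 0L) {
    modules$left_flank <- character(0)
    modules$right_flank <- character(0)
    modules$species_label <- character(0)
    return(modules)
  }
  reps <- setNames(replicons, vapply(replicons, `[[`, "", "id"))
  lf <- character(nrow(modules)); rf <- character(nrow(modules))
  sp <- character(nrow(modules))
  for (i in seq_len(nrow(modules))) {
    r <- reps[[modules$replicon_id[i]]]
    if (is.null(r)) stop("replicon not supplied: ", modules$replicon_id[i])
    L <- r$length
    circ <- r$topology == "circular"
    s <- modules$start[i]; e <- modules$end[i]
    if (circ) {
      seq3 <- paste0(r$sequence, r$sequence, r$sequence)
      # shift into the middle copy so both flanks are available
      s2 <- s + L; e2 <- e + L
      span <- e - s + 1L
      avail <- max(L - span, 0L)  # outside-module bases on a circle
      fl <- min(flank_len, avail %/% 2L)
      lf[i] <- substr(seq3, s2 - fl, s2 - 1L)
      rf[i] <- substr(seq3, e2 + 1L, e2 + fl)
    } else {
      lf[i] <- substr(r$sequence, max(1L, s - flank_len), s - 1L)
      rf[i] <- substr(r$sequence, e + 1L, min(L, e + flank_len))
    }
    sp[i] <- r$species_label
  }
  modules$left_flank <- lf
  modules$right_flank <- rf
  modules$species_label <- sp
  modules
}

#' Are two module occurrences in different sequence contexts?
#'
#' Compares the flanking sequences of two occurrences under both the direct
#' pairing (left-left, right-right) and the inverted pairing (left vs
#' reverse-complemented right), and reports `TRUE` when the best pairwise
#' flank identity stays below `max_context_identity`. When both flanks of
#' either occurrence are shorter than `min_informative` bp the comparison is
#' indeterminate (`NA`) and excluded from mobility support.
#'
#' @param a,b one-row occurrence data.frames from [module_occurrences()].
#' @param max_context_identity identity above which contexts count as the
#'   same; default 0.80.
#' @param min_informative minimum flank length carrying signal; default 100.
#' @return `TRUE`, `FALSE` or `NA` (indeterminate).
#' @export
context_different <- function(a, b, max_context_identity = 0.80,
                              min_informative = 100L) {
  fl <- function(x) c(x$left_flank[[1]], x$right_flank[[1]])
  fa <- fl(a); fb <- fl(b)
  if (all(nchar(fa) < min_informative) || all(nchar(fb) < min_informative))
    return(NA)
  pair_id <- function(x, y) {
    if (nchar(x) < min_informative || nchar(y) < min_informative) return(NA_real_)
    alignment_identity(x, y, revcomp_best = FALSE, type = "global")
  }
  ids <- c(pair_id(fa[1], fb[1]), pair_id(fa[2], fb[2]),
           pair_id(fa[1], revcomp(fb[2])), pair_id(fa[2], revcomp(fb[1])))
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) return(NA)
  max(ids) < max_context_identity
}

#' Group module occurrences into families
#'
#' Single-linkage closure of pairwise [module_identity()] at `threshold`
#' (default 0.95): occurrences linked directly or transitively at or above
#' the threshold form one family.
#'
#' @param occurrences occurrence table from [module_occurrences()].
#' @param threshold family-linkage identity; default 0.95.
#' @return integer vector of family ids (1-based, decreasing family size).
#' @export
group_module_families <- function(occurrences, threshold = 0.95) {
  n <- nrow(occurrences)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  # Cheap exact prescreens before the O(len^2) alignment:
  # (i) global identity can never exceed min(len)/max(len);
  # (ii) at divergence d the fraction of broken 12-mers is at most 12 d, so
  #      identity >= 0.95 guarantees 12-mer containment >= 0.4; screening at
  #      0.3 keeps a wide safety margin and rejects unrelated pairs
  #      (expected random containment ~ len / 4^12).
  seqs <- occurrences$module_sequence
  lens <- nchar(seqs)
  kmers <- lapply(seqs, function(s)
    unique(substring(s, seq_len(nchar(s) - 11L), 12:nchar(s))))
  kmers_rc <- lapply(seqs, function(s) {
    r <- revcomp(s)
    unique(substring(r, seq_len(nchar(r) - 11L), 12:nchar(r)))
  })
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < threshold) next
    cont <- max(mean(kmers[[i]] %in% kmers[[j]]),
                mean(kmers[[i]] %in% kmers_rc[[j]]))
    if (cont < 0.3) next
    if (module_identity(occurrences[i, ], occurrences[j, ]) >= threshold)
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  g <- if (length(edges))
    igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  else igraph::make_empty_graph(n = n, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  # renumber by decreasing family size, ties by first occurrence
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), match(names(sizes), as.character(memb)))
  match(as.character(memb), names(sizes)[ord])
}

#' Assess horizontal mobility of a module family
#'
#' A family shows evidence of mobility when at least one occurrence pair
#' satisfies all three conditions: module identity at or above
#' `min_module_identity` (default 0.98), demonstrably different flanking
#' context, and location on different replicons. A species difference is
#' recorded for each supporting pair but required only in `strict` mode
#' (species labels are often absent on contigs).
#'
#' @param occurrences occurrence table (one family) from
#'   [module_occurrences()].
#' @param min_module_identity default 0.98.
#' @param max_context_identity passed to [context_different()].
#' @param min_informative passed to [context_different()].
#' @param strict also require different species labels; default FALSE.
#' @param family_label label reported for the family; defaults to the most
#'   common module label among the occurrences.
#' @return list with `family_label`, `n_occurrences`, `is_mobile`, and a
#'   `supporting_pairs` data.frame (`i`, `j`, `module_identity`,
#'   `context_different`, `different_replicons`, `different_species`).
#' @export
assess_mobility <- function(occurrences, min_module_identity = 0.98,
                            max_context_identity = 0.80,
                            min_informative = 100L, strict = FALSE,
                            family_label = NULL) {
  n <- nrow(occurrences)
  if (is.null(family_label)) {
    family_label <- if (n) names(sort(table(occurrences$label),
                                      decreasing = TRUE))[1] else "unlabeled"
  }
  pairs <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mid <- module_identity(occurrences[i, ], occurrences[j, ])
    if (mid < min_module_identity) next
    diff_rep <- occurrences$replicon_id[i] != occurrences$replicon_id[j]
    if (!diff_rep) next
    ctx <- context_different(occurrences[i, ], occurrences[j, ],
                             max_context_identity = max_context_identity,
                             min_informative = min_informative)
    if (!isTRUE(ctx)) next
    sa <- occurrences$species_label[i]; sb <- occurrences$species_label[j]
    diff_sp <- !is.na(sa) && !is.na(sb) && sa != sb
    if (strict && !diff_sp) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      i = i, j = j, module_identity = mid, context_different = TRUE,
      different_replicons = TRUE, different_species = diff_sp,
      stringsAsFactors = FALSE)
  }
  supporting <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(0), j = integer(0), module_identity = numeric(0),
               context_different = logical(0), different_replicons = logical(0),
               different_species = logical(0), stringsAsFactors = FALSE)
  list(family_label = family_label, n_occurrences = n,
       is_mobile = nrow(supporting) > 0L, supporting_pairs = supporting)
}

#' Assess mobility for every family in a module table
#'
#' Groups occurrences into families with [group_module_families()] and runs
#' [assess_mobility()] on each.
#'
#' @inheritParams assess_mobility
#' @param occurrences full occurrence table.
#' @param family_threshold single-linkage threshold; default 0.95.
#' @return list of mobility calls, one per family (decreasing family size),
#'   each with an extra `members` element giving occurrence row indices.
#' @export
assess_all_families <- function(occurrences, family_threshold = 0.95,
                                min_module_identity = 0.98,
                                max_context_identity = 0.80,
                                min_informative = 100L, strict = FALSE) {
  fam <- group_module_families(occurrences, threshold = family_threshold)
  lapply(sort(unique(fam)), function(f) {
    idx <- which(fam == f)
    call <- assess_mobility(occurrences[idx, , drop = FALSE],
                            min_module_identity = min_module_identity,
                            max_context_identity = max_context_identity,
                            min_informative = min_informative, strict = strict)
    call$members <- idx
    call
  })
}
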