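#' Ungapped identity between two site sequences
#'
#' Hamming matches / 28 on 28-bp strings. Callers should pass sequences in
#' site-intrinsic orientation (DC hits reverse-complemented) so that a site
#' and its reverse-complement occurrence compare as equals.
#'
#' @param a,b 28-bp strings.
#' @return fraction in `[0, 1]`.
#' @export
pairwise_site_identity <- function(a, b) identity28(a, b)

# Site-intrinsic sequences of a site table (DC hits reverse-complemented).
intrinsic_site_seqs <- function(sites) {
  ifelse(sites$orientation == "CD", sites$sequence, revcomp(sites$sequence))
}

#' Cluster sites at an identity threshold
#'
#' Single-linkage transitive closure of the relation
#' `identity >= threshold`, in the manner of neighbour-based sequence
#' clustering tools. At 28 bp a 0.95 threshold admits at most one mismatch
#' per link (27/28 = 0.964; 26/28 = 0.929). DC-oriented sites are
#' orientation-normalised before comparison. Clusters are numbered 1..K in
#' decreasing size; ties are broken by the representative's (replicon id,
#' start) order. The representative of a cluster is its first member by
#' (replicon id, start).
#'
#' @param sites site table from [scan_replicon()] (>= 1 row).
#' @param threshold linkage identity; default 0.95.
#' @return list with `assignments` (integer cluster id per input row) and
#'   `clusters` (data.frame: `cluster_id`, `size`, `representative_replicon`,
#'   `representative_start`, `representative_sequence`).
#' @export
cluster_sites <- function(sites, threshold = 0.95) {
  n <- nrow(sites)
  if (n == 0L) stop("cluster_sites requires at least one site")
  seqs <- intrinsic_site_seqs(sites)
  # pairwise Hamming distance via position-wise character matrix
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  min_matches <- ceiling(SITE_LEN * threshold - 1e-9)
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      block <- mat[rest, , drop = FALSE]
      eq <- block == matrix(mat[i, ], nrow = length(rest), ncol = SITE_LEN,
                            byrow = TRUE)
      eq[block == "N"] <- FALSE
      eq[, mat[i, ] == "N"] <- FALSE
      m <- rowSums(eq)
      hit <- rest[m >= min_matches]
      if (length(hit))
        edges[[length(edges) + 1L]] <- cbind(i, hit)
    }
  }
  g <- if (length(edges))
    igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  else igraph::make_empty_graph(n = n, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g)$membership

  ord_key <- order(sites$replicon_id, sites$start)
  rep_of <- vapply(split(seq_len(n), memb), function(idx)
    idx[which.min(match(idx, ord_key))], 1L)
  sizes <- vapply(split(seq_len(n), memb), length, 1L)
  comp_order <- order(-sizes, match(rep_of, ord_key))
  new_id <- match(memb, as.integer(names(sizes))[comp_order])
  reps <- rep_of[comp_order]
  list(assignments = new_id,
       clusters = data.frame(cluster_id = seq_along(reps),
                             size = sizes[comp_order],
                             representative_replicon = sites$replicon_id[reps],
                             representative_start = sites$start[reps],
                             representative_sequence = seqs[reps],
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Order sites by cluster and write an annotated FASTA
#'
#' Output order: clusters by decreasing size, members within a cluster by
#' (replicon id, start), so that same-cluster sites follow each other.
#'
#' @param sites site table passed to [cluster_sites()].
#' @param clustering result of [cluster_sites()] on the same table.
#' @param fasta_path optional path; when given, the ordered sites are written
#'   as FASTA with headers `replicon:start-end|cluster_<id>`.
#' @return the reordered site table with a `cluster_id` column.
#' @export
sort_by_cluster <- function(sites, clustering, fasta_path = NULL) {
  sites$cluster_id <- clustering$assignments
  ord <- order(sites$cluster_id, sites$replicon_id, sites$start)
  out <- sites[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(fasta_path)) {
    if (nrow(out)) {
      ss <- Biostrings::DNAStringSet(intrinsic_site_seqs(out))
      names(ss) <- sprintf("%s:%d-%d|cluster_%d", out$replicon_id, out$start,
                           out$end, out$cluster_id)
      Biostrings::writeXStringSet(ss, fasta_path)
    } else {
      file.create(fasta_path)
    }
  }
  out
}
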