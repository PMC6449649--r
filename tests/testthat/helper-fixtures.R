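# Shared fixtures and independent oracles, built in code at test time.

REFS <- reference_sites()
CATALOG <- read_cargo_catalog()

# Background with a site or arbitrary insert planted at a fixed position.
plant_in_background <- function(insert, bg_len = 500L, at = 101L, seed = 1L,
                                gc = 0.40) {
  stopifnot(at + nchar(insert) - 1L <= bg_len)
  withr_seed(seed, {
    bg <- random_bg(bg_len, gc)
    paste0(substr(bg, 1L, at - 1L), insert,
           substr(bg, at + nchar(insert), bg_len))
  })
}

random_bg <- function(n, gc = 0.40) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Substitute exactly k positions of a string (independent of mutate_site).
substitute_k <- function(seq, k, seed = NULL) {
  go <- function() {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) go() else withr_seed(seed, go())
}

# Hamming identity oracle (plain loop, N never matches).
hamming28 <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av == bv & av != "N" & bv != "N") / 28
}

# Brute-force site scan oracle: all windows x all four reference variants,
# followed by an independently written greedy overlap resolution.
brute_scan <- function(seq, refs, min_identity, circular = FALSE) {
  L <- nchar(seq)
  s <- if (circular) paste0(seq, substr(seq, 1, 27)) else seq
  n <- if (circular) L else L - 27L
  variants <- data.frame(
    ref = c(refs$CD, refs$DC, revcomp(refs$DC), revcomp(refs$CD)),
    orientation = c("CD", "DC", "CD", "DC"), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(max(n, 0L))) {
    w <- substr(s, i, i + 27L)
    ids <- vapply(variants$ref, hamming28, 0, a = w, USE.NAMES = FALSE)
    best <- which.max(ids)
    if (ids[best] >= min_identity - 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, identity = ids[best],
        orientation = variants$orientation[best], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), identity = numeric(0),
                      orientation = character(0)))
  h <- do.call(rbind, rows)
  # greedy: best identity first, leftmost, CD first; drop circularly overlapping
  h <- h[order(-h$identity, h$start, h$orientation != "CD"), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(h))) {
    d <- abs(h$start[i] - h$start[keep])
    if (circular && length(keep)) d <- pmin(d, L - d)
    if (!length(keep) || all(d >= 28)) keep <- c(keep, i)
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

# Union-find single-linkage clustering oracle.
union_find_clusters <- function(seqs, threshold = 0.95) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hamming28(seqs[i], seqs[j]) >= threshold - 1e-12) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Tiny GenBank flat-file record for reader tests.
genbank_record <- function(name = "TESTREC", topology = "circular",
                           definition = "Acinetobacter lwoffii plasmid pTest, complete sequence.",
                           sequence = strrep("acgt", 30), origin = TRUE) {
  seq_lines <- character(0)
  if (origin) {
    seq_lines <- "ORIGIN"
    chunks <- substring(sequence, seq(1, nchar(sequence), 60),
                        pmin(seq(1, nchar(sequence), 60) + 59, nchar(sequence)))
    for (i in seq_along(chunks))
      seq_lines <- c(seq_lines, sprintf("%9d %s", (i - 1L) * 60L + 1L, chunks[i]))
  }
  c(sprintf("LOCUS       %s             %d bp    DNA     %s   BCT 01-JAN-2019",
            name, nchar(sequence), topology),
    sprintf("DEFINITION  %s", definition),
    sprintf("ACCESSION   %s", name),
    sprintf("VERSION     %s.1", name),
    seq_lines,
    "//")
}
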