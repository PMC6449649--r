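#' Call candidate dif modules between consecutive sites
#'
#' A candidate module spans from the first base of one site to the last base
#' of the next site along the replicon (the span is inclusive of both
#' flanking 28-bp sites). Pairing is consecutive-only; on circular replicons
#' the pair wrapping the origin is also considered. Candidates longer than
#' `max_len` are dropped, and with `require_orf = TRUE` so are candidates
#' whose interior carries no ORF of at least `orf_min_len` bp.
#'
#' @param sites site table from [scan_replicon()] for one replicon (>= 2
#'   sites required to yield any module; fewer return an empty table).
#' @param replicon the corresponding `replicon` object.
#' @param max_len maximum inclusive module span in bp; default 20000.
#' @param require_orf drop candidates lacking a cargo ORF; default TRUE.
#' @param orf_min_len minimum cargo ORF length in bp; default 150.
#' @return data.frame with one row per module: `replicon_id`, `start`, `end`
#'   (`end` may exceed the replicon length for the origin-wrapping module of
#'   a circular replicon), `length`, flanking-site columns
#'   (`left_start/left_end/left_orientation/left_identity` and the `right_*`
#'   equivalents), `label` (filled by [label_module()]; initialised
#'   `"unlabeled"`), `module_sequence`, and a `cargo_orfs` list-column of ORF
#'   tables in replicon coordinates.
#' @export
call_modules <- function(sites, replicon, max_len = 20000L,
                         require_orf = TRUE, orf_min_len = 150L) {
  stopifnot(inherits(replicon, "replicon"))
  empty <- empty_modules()
  if (nrow(sites) < 2L) return(empty)
  sites <- sites[order(sites$start), , drop = FALSE]
  if (any(diff(sites$start) < SITE_LEN))
    stop("overlapping sites passed to call_modules (scanner contract violation)")
  L <- replicon$length
  circular <- replicon$topology == "circular"
  n <- nrow(sites)
  pairs <- cbind(seq_len(n - 1L), 2:n)
  if (circular && n >= 2L) pairs <- rbind(pairs, c(n, 1L))
  seq2 <- paste0(replicon$sequence, replicon$sequence)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    start <- sites$start[i]
    end <- if (j > i) sites$end[j] else sites$end[j] + L  # wrap pair
    len <- end - start + 1L
    if (len > max_len || len < 2L * SITE_LEN) next
    mod_seq <- substr(seq2, start, end)
    orfs <- find_orfs(mod_seq, min_len = orf_min_len, wrap = FALSE)
    # cargo = ORFs overlapping the inter-site interior by >= orf_min_len bp
    # (permissive GTG/TTG starts may bleed a genuine cargo ORF into a
    # flanking site, so containment in the interior is not required)
    if (nrow(orfs)) {
      overlap <- pmin(orfs$end, len - SITE_LEN) - pmax(orfs$start, SITE_LEN + 1L) + 1L
      orfs <- orfs[overlap >= orf_min_len, , drop = FALSE]
      if (nrow(orfs)) {
        orfs$start <- orfs$start + start - 1L
        orfs$end <- orfs$end + start - 1L
      }
    }
    if (require_orf && nrow(orfs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      replicon_id = replicon$id, start = start, end = end, length = len,
      left_start = sites$start[i], left_end = sites$end[i],
      left_orientation = sites$orientation[i], left_identity = sites$identity[i],
      right_start = sites$start[j], right_end = sites$end[j],
      right_orientation = sites$orientation[j], right_identity = sites$identity[j],
      label = "unlabeled", module_sequence = mod_seq,
      stringsAsFactors = FALSE)
    out[[length(out)]]$cargo_orfs <- list(orfs)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_modules <- function() {
  df <- data.frame(replicon_id = character(0), start = integer(0),
                   end = integer(0), length = integer(0),
                   left_start = integer(0), left_end = integer(0),
                   left_orientation = character(0), left_identity = numeric(0),
                   right_start = integer(0), right_end = integer(0),
                   right_orientation = character(0), right_identity = numeric(0),
                   label = character(0), module_sequence = character(0),
                   stringsAsFactors = FALSE)
  df$cargo_orfs <- list()
  df
}

#' Read a cargo catalog FASTA
#'
#' Headers may carry `name|function_class`; with no `|`, the function class
#' is `"unknown"`.
#'
#' @param path catalog FASTA; defaults to the packaged synthetic catalog
#'   (randomly generated ORFs with the lengths of the known dif-module cargo
#'   genes -- stand-ins, not the real genes).
#' @return data.frame: `name`, `function_class`, `reference_sequence`.
#' @export
read_cargo_catalog <- function(path = system.file("extdata", "cargo_catalog_synthetic.fa",
                                                  package = "difmod")) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  name <- vapply(parts, `[`, "", 1L)
  fclass <- vapply(parts, function(p) if (length(p) > 1L) p[2] else "unknown", "")
  if (anyDuplicated(name)) stop("duplicate catalog entry names")
  data.frame(name = name, function_class = fclass,
             reference_sequence = normalize_sequence(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label a module against a cargo catalog
#'
#' Each catalog reference is aligned (local alignment, orientation
#' normalised) against the module sequence; entries whose identity over the
#' full reference length reaches `min_identity` contribute their name. Names
#' are joined with `-` in coordinate order of their matches and suffixed
#' `"_dif"`; a module matching nothing is `"unlabeled"`.
#'
#' @param module one-row module data.frame from [call_modules()].
#' @param catalog catalog from [read_cargo_catalog()].
#' @param min_identity minimum identity over the reference length; default 0.90.
#' @return character label, e.g. `"terC_dif"`, `"sulP-uspA_dif"`, `"unlabeled"`.
#' @export
label_module <- function(module, catalog, min_identity = 0.90) {
  if (nrow(catalog) == 0L) stop("empty cargo catalog")
  mod_seq <- module$module_sequence[[1]]
  mod_rc <- revcomp(mod_seq)
  # 12-mer containment prescreen: a catalog gene present at >= min_identity
  # shares a large fraction of its 12-mers with the module (~0.94 at 0.5%
  # divergence, ~0.28 expected at 10%), while an absent gene shares ~0.1%
  # by chance; only entries passing the screen are aligned.
  mod_kmers <- unique(c(substring(mod_seq, seq_len(nchar(mod_seq) - 11L),
                                  12:nchar(mod_seq)),
                        substring(mod_rc, seq_len(nchar(mod_rc) - 11L),
                                  12:nchar(mod_rc))))
  matches <- list()
  for (i in seq_len(nrow(catalog))) {
    q <- catalog$reference_sequence[i]
    qk <- unique(substring(q, seq_len(nchar(q) - 11L), 12:nchar(q)))
    if (mean(qk %in% mod_kmers) < 0.05) next
    fw <- local_query_identity(q, mod_seq)
    rv <- local_query_identity(q, mod_rc)
    best <- if (fw$identity >= rv$identity) fw else
      list(identity = rv$identity,
           subject_start = nchar(mod_seq) - rv$subject_start + 1L)
    if (best$identity >= min_identity)
      matches[[length(matches) + 1L]] <- data.frame(
        name = catalog$name[i], pos = best$subject_start,
        stringsAsFactors = FALSE)
  }
  if (length(matches) == 0L) return("unlabeled")
  m <- do.call(rbind, matches)
  m <- m[order(m$pos), , drop = FALSE]
  paste0(paste(m$name, collapse = "-"), "_dif")
}

#' Label every module in a table
#'
#' @inheritParams label_module
#' @param modules module table from [call_modules()].
#' @return the module table with the `label` column filled.
#' @export
label_modules <- function(modules, catalog, min_identity = 0.90) {
  if (nrow(modules) == 0L) return(modules)
  modules$label <- vapply(seq_len(nrow(modules)), function(i)
    label_module(modules[i, , drop = FALSE], catalog, min_identity), "")
  modules
}
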