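#' Read replicons from FASTA
#'
#' One `replicon` per record. Sequences are uppercased and non-ACGT IUPAC
#' letters collapsed to `N`; record ids must be unique.
#'
#' @param path FASTA file.
#' @param topology topology assigned to every record (`"circular"` or
#'   `"linear"`).
#' @param category category assigned to every record.
#' @return list of `replicon` objects, in file order.
#' @export
read_fasta <- function(path, topology = c("circular", "linear"),
                       category = c("plasmid", "chromosome", "contig")) {
  topology <- match.arg(topology)
  category <- match.arg(category)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA input: ", path)
  hdr <- names(ss)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  reps <- lapply(seq_along(ss), function(i)
    replicon(ids[i], as.character(ss[[i]]), topology = topology,
             category = category, description = desc[i]))
  check_replicon_set(reps)
}

#' Write replicons to FASTA
#'
#' Headers are `id description` (description omitted when empty); a
#' read-write-read round trip preserves ids, sequences and order.
#'
#' @param replicons list of `replicon` objects.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(replicons, path) {
  ss <- Biostrings::DNAStringSet(vapply(replicons, `[[`, "", "sequence"))
  ids <- vapply(replicons, `[[`, "", "id")
  desc <- vapply(replicons, `[[`, "", "description")
  names(ss) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read replicons from a GenBank flat file
#'
#' Minimal flat-file reader: uses the LOCUS line for topology
#' (circular/linear), ACCESSION/VERSION (falling back to the LOCUS name) for
#' the id, DEFINITION for the description, and the ORIGIN block for the
#' sequence. Category is inferred from the definition line ("plasmid" /
#' "chromosome" keywords, else contig) unless overridden.
#'
#' @param path GenBank flat file (one or more records).
#' @param category optional override; when given, metadata inference is
#'   ignored for every record.
#' @return list of `replicon` objects.
#' @export
read_genbank <- function(path, category = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS record found in '", path, "'")
  ends <- c(starts[-1] - 1L, length(lines))
  reps <- lapply(seq_along(starts), function(i) {
    rec <- lines[starts[i]:ends[i]]
    locus <- rec[1]
    topo <- if (grepl("\\bcircular\\b", locus, ignore.case = TRUE)) "circular" else "linear"
    locus_name <- strsplit(trimws(sub("^LOCUS\\s+", "", locus)), "\\s+")[[1]][1]
    id <- locus_name
    ver <- grep("^VERSION\\s+\\S", rec, value = TRUE)
    acc <- grep("^ACCESSION\\s+\\S", rec, value = TRUE)
    if (length(ver)) id <- strsplit(trimws(sub("^VERSION\\s+", "", ver[1])), "\\s+")[[1]][1]
    else if (length(acc)) id <- strsplit(trimws(sub("^ACCESSION\\s+", "", acc[1])), "\\s+")[[1]][1]
    def_i <- grep("^DEFINITION", rec)
    def <- ""
    if (length(def_i)) {
      j <- def_i[1]
      def_lines <- rec[j]
      while (j < length(rec) && grepl("^\\s{5,}", rec[j + 1L])) {
        j <- j + 1L
        def_lines <- c(def_lines, rec[j])
      }
      def <- trimws(sub("^DEFINITION\\s+", "", paste(trimws(def_lines), collapse = " ")))
    }
    ori <- grep("^ORIGIN", rec)
    if (length(ori) == 0L)
      stop("record '", id, "' in '", path, "' has no ORIGIN sequence")
    term <- grep("^//", rec)
    term <- term[term > ori[1]]
    seq_end <- if (length(term)) term[1] - 1L else length(rec)
    seq_lines <- rec[(ori[1] + 1L):seq_end]
    sequence <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
    if (!nzchar(sequence))
      stop("record '", id, "' in '", path, "' has an empty ORIGIN sequence")
    cat_i <- if (!is.null(category)) category
    else if (grepl("plasmid", def, ignore.case = TRUE)) "plasmid"
    else if (grepl("chromosome|complete genome", def, ignore.case = TRUE)) "chromosome"
    else "contig"
    replicon(id, sequence, topology = topo, category = cat_i, description = def)
  })
  check_replicon_set(reps)
}

#' Write detected sites as TSV or BED
#'
#' Internally sites use 1-based inclusive coordinates; BED output is 0-based
#' half-open, with orientation in the strand column (`+` for CD, `-` for DC)
#' and the identity fraction in the score column (scaled to 0-1000).
#'
#' @param sites site table from [scan_replicon()] (possibly empty).
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- c("replicon_id", "start", "end", "orientation", "identity",
              "matched_reference", "sequence", "xerC_arm", "central", "xerD_arm")
    df <- if (nrow(sites)) sites[, cols, drop = FALSE] else
      as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(sites) == 0L) {
      file.create(path)
    } else {
      gr <- GenomicRanges::GRanges(
        seqnames = sites$replicon_id,
        ranges = IRanges::IRanges(start = sites$start, end = sites$end),
        strand = ifelse(sites$orientation == "CD", "+", "-"))
      S4Vectors::mcols(gr)$name <- paste0("pdif_", sites$orientation, "_",
                                          seq_len(nrow(sites)))
      S4Vectors::mcols(gr)$score <- round(sites$identity * 1000)
      rtracklayer::export(gr, path, format = "BED")
    }
  }
  invisible(path)
}

#' Read a site TSV written by [write_sites()]
#'
#' @param path TSV file.
#' @return site data.frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(replicon_id = "character",
                                         sequence = "character"),
                          stringsAsFactors = FALSE)
  df$replicon_id <- as.character(df$replicon_id)
  df
}

#' Write called modules as GFF3
#'
#' One `mobile_genetic_element` parent feature per module with child features
#' for the two flanking recombination sites and each cargo ORF. A module that
#' wraps the circular origin is emitted as two parent segments sharing one
#' feature ID (the standard GFF3 discontinuous-feature convention); its
#' children are placed on the segment that contains them.
#'
#' @param modules module table from [call_modules()].
#' @param path output GFF3 file.
#' @param replicon_lengths optional named integer vector; when provided,
#'   module coordinates beyond a non-circular replicon's length raise an
#'   error, and circular wrap coordinates are split at the origin.
#' @param circular named logical vector (or single logical) saying which
#'   replicons are circular; defaults to FALSE.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path, replicon_lengths = NULL, circular = FALSE) {
  rows <- list()
  add <- function(seqid, start, end, type, id, parent = NA_character_, attrs = list()) {
    a <- c(list(type = type, ID = id), attrs)
    if (!is.na(parent)) a$Parent <- parent
    rows[[length(rows) + 1L]] <<- c(list(seqid = seqid, start = start, end = end), a)
  }
  is_circ <- function(rid) {
    if (length(circular) == 1L && is.null(names(circular))) isTRUE(circular)
    else isTRUE(unname(circular[rid]))
  }
  for (i in seq_len(nrow(modules))) {
    m <- modules[i, ]
    rid <- m$replicon_id
    L <- if (!is.null(replicon_lengths)) unname(replicon_lengths[rid]) else NA_integer_
    mid <- sprintf("module_%03d", i)
    attrs <- list(label = m$label,
                  left_identity = m$left_identity,
                  right_identity = m$right_identity,
                  module_length = m$length)
    wraps <- !is.na(L) && m$end > L
    if (wraps && !is_circ(rid))
      stop("module ", mid, " extends beyond the end of non-circular replicon '",
           rid, "' (", m$end, " > ", L, ")")
    if (!is.na(L) && !wraps && (m$start < 1L || m$end > L))
      stop("module ", mid, " out of bounds on replicon '", rid, "'")
    seg <- function(s, e) {
      if (wraps && s > L) c(s - L, e - L) else if (wraps && e > L) c(s, NA) else c(s, e)
    }
    if (wraps) {
      add(rid, m$start, L, "mobile_genetic_element", mid, attrs = attrs)
      add(rid, 1L, m$end - L, "mobile_genetic_element", mid, attrs = attrs)
    } else {
      add(rid, m$start, m$end, "mobile_genetic_element", mid, attrs = attrs)
    }
    place <- function(s, e, type, cid, attrs2 = list()) {
      if (wraps && s > L) { s <- s - L; e <- e - L }
      else if (wraps && e > L) e <- L  # child straddles origin: truncate at origin
      add(rid, s, e, type, cid, parent = mid, attrs = attrs2)
    }
    place(m$left_start, m$left_end, "recombination_site", paste0(mid, "_siteL"),
          list(orientation = m$left_orientation))
    place(m$right_start, m$right_end, "recombination_site", paste0(mid, "_siteR"),
          list(orientation = m$right_orientation))
    orfs <- m$cargo_orfs[[1]]
    if (!is.null(orfs) && nrow(orfs)) {
      for (k in seq_len(nrow(orfs))) {
        place(orfs$start[k], orfs$end[k], "ORF", sprintf("%s_orf%d", mid, k),
              list(strand_orf = orfs$strand[k], orf_length = orfs$length[k]))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (r in rows) {
    extra <- r[setdiff(names(r), c("seqid", "start", "end", "type", "ID", "Parent"))]
    attr_str <- paste0("ID=", r$ID)
    if (!is.null(r$Parent)) attr_str <- paste0(attr_str, ";Parent=", r$Parent)
    if (length(extra))
      attr_str <- paste(c(attr_str,
                          paste0(names(extra), "=", vapply(extra, as.character, ""))),
                        collapse = ";")
    writeLines(sprintf("%s\tdifmod\t%s\t%d\t%d\t.\t.\t.\t%s",
                       r$seqid, r$type, as.integer(r$start), as.integer(r$end),
                       attr_str), con)
  }
  invisible(path)
}
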