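#' Replicon objects
#'
#' A `replicon` is one input sequence record (plasmid, chromosome or contig)
#' carrying its topology, category and an uppercased `{A,C,G,T,N}` sequence.
#' Coordinates throughout the package are 1-based and inclusive on the forward
#' strand of the deposited sequence.
#'
#' @param id character scalar, unique identifier within a dataset.
#' @param sequence nucleotide string; lowercased input is uppercased and any
#'   non-ACGT IUPAC letter is collapsed to `N` on ingest.
#' @param topology `"circular"` or `"linear"`.
#' @param category `"plasmid"`, `"chromosome"` or `"contig"`.
#' @param description free-text description.
#' @param species_label optional species annotation.
#' @return An object of class `replicon`: a list with fields `id`,
#'   `description`, `sequence`, `topology`, `category`, `species_label` and
#'   `length` (bp).
#' @examples
#' r <- replicon("p1", "acgtACGT", topology = "linear", category = "plasmid")
#' r$length    # 8
#' r$sequence  # "ACGTACGT"
#' @export
replicon <- function(id, sequence, topology = c("circular", "linear"),
                     category = c("plasmid", "chromosome", "contig"),
                     description = "", species_label = NA_character_) {
  topology <- match.arg(topology)
  category <- match.arg(category)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  structure(list(id = id, description = description, sequence = sequence,
                 topology = topology, category = category,
                 species_label = species_label, length = nchar(sequence)),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s %s, %d bp%s\n", x$id, x$topology, x$category,
              x$length,
              if (!is.na(x$species_label)) paste0(" [", x$species_label, "]") else ""))
  invisible(x)
}

# Validate a list of replicons: unique ids, consistent fields.
check_replicon_set <- function(replicons) {
  ids <- vapply(replicons, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate replicon id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(replicons)
}

#' Reference dif site pair
#'
#' Loads the packaged 28-bp reference site pair used by the scanner. The
#' shipped file is a synthetic consensus-style pair (see the file name):
#' `CD` carries the XerC-arm/central/XerD-arm architecture read
#' left-to-right, `DC` the opposite arm order, so that the reverse complement
#' of the `CD` reference presents the `DC` arm arrangement.
#'
#' @param path FASTA file with records named `CD` and `DC`; defaults to the
#'   packaged synthetic reference pair.
#' @return named list with character elements `CD` and `DC`, each 28 bp.
#' @export
reference_sites <- function(path = system.file("extdata", "pdif_reference_synthetic.fa",
                                               package = "difmod")) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(normalize_sequence(as.character(ss)),
                   sub("\\s.*$", "", names(ss)))
  if (!all(c("CD", "DC") %in% names(seqs)))
    stop("reference FASTA must contain records named 'CD' and 'DC'")
  if (any(nchar(seqs[c("CD", "DC")]) != SITE_LEN))
    stop("reference sites must be exactly 28 bp")
  as.list(seqs[c("CD", "DC")])
}

#' Chromosomal dif1 reference
#'
#' The packaged Proteobacteria-consensus-style 28-bp dif1 sequence used to
#' separate the main chromosomal dif site from additional sites. Synthetic
#' stand-in sequence; replace via `path` for organism-specific work.
#'
#' @param path single-record FASTA; defaults to the packaged fixture.
#' @return 28-bp character scalar.
#' @export
dif1_reference <- function(path = system.file("extdata", "dif1_reference_synthetic.fa",
                                              package = "difmod")) {
  s <- normalize_sequence(as.character(Biostrings::readDNAStringSet(path))[1])
  if (nchar(s) != SITE_LEN) stop("dif1 reference must be 28 bp")
  unname(s)
}
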