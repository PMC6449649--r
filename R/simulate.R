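#' Substitute exactly k positions of a 28-bp site
#'
#' Every substituted position receives a different base, so the identity of
#' the result to `ref` is exactly `(28 - k) / 28`.
#'
#' @param ref 28-bp string.
#' @param k_mismatches number of substitutions, `0 <= k <= 28`.
#' @return mutated 28-bp string.
#' @export
mutate_site <- function(ref, k_mismatches) {
  if (nchar(ref) != SITE_LEN) stop("ref must be 28 bp")
  if (k_mismatches < 0L || k_mismatches > SITE_LEN)
    stop("k_mismatches must be in [0, 28]")
  mutate_positions(ref, k_mismatches)
}

# Substitute exactly k positions of any string to a different base.
mutate_positions <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# Random ORF of n bp (n divisible by 3, >= 9): ATG + non-stop codons + TAA.
random_orf <- function(n) {
  stopifnot(n %% 3L == 0L, n >= 9L)
  bases <- c("A", "C", "G", "T")
  n_mid <- n / 3L - 2L
  repeat_codon <- function() paste(sample(bases, 3L, replace = TRUE), collapse = "")
  mids <- character(n_mid)
  i <- 1L
  while (i <= n_mid) {
    cod <- repeat_codon()
    if (!cod %in% c("TAA", "TAG", "TGA")) { mids[i] <- cod; i <- i + 1L }
  }
  paste0("ATG", paste(mids, collapse = ""), "TAA")
}

#' Default dif-module templates
#'
#' Builds the seven module templates carried by the generator, using the
#' cargo catalog genes and spacer sequences drawn from the current RNG
#' stream. Interior layouts are sized so each template's total span
#' (two 28-bp sites + interior) matches the catalogued module lengths:
#' chrAB 3011, terC 1221, kup 2549, ohr1 1063, sulP 2159, sulP-uspA 2739,
#' add 768 bp.
#'
#' @param catalog cargo catalog from [read_cargo_catalog()].
#' @param refs reference site pair from [reference_sites()].
#' @return list of templates, each a list with `label`, `expected_label`
#'   (the [label_module()] output for an unmutated copy), `interior`,
#'   `sequence` (site + interior + site) and `span`.
#' @export
default_module_templates <- function(catalog = read_cargo_catalog(),
                                     refs = reference_sites()) {
  gene <- function(nm) catalog$reference_sequence[match(nm, catalog$name)]
  layouts <- list(
    list(label = "chrAB", genes = c("chrA", "chrB"), span = 3011L,
         expected = "chrA-chrB_dif"),
    list(label = "terC", genes = "terC", span = 1221L, expected = "terC_dif"),
    list(label = "kup", genes = c("kup", "orf210"), span = 2549L,
         expected = "kup-orf210_dif"),
    list(label = "ohr1", genes = c("ohr", "ohrR"), span = 1063L,
         expected = "ohr-ohrR_dif"),
    list(label = "sulP", genes = c("sulP", "orf198"), span = 2159L,
         expected = "sulP-orf198_dif"),
    list(label = "sulP-uspA", genes = c("sulP", "uspA"), span = 2739L,
         expected = "sulP-uspA_dif"),
    list(label = "add", genes = c("add_toxin", "add_antitoxin"), span = 768L,
         expected = "add_toxin-add_antitoxin_dif"))
  lapply(layouts, function(ly) {
    gseqs <- vapply(ly$genes, gene, "")
    if (anyNA(gseqs)) stop("catalog lacks genes for template ", ly$label)
    interior_len <- ly$span - 2L * SITE_LEN
    spare <- interior_len - sum(nchar(gseqs))
    if (spare < 0L) stop("template ", ly$label, " genes exceed its span")
    n_gaps <- length(gseqs) + 1L
    gap_len <- diff(floor(seq(0, spare, length.out = n_gaps + 1L)))
    # each gap ends with an in-frame stop so a planted gene's ORF cannot
    # extend upstream into the gap or the flanking site
    guard_gap <- function(len) {
      if (len >= 3L) paste0(random_sequence(len - 3L), "TAA")
      else random_sequence(len)
    }
    parts <- character(0)
    for (g in seq_along(gseqs))
      parts <- c(parts, guard_gap(gap_len[g]), gseqs[g])
    parts <- c(parts, random_sequence(gap_len[n_gaps]))
    interior <- paste(parts, collapse = "")
    stopifnot(nchar(interior) == interior_len)
    list(label = ly$label, expected_label = ly$expected, interior = interior,
         sequence = paste0(refs$CD, interior, refs$DC), span = ly$span)
  })
}

#' Simulation specification
#'
#' Parameters of the synthetic-replicon generator. The defaults emulate the
#' study conditions the analysis assumes: replicon lengths log-uniform on
#' 2-400 kb, GC content 0.40, per-replicon standalone site burden drawn from
#' the observed category proportions (40% zero, 43% 1-4 sites, 10% 5-8, 7%
#' more than 8), per-site divergence uniform on 0-3 mismatches of 28, and
#' replicons under 6 kb carrying no sites (category drawn first, length
#' drawn conditionally).
#'
#' @param n_replicons number of replicons; default 50.
#' @param length_range log-uniform bounds in bp; default `c(2000, 400000)`.
#' @param topology `"circular"`, `"linear"` or `"mixed"` (80% circular).
#' @param gc_content background GC fraction; default 0.40.
#' @param category_probs probabilities of the site-count categories
#'   `0`, `1-4`, `5-8`, `>8`; must sum to 1.
#' @param divergence_max standalone site mismatches drawn uniformly from
#'   `0:divergence_max`; default 3.
#' @param n_transfer_events number of module templates copied onto two
#'   distinct replicons with fresh contexts and light (~0.5%) interior
#'   mutation of the second copy; default 3.
#' @param n_resident_modules number of further templates placed exactly once
#'   (immobile controls); default 2.
#' @param seed RNG seed; default 1.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_replicons = 50L,
                            length_range = c(2000L, 400000L),
                            topology = c("circular", "linear", "mixed"),
                            gc_content = 0.40,
                            category_probs = c("0" = 0.40, "1-4" = 0.43,
                                               "5-8" = 0.10, ">8" = 0.07),
                            divergence_max = 3L,
                            n_transfer_events = 3L,
                            n_resident_modules = 2L,
                            seed = 1L) {
  topology <- match.arg(topology)
  if (abs(sum(category_probs) - 1) > 1e-9)
    stop("category_probs must sum to 1")
  if (n_transfer_events + n_resident_modules > 7L)
    stop("at most 7 module templates are available")
  structure(list(n_replicons = as.integer(n_replicons),
                 length_range = as.integer(length_range), topology = topology,
                 gc_content = gc_content, category_probs = category_probs,
                 divergence_max = as.integer(divergence_max),
                 n_transfer_events = as.integer(n_transfer_events),
                 n_resident_modules = as.integer(n_resident_modules),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Plant a module into a background replicon
#'
#' Replaces the window starting at `position` with the template sequence
#' (site + interior + site), leaving the replicon length unchanged.
#'
#' @param background a `replicon` object.
#' @param template a template from [default_module_templates()] (optionally
#'   with a mutated interior).
#' @param position 1-based start; the full span must fit unless the replicon
#'   is circular, in which case the span may wrap the origin.
#' @param occupied optional matrix of (start, end) spans already planted;
#'   overlap raises an error.
#' @return list: `replicon` (modified), `module_truth` (one-row data.frame),
#'   `site_truth` (two rows, the flanking sites).
#' @export
plant_module <- function(background, template, position, occupied = NULL) {
  L <- background$length
  span <- template$span
  end <- position + span - 1L
  if (end > L && background$topology != "circular")
    stop("module does not fit at position ", position)
  if (!is.null(occupied) && nrow(occupied)) {
    if (any(pmax(occupied[, 1], position) <= pmin(occupied[, 2], end)))
      stop("planting position overlaps a previously planted feature")
  }
  seq <- background$sequence
  if (end <= L) {
    seq <- paste0(substr(seq, 1L, position - 1L), template$sequence,
                  substr(seq, end + 1L, L))
  } else {
    tail_len <- L - position + 1L
    seq <- paste0(substr(template$sequence, tail_len + 1L, span),
                  substr(seq, end - L + 1L, position - 1L),
                  substr(template$sequence, 1L, tail_len))
  }
  rep2 <- background
  rep2$sequence <- seq
  module_truth <- data.frame(
    label = template$label, expected_label = template$expected_label,
    replicon_id = background$id, start = position, end = end, length = span,
    stringsAsFactors = FALSE)
  site_truth <- data.frame(
    replicon_id = background$id,
    start = c(position, end - SITE_LEN + 1L),
    end = c(position + SITE_LEN - 1L, end),
    orientation = c("CD", "DC"), mismatches = 0L, identity = 1,
    from_module = template$label, stringsAsFactors = FALSE)
  list(replicon = rep2, module_truth = module_truth, site_truth = site_truth)
}

#' Generate a synthetic replicon dataset with planted ground truth
#'
#' Backgrounds are i.i.d. nucleotide sequences at the specified GC content.
#' Standalone sites are planted at controlled divergence from the reference
#' pair (exact mismatch counts, random orientation), spaced at least 28 bp
#' apart. Module templates are planted on eligible replicons; the templates
#' subject to a transfer event receive a second copy on a different replicon
#' with ~0.5% interior substitutions and necessarily fresh flanking context.
#' Deterministic for a fixed seed.
#'
#' @param spec a [simulation_spec()].
#' @param refs reference site pair.
#' @param catalog cargo catalog used to build module templates.
#' @param out_dir optional directory; when given, writes `replicons.fa`,
#'   `sites_truth.tsv`, `modules_truth.tsv`, `replicons.tsv` and
#'   `spec.json`.
#' @return list with `replicons` (list of `replicon`), `sites` (planted-site
#'   truth), `modules` (planted-module truth with `transfer_id`),
#'   `replicon_table` (id, length, topology, category drawn, species).
#' @export
generate_dataset <- function(spec = simulation_spec(), refs = reference_sites(),
                             catalog = read_cargo_catalog(), out_dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_replicons
    cats <- sample(names(spec$category_probs), n, replace = TRUE,
                   prob = spec$category_probs)
    counts <- vapply(cats, function(cc) switch(cc,
      "0" = 0L, "1-4" = sample(1:4, 1L), "5-8" = sample(5:8, 1L),
      ">8" = sample(9:16, 1L)), 1L)
    lo <- spec$length_range[1]; hi <- spec$length_range[2]
    lens <- integer(n)
    for (i in seq_len(n)) {
      lmin <- if (counts[i] > 0L) max(lo, 6000L) else lo
      lens[i] <- as.integer(round(exp(runif(1, log(lmin), log(hi)))))
    }
    topo <- switch(spec$topology,
                   circular = rep("circular", n), linear = rep("linear", n),
                   mixed = sample(c("circular", "linear"), n, replace = TRUE,
                                  prob = c(0.8, 0.2)))
    species_pool <- c("A. lwoffii", "A. baumannii", "A. pseudolwoffii",
                      "A. johnsonii", "A. towneri")
    species <- sample(species_pool, n, replace = TRUE)
    ids <- sprintf("synth_p%03d", seq_len(n))
    reps <- lapply(seq_len(n), function(i)
      replicon(ids[i], random_sequence(lens[i], spec$gc_content),
               topology = topo[i], category = "plasmid",
               species_label = species[i],
               description = sprintf("synthetic plasmid %d", i)))
    names(reps) <- ids

    occupied <- lapply(seq_len(n), function(i) matrix(numeric(0), 0, 2))
    site_rows <- list(); module_rows <- list()

    place_span <- function(i, span, margin = SITE_LEN) {
      # rejection-sample a non-wrapping start leaving `margin` bp to other features
      L <- lens[i]
      for (try in 1:200) {
        pos <- sample.int(L - span + 1L, 1L)
        occ <- occupied[[i]]
        if (!nrow(occ) || all(pmax(occ[, 1] - margin, pos) >
                                pmin(occ[, 2] + margin, pos + span - 1L))) {
          occupied[[i]] <<- rbind(occ, c(pos, pos + span - 1L))
          return(pos)
        }
      }
      NA_integer_
    }

    # --- modules ---
    templates <- default_module_templates(catalog, refs)
    n_templ <- spec$n_transfer_events + spec$n_resident_modules
    use <- templates[seq_len(n_templ)]
    transfer_id <- 0L
    for (t in seq_along(use)) {
      tm <- use[[t]]
      is_transfer <- t <= spec$n_transfer_events
      eligible <- which(lens >= max(8000L, tm$span + 1200L))
      n_copies <- if (is_transfer) 2L else 1L
      if (length(eligible) < n_copies)
        stop("not enough replicons large enough to host template ", tm$label)
      hosts <- eligible[sample.int(length(eligible), n_copies)]
      if (is_transfer) transfer_id <- transfer_id + 1L
      for (ci in seq_len(n_copies)) {
        tm_i <- tm
        if (ci == 2L) {  # mutate the transferred copy's interior (~0.5%)
          k <- max(1L, round(0.005 * nchar(tm$interior)))
          tm_i$interior <- mutate_positions(tm$interior, k)
          tm_i$sequence <- paste0(refs$CD, tm_i$interior, refs$DC)
        }
        h <- hosts[ci]
        pos <- place_span(h, tm_i$span, margin = 600L)
        if (is.na(pos)) next
        pl <- plant_module(reps[[h]], tm_i, pos)
        reps[[h]] <- pl$replicon
        pl$module_truth$transfer_id <- if (is_transfer) transfer_id else NA_integer_
        pl$module_truth$copy <- ci
        module_rows[[length(module_rows) + 1L]] <- pl$module_truth
        site_rows[[length(site_rows) + 1L]] <- pl$site_truth
      }
    }

    # --- standalone sites ---
    for (i in seq_len(n)) {
      if (counts[i] == 0L) next
      for (s in seq_len(counts[i])) {
        pos <- place_span(i, SITE_LEN)
        if (is.na(pos)) next
        k <- sample(0:spec$divergence_max, 1L)
        orient <- sample(c("CD", "DC"), 1L)
        site_seq <- mutate_site(refs[[orient]], k)
        reps[[i]]$sequence <- paste0(
          substr(reps[[i]]$sequence, 1L, pos - 1L), site_seq,
          substr(reps[[i]]$sequence, pos + SITE_LEN, lens[i]))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          replicon_id = ids[i], start = pos, end = pos + SITE_LEN - 1L,
          orientation = orient, mismatches = k, identity = (SITE_LEN - k) / SITE_LEN,
          from_module = NA_character_, stringsAsFactors = FALSE)
      }
    }

    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(replicon_id = character(0), start = integer(0),
                 end = integer(0), orientation = character(0),
                 mismatches = integer(0), identity = numeric(0),
                 from_module = character(0), stringsAsFactors = FALSE)
    modules <- if (length(module_rows)) do.call(rbind, module_rows) else
      data.frame(label = character(0), expected_label = character(0),
                 replicon_id = character(0), start = integer(0),
                 end = integer(0), length = integer(0),
                 transfer_id = integer(0), copy = integer(0),
                 stringsAsFactors = FALSE)
    sites <- sites[order(sites$replicon_id, sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    replicon_table <- data.frame(replicon_id = ids, length = lens,
                                 topology = topo, category = cats,
                                 n_planted_standalone = unname(counts),
                                 species_label = species,
                                 stringsAsFactors = FALSE)
    result <- list(replicons = reps, sites = sites, modules = modules,
                   replicon_table = replicon_table, spec = spec)
    if (!is.null(out_dir)) write_dataset(result, out_dir)
    result
  })
}

# Write a generated dataset to disk (FASTA + truth TSVs + spec echo).
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(vapply(dataset$replicons, `[[`, "", "sequence"))
  names(ss) <- vapply(dataset$replicons, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, file.path(out_dir, "replicons.fa"))
  utils::write.table(dataset$sites, file.path(out_dir, "sites_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$modules, file.path(out_dir, "modules_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$replicon_table, file.path(out_dir, "replicons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dataset$spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
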