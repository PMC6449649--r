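IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Per-position nucleotide profile of a site group
#'
#' Builds the 28 x 4 count and frequency matrices, per-position information
#' content (2 minus Shannon entropy, bits) and a consensus string for a
#' group of orientation-normalised sites. Sites carrying `N` at a position
#' are excluded from that position's denominator. The region annotation is
#' fixed: XerC arm = positions 1-11, central = 12-17, XerD arm = 18-28 in
#' site-intrinsic orientation.
#'
#' @param sites site table (their intrinsic sequences are profiled), or a
#'   character vector of 28-bp sequences.
#' @param group_label label carried on the profile.
#' @param small_sample_correction subtract the standard small-sample entropy
#'   correction `(4-1) / (2 ln 2 n)` bits from the information content
#'   (floored at 0); default FALSE.
#' @return object of class `position_profile`: list with `group_label`,
#'   `n_sites`, `counts` (28 x 4), `frequencies` (28 x 4), `info_content`
#'   (28 values in bits), `consensus` (28 characters, ties as IUPAC codes)
#'   and `regions` (list of position indices).
#' @export
build_profile <- function(sites, group_label = "sites",
                          small_sample_correction = FALSE) {
  seqs <- if (is.character(sites)) toupper(sites) else intrinsic_site_seqs(sites)
  if (length(seqs) == 0L) stop("build_profile requires at least one site")
  if (any(nchar(seqs) != SITE_LEN)) stop("all site sequences must be 28 bp")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = bases))
    as.integer(tab)
  }))
  colnames(counts) <- bases
  denom <- rowSums(counts)
  if (any(denom == 0L)) stop("a position has no non-N characters")
  freqs <- counts / denom
  H <- apply(freqs, 1L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  info <- 2 - H
  if (small_sample_correction) {
    corr <- 3 / (2 * log(2) * denom)
    info <- pmax(info - corr, 0)
  }
  consensus <- apply(freqs, 1L, function(f) {
    top <- bases[f == max(f)]
    IUPAC_CODES[[paste(sort(top), collapse = "")]]
  })
  structure(list(group_label = group_label, n_sites = length(seqs),
                 counts = counts, frequencies = freqs, info_content = info,
                 consensus = paste(consensus, collapse = ""),
                 regions = list(xerC_arm = XERC_ARM, central = CENTRAL,
                                xerD_arm = XERD_ARM)),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> %s: %d sites\n consensus: %s\n mean info: %.2f bits\n",
              x$group_label, x$n_sites, x$consensus, mean(x$info_content)))
  invisible(x)
}

# Jensen-Shannon divergence (base 2) between two frequency vectors.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  h <- function(f) { f <- f[f > 0]; -sum(f * log2(f)) }
  h(m) - (h(p) + h(q)) / 2
}

#' Compare two position profiles
#'
#' Per-position Jensen-Shannon divergence (base 2, in `[0, 1]`) between the
#' frequency rows, plus mean divergence per site region.
#'
#' @param a,b `position_profile` objects.
#' @return list with `per_position` (28 JSD values) and `region_means`
#'   (named vector: xerC_arm, central, xerD_arm).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "position_profile"), inherits(b, "position_profile"))
  jsd <- vapply(seq_len(SITE_LEN), function(p)
    jsd2(a$frequencies[p, ], b$frequencies[p, ]), 0)
  region_means <- vapply(a$regions, function(idx) mean(jsd[idx]), 0)
  list(per_position = jsd, region_means = region_means)
}

#' Rank comparison profiles by similarity
#'
#' For a focal profile and two or more others, orders the others by mean
#' per-position Jensen-Shannon divergence (most similar first).
#'
#' @param focal `position_profile`.
#' @param others named list of `position_profile` objects.
#' @return data.frame: `group`, `mean_jsd`, `central_jsd`, ordered by
#'   increasing `mean_jsd`.
#' @export
similarity_ordering <- function(focal, others) {
  rows <- lapply(names(others), function(nm) {
    cmp <- compare_profiles(focal, others[[nm]])
    data.frame(group = nm, mean_jsd = mean(cmp$per_position),
               central_jsd = cmp$region_means[["central"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_jsd), , drop = FALSE]
}

#' Region conservation ranking of a profile
#'
#' Mean information content for the XerC arm, central region and XerD arm,
#' and a check of the ordering expected for dif sites: the XerD arm at least
#' as conserved as the XerC arm, both at least as conserved as the central
#' region.
#'
#' @param profile `position_profile` built from >= 2 sites for a meaningful
#'   check (single-site profiles are uniformly 2 bits).
#' @return list with `region_info` (named means, bits) and
#'   `expected_ordering` (logical: XerD >= XerC >= central).
#' @export
conservation_ranking <- function(profile) {
  stopifnot(inherits(profile, "position_profile"))
  region_info <- vapply(profile$regions, function(idx)
    mean(profile$info_content[idx]), 0)
  list(region_info = region_info,
       expected_ordering = region_info[["xerD_arm"]] >= region_info[["xerC_arm"]] &&
         region_info[["xerC_arm"]] >= region_info[["central"]])
}

#' Serialise profiles to JSON
#'
#' @param profiles named list of `position_profile` objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  obj <- lapply(profiles, function(p)
    list(group_label = p$group_label, n_sites = p$n_sites,
         counts = p$counts, frequencies = p$frequencies,
         info_content = p$info_content, consensus = p$consensus))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
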