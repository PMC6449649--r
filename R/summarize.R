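BURDEN_CATEGORIES <- c("0", "1-4", "5-8", ">8")

site_count_category <- function(n) {
  cut(n, breaks = c(-0.5, 0.5, 4.5, 8.5, Inf), labels = BURDEN_CATEGORIES)
}

#' Site-burden table across replicon groups
#'
#' Counts replicons per group falling into the site-count categories
#' 0, 1-4, 5-8 and >8, with percentages (one decimal, half-up) and a totals
#' row aggregating all groups.
#'
#' @param site_counts named integer vector: replicon id -> site count.
#' @param groups named character vector: replicon id -> group label; every
#'   replicon in `site_counts` must be assigned a group.
#' @return data.frame with one row per group plus a `"Total"` row; columns
#'   `group`, then `n_<cat>` and `pct_<cat>` per category, then `total`.
#' @export
burden_table <- function(site_counts, groups) {
  ids <- names(site_counts)
  if (is.null(ids) || !all(ids %in% names(groups)))
    stop("every replicon in site_counts needs a group assignment")
  grp <- factor(groups[ids])
  cat_ <- site_count_category(site_counts)
  tab <- table(grp, cat_)
  tab <- rbind(tab, Total = colSums(tab))
  totals <- rowSums(tab)
  out <- data.frame(group = rownames(tab), stringsAsFactors = FALSE)
  cnames <- c("0" = "0", "1-4" = "1_4", "5-8" = "5_8", ">8" = "gt8")
  for (cc in BURDEN_CATEGORIES) {
    cname <- cnames[[cc]]
    out[[paste0("n_", cname)]] <- as.integer(tab[, cc])
    out[[paste0("pct_", cname)]] <- round_half_up1(100 * tab[, cc] / totals)
  }
  out$total <- as.integer(totals)
  rownames(out) <- NULL
  out
}

#' Plasmid size histogram with site-presence split
#'
#' @param replicons list of `replicon` objects.
#' @param site_counts named integer vector: replicon id -> site count
#'   (replicons absent from the vector count as 0 sites).
#' @param bin_edges strictly increasing bp edges; replicons outside every
#'   bin are counted in an `overflow` bin. Default edges follow the sub-6 kb
#'   / 6-30 kb size classes discussed for Acinetobacter plasmids:
#'   0, 6, 10, 20, 30, 50, 100, 200, 400 kb.
#' @return data.frame: `bin` (label), `total`, `with_sites`.
#' @export
size_histogram <- function(replicons, site_counts,
                           bin_edges = c(0, 6e3, 1e4, 2e4, 3e4, 5e4, 1e5, 2e5, 4e5)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  lens <- vapply(replicons, `[[`, 0, "length")
  ids <- vapply(replicons, `[[`, "", "id")
  has <- ids %in% names(site_counts) & site_counts[ids] > 0
  has[is.na(has)] <- FALSE
  nb <- length(bin_edges) - 1L
  labels <- sprintf("(%g,%g]", bin_edges[-length(bin_edges)], bin_edges[-1])
  idx <- findInterval(lens, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  # findInterval: 0 => below first edge -> overflow; nb+1 => above last edge
  overflow <- idx < 1L | idx > nb
  total <- tabulate(idx[!overflow], nbins = nb)
  with_sites <- tabulate(idx[!overflow & has], nbins = nb)
  out <- data.frame(bin = c(labels, "overflow"),
                    total = c(total, sum(overflow)),
                    with_sites = c(with_sites, sum(overflow & has)),
                    stringsAsFactors = FALSE)
  out
}

#' Replicons carrying multiple sites
#'
#' Lists replicons whose total site count exceeds `cutoff` (default 10,
#' i.e. > 10 sites), with per-orientation counts, sorted by strain then
#' replicon id.
#'
#' @param scans data.frame with columns `replicon_id`, `strain` (optional),
#'   `length`, `n_CD`, `n_DC` -- see [orientation_count_table()].
#' @param cutoff inclusion requires `n_CD + n_DC > cutoff`.
#' @return the qualifying rows, sorted.
#' @export
multi_site_report <- function(scans, cutoff = 10L) {
  total <- scans$n_CD + scans$n_DC
  out <- scans[total > cutoff, , drop = FALSE]
  key1 <- if ("strain" %in% names(out)) out$strain else out$replicon_id
  out <- out[order(key1, out$replicon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-replicon orientation count table
#'
#' @param sites combined site table from [scan_replicons()].
#' @param replicons list of `replicon` objects (provides lengths and zero
#'   rows for site-free replicons).
#' @return data.frame: `replicon_id`, `length`, `n_CD`, `n_DC`.
#' @export
orientation_count_table <- function(sites, replicons) {
  ids <- vapply(replicons, `[[`, "", "id")
  lens <- vapply(replicons, `[[`, 0, "length")
  n_cd <- vapply(ids, function(i)
    sum(sites$replicon_id == i & sites$orientation == "CD"), 0L)
  n_dc <- vapply(ids, function(i)
    sum(sites$replicon_id == i & sites$orientation == "DC"), 0L)
  data.frame(replicon_id = ids, length = lens, n_CD = n_cd, n_DC = n_dc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Site position map of one replicon
#'
#' Reports the ordered site positions, the fraction of sites whose midpoint
#' falls inside user-supplied backbone intervals, and the number of
#' site-dense clusters (maximal runs of consecutive sites with inter-site
#' gap at most `cluster_gap`, merged across the origin on circular
#' replicons).
#'
#' @param replicon a `replicon` object.
#' @param sites site table for that replicon.
#' @param backbone_intervals optional two-column matrix/data.frame of
#'   1-based inclusive (start, end) backbone spans.
#' @param cluster_gap maximum intra-cluster gap in bp; default 5000.
#' @return list with `replicon_id`, `positions` (site midpoints, sorted),
#'   `backbone_fraction` (`NA` when no backbone supplied) and `n_clusters`.
#' @export
position_map <- function(replicon, sites, backbone_intervals = NULL,
                         cluster_gap = 5000L) {
  stopifnot(inherits(replicon, "replicon"))
  mids <- sort((sites$start + sites$end) / 2)
  frac <- NA_real_
  if (!is.null(backbone_intervals)) {
    bi <- as.matrix(backbone_intervals)
    if (nrow(bi) && (any(bi[, 1] < 1) || any(bi[, 2] > replicon$length)))
      stop("backbone intervals outside replicon bounds")
    if (length(mids)) {
      inside <- vapply(mids, function(m)
        any(m >= bi[, 1] & m <= bi[, 2]), TRUE)
      frac <- mean(inside)
    }
  }
  n_sites <- length(mids)
  n_clusters <- if (n_sites == 0L) 0L else if (n_sites == 1L) 1L else {
    gaps <- diff(mids)
    k <- 1L + sum(gaps > cluster_gap)
    if (replicon$topology == "circular" && k > 1L) {
      wrap_gap <- replicon$length - mids[n_sites] + mids[1]
      if (wrap_gap <= cluster_gap) k <- k - 1L
    }
    k
  }
  list(replicon_id = replicon$id, positions = mids,
       backbone_fraction = frac, n_clusters = n_clusters)
}
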