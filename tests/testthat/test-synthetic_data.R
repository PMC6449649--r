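test_that("site mutation realises exact mismatch counts", {
  withr_seed(401, {
    expect_equal(mutate_site(REFS$CD, 0), REFS$CD)
    m7 <- mutate_site(REFS$CD, 7)
    expect_equal(identity28(m7, REFS$CD), 21 / 28)
    m28 <- mutate_site(REFS$CD, 28)
    expect_equal(identity28(m28, REFS$CD), 0)
  })
  expect_error(mutate_site(REFS$CD, 29), "0, 28")
  expect_error(mutate_site(REFS$CD, -1), "0, 28")
})

test_that("module planting records exact spans and flanking sites", {
  withr_seed(402, {
    templates <- default_module_templates(CATALOG, REFS)
    terc <- templates[[which(vapply(templates, `[[`, "", "label") == "terC")]]
    expect_equal(terc$span, 1221L)
    expect_equal(nchar(terc$sequence), 1221L)

    bg <- replicon("host", random_bg(10000), "circular", "plasmid")
    pl <- plant_module(bg, terc, 2001L)
    expect_equal(pl$replicon$length, 10000L)
    expect_equal(pl$module_truth$start, 2001L)
    expect_equal(pl$module_truth$end, 2001L + 1221L - 1L)
    expect_equal(substr(pl$replicon$sequence, 2001, 2028), REFS$CD)
    expect_equal(pl$site_truth$orientation, c("CD", "DC"))

    # second template on the same replicon, overlap rejected
    add <- templates[[which(vapply(templates, `[[`, "", "label") == "add")]]
    occ <- as.matrix(pl$module_truth[, c("start", "end")])
    pl2 <- plant_module(pl$replicon, add, 6001L, occupied = occ)
    expect_equal(pl2$module_truth$length, 768L)
    expect_error(plant_module(pl$replicon, add, 2100L, occupied = occ),
                 "overlap")

    # wrap planting splits across the origin
    plw <- plant_module(bg, add, 10000L - 100L)
    expect_equal(plw$module_truth$end - plw$module_truth$start + 1L, 768L)
    expect_true(plw$module_truth$end > 10000L)
    expect_equal(substr(plw$replicon$sequence, 9900, 9927), REFS$CD)
  })
})

test_that("dataset generation is deterministic for a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  spec <- simulation_spec(n_replicons = 8, seed = 11,
                          length_range = c(2000L, 30000L))
  generate_dataset(spec, out_dir = d1)
  generate_dataset(spec, out_dir = d2)
  for (f in c("replicons.fa", "sites_truth.tsv", "modules_truth.tsv",
              "replicons.tsv", "spec.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  other <- generate_dataset(simulation_spec(n_replicons = 8, seed = 12,
                                            length_range = c(2000L, 30000L)))
  ds <- generate_dataset(spec)
  expect_false(identical(ds$replicons[[1]]$sequence,
                         other$replicons[[1]]$sequence))
})

test_that("a site-free dataset yields almost no scanner hits (analytic bound)", {
  spec <- simulation_spec(n_replicons = 10, seed = 21,
                          length_range = c(5000L, 20000L),
                          category_probs = c("0" = 1, "1-4" = 0, "5-8" = 0,
                                             ">8" = 0),
                          n_transfer_events = 0L, n_resident_modules = 0L)
  ds <- generate_dataset(spec)
  expect_equal(nrow(ds$sites), 0)
  sites <- scan_replicons(ds$replicons)
  # Analytic false-hit oracle: per-position match probability for a random
  # background letter equals the background frequency of the reference base;
  # the chance a window reaches >= 21/28 is the Poisson-binomial tail,
  # bounded here by the binomial tail at the per-reference mean match
  # probability. Expected hits = tail x windows x 4 variants.
  total_bp <- sum(vapply(ds$replicons, `[[`, 0, "length"))
  p_match <- function(ref) {
    freq <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    mean(freq[strsplit(ref, "")[[1]]])
  }
  lambda <- sum(vapply(c(REFS$CD, REFS$DC, revcomp(REFS$CD), revcomp(REFS$DC)),
                       function(r) {
                         pbinom(20, 28, p_match(r), lower.tail = FALSE) * total_bp
                       }, 0))
  expect_lt(lambda, 1)  # the design keeps the expected false-hit count tiny
  expect_lte(nrow(sites), qpois(1 - 1e-6, lambda))
})

test_that("transfer events put the requested module labels on two replicons", {
  ds <- generate_dataset(simulation_spec(n_replicons = 15, seed = 31,
                                         length_range = c(6000L, 50000L),
                                         n_transfer_events = 3L,
                                         n_resident_modules = 2L))
  mt <- ds$modules
  transferred <- unique(mt$label[!is.na(mt$transfer_id)])
  expect_length(transferred, 3)
  for (lb in transferred)
    expect_equal(length(unique(mt$replicon_id[mt$label == lb])), 2)
  residents <- mt[is.na(mt$transfer_id), ]
  expect_equal(nrow(residents), 2)
})

test_that("generated category proportions match the specification", {
  spec <- simulation_spec(n_replicons = 1000, seed = 41,
                          length_range = c(2000L, 12000L),
                          n_transfer_events = 0L, n_resident_modules = 0L)
  ds <- generate_dataset(spec)
  obs <- table(factor(ds$replicon_table$category,
                      levels = names(spec$category_probs)))
  gof <- suppressWarnings(chisq.test(obs, p = spec$category_probs))
  expect_gt(gof$p.value, 0.01)
  # planted standalone counts respect their category ranges
  tab <- ds$replicon_table
  expect_true(all(tab$n_planted_standalone[tab$category == "0"] == 0))
  expect_true(all(tab$n_planted_standalone[tab$category == "1-4"] %in% 1:4))
  expect_true(all(tab$n_planted_standalone[tab$category == "5-8"] %in% 5:8))
  expect_true(all(tab$n_planted_standalone[tab$category == ">8"] > 8))
})

test_that("planted truth is recovered end-to-end across seeds", {
  for (seed in 1:5) {
    spec <- simulation_spec(n_replicons = 10, seed = seed,
                            length_range = c(6000L, 40000L),
                            n_transfer_events = 2L, n_resident_modules = 1L)
    ds <- generate_dataset(spec)
    sites <- scan_replicons(ds$replicons)
    truth_key <- paste(ds$sites$replicon_id, ds$sites$start, ds$sites$orientation)
    got_key <- paste(sites$replicon_id, sites$start, sites$orientation)
    expect_true(all(truth_key %in% got_key), label = paste("site recall seed", seed))

    mods <- do.call(rbind, lapply(ds$replicons, function(r)
      call_modules(sites[sites$replicon_id == r$id, , drop = FALSE], r)))
    span_key <- paste(mods$replicon_id, mods$start, mods$end)
    truth_span <- paste(ds$modules$replicon_id, ds$modules$start, ds$modules$end)
    expect_true(all(truth_span %in% span_key),
                label = paste("module spans seed", seed))

    occ <- module_occurrences(mods, ds$replicons)
    calls <- assess_all_families(occ)
    mobile_spans <- unlist(lapply(calls[vapply(calls, `[[`, TRUE, "is_mobile")],
                                  function(cl) {
                                    m <- occ[cl$members, , drop = FALSE]
                                    paste(m$replicon_id, m$start, m$end)
                                  }))
    planted_mobile <- truth_span[!is.na(ds$modules$transfer_id)]
    # every planted transferred copy sits in a mobile family, and mobile
    # families contain nothing but planted transferred copies
    expect_true(all(planted_mobile %in% mobile_spans),
                label = paste("mobility recall seed", seed))
    expect_true(all(mobile_spans %in% planted_mobile),
                label = paste("mobility precision seed", seed))
  }
})
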