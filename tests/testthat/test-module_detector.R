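# A synthetic terC-like module: CD site + interior carrying the 978-bp
# catalog terC ORF + DC site, with a total span of 1221 bp.
make_terc_module <- function() {
  terc <- CATALOG$reference_sequence[CATALOG$name == "terC"]
  interior_len <- 1221L - 56L
  pad <- interior_len - nchar(terc)
  # left pad ends with an in-frame stop so the cargo ORF starts exactly at ATG
  left_pad <- paste0(withr_seed(61, random_bg(97)), "TAA")
  right_pad <- withr_seed(62, random_bg(pad - 100))
  insert <- paste0(REFS$CD, left_pad, terc, right_pad, REFS$DC)
  stopifnot(nchar(insert) == 1221L)
  insert
}

test_that("ORF finder reports constructed ORFs with exact boundaries", {
  # ATG + 98 sense codons + TAA = 300 bp, preceded by an in-frame stop guard
  orf300 <- paste0("ATG", strrep("GCTGAA", 49), "TAA")
  expect_equal(nchar(orf300), 300L)
  seq <- plant_in_background(paste0("TAA", orf300), bg_len = 700L, at = 198L,
                             seed = 8)
  orfs <- find_orfs(seq, min_len = 150L)
  hit <- orfs[orfs$start == 201 & orfs$end == 500, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length, 300L)
  expect_equal(hit$strand, "+")
  expect_equal(substr(hit$translation, 1, 3), "MAE")

  # homopolymer sequence has no ORFs
  expect_equal(nrow(find_orfs(strrep("A", 2000), min_len = 150L)), 0)
  expect_error(find_orfs("ACGT", min_len = 30L), ">= 60")
})

test_that("the planted 978-bp cargo ORF is recovered exactly inside its module", {
  insert <- make_terc_module()
  seq <- plant_in_background(insert, bg_len = 3000L, at = 1001L, seed = 9)
  orfs <- find_orfs(seq, min_len = 150L)
  # terC starts 28 (site) + 100 (pad) after the module start
  terc_start <- 1001L + 28L + 100L
  hit <- orfs[orfs$start == terc_start & orfs$length == 978L, ]
  expect_equal(nrow(hit), 1)
})

test_that("module calling spans consecutive site pairs inclusively", {
  insert <- make_terc_module()
  seq <- plant_in_background(insert, bg_len = 3000L, at = 1001L, seed = 9)
  r <- replicon("pTer", seq, "linear", "plasmid")
  sites <- scan_replicon(r, REFS)
  mods <- call_modules(sites, r)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$start, 1001L)
  expect_equal(mods$end, 1001L + 1221L - 1L)
  expect_equal(mods$length, 1221L)
  expect_equal(mods$length, mods$end - mods$start + 1L)
  expect_equal(nchar(mods$module_sequence), mods$length)
  expect_equal(mods$left_orientation, "CD")
  expect_equal(mods$right_orientation, "DC")
  orfs <- mods$cargo_orfs[[1]]
  expect_true(any(orfs$length == 978L))
})

test_that("the span cap and the two-site requirement are enforced", {
  # two sites 30 kb apart exceed the 20-kb default cap
  seq <- withr_seed(71, {
    bg <- random_bg(31000)
    bg <- paste0(substr(bg, 1, 100), REFS$CD, substr(bg, 129, 31000))
    paste0(substr(bg, 1, 30100), REFS$DC, substr(bg, 30129, 31000))
  })
  r <- replicon("far", seq, "linear", "plasmid")
  sites <- scan_replicon(r, REFS)
  expect_gte(nrow(sites), 2)
  mods <- call_modules(sites, r, require_orf = FALSE)
  expect_equal(nrow(mods), 0)

  # fewer than two sites: no modules
  one <- scan_replicon(replicon("one", plant_in_background(REFS$CD, 500, 101, 3),
                                "linear", "plasmid"), REFS)
  expect_equal(nrow(call_modules(one, replicon("one", strrep("A", 500),
                                               "linear", "plasmid"))), 0)
})

test_that("three sites on a linear replicon give at most two candidates", {
  seq <- withr_seed(72, {
    bg <- random_bg(3000)
    for (pos in c(101, 1101, 2101)) bg <- paste0(substr(bg, 1, pos - 1),
                                                 REFS$CD, substr(bg, pos + 28, 3000))
    bg
  })
  r <- replicon("three", seq, "linear", "plasmid")
  sites <- scan_replicon(r, REFS)
  expect_equal(nrow(sites), 3)
  mods <- call_modules(sites, r, require_orf = FALSE)
  expect_lte(nrow(mods), 2)
  expect_equal(mods$start, sites$start[-3])
})

test_that("require_orf drops candidates without cargo", {
  # two sites 200 bp apart over a stop-rich interior: no ORF >= 150
  interior <- strrep("TAATAG", 24)  # 144 bp of stops
  seq <- plant_in_background(paste0(REFS$CD, interior, REFS$DC),
                             bg_len = 800L, at = 201L, seed = 12)
  r <- replicon("noorf", seq, "linear", "plasmid")
  sites <- scan_replicon(r, REFS)
  expect_equal(nrow(sites), 2)
  expect_equal(nrow(call_modules(sites, r, require_orf = TRUE)), 0)
  expect_equal(nrow(call_modules(sites, r, require_orf = FALSE)), 1)
})

test_that("mutating one flanking site below threshold removes its module", {
  insert <- make_terc_module()
  seq <- plant_in_background(insert, bg_len = 3000L, at = 1001L, seed = 9)
  r <- replicon("pTer", seq, "linear", "plasmid")
  mods <- call_modules(scan_replicon(r, REFS), r)
  expect_equal(nrow(mods), 1)
  # destroy the right (DC) flanking site with 9 substitutions
  broken_dc <- substitute_k(REFS$DC, 9, seed = 13)
  seq2 <- paste0(substr(seq, 1, 1001L + 1221L - 28L - 1L), broken_dc,
                 substr(seq, 1001L + 1221L, 3000L))
  r2 <- replicon("pTer2", seq2, "linear", "plasmid")
  mods2 <- call_modules(scan_replicon(r2, REFS), r2)
  expect_equal(nrow(mods2), 0)
})

test_that("catalog labelling names cargo in coordinate order", {
  insert <- make_terc_module()
  seq <- plant_in_background(insert, bg_len = 3000L, at = 1001L, seed = 9)
  r <- replicon("pTer", seq, "linear", "plasmid")
  mods <- call_modules(scan_replicon(r, REFS), r)
  expect_equal(label_module(mods[1, ], CATALOG), "terC_dif")

  # two-gene cargo: sulP then uspA
  sulp <- CATALOG$reference_sequence[CATALOG$name == "sulP"]
  uspa <- CATALOG$reference_sequence[CATALOG$name == "uspA"]
  gap <- withr_seed(63, random_bg(60))
  insert2 <- paste0(REFS$CD, gap, sulp, gap, uspa, gap, REFS$DC)
  seq2 <- plant_in_background(insert2, bg_len = 4000L, at = 501L, seed = 14)
  r2 <- replicon("pSulp", seq2, "linear", "plasmid")
  mods2 <- call_modules(scan_replicon(r2, REFS), r2)
  expect_equal(nrow(mods2), 1)
  expect_equal(label_module(mods2[1, ], CATALOG), "sulP-uspA_dif")

  # random cargo matches nothing
  rand_orf <- paste0("ATG", strrep("GCA", 100), "TAA")
  insert3 <- paste0(REFS$CD, rand_orf, REFS$DC)
  seq3 <- plant_in_background(insert3, bg_len = 1500L, at = 301L, seed = 15)
  r3 <- replicon("pRand", seq3, "linear", "plasmid")
  mods3 <- call_modules(scan_replicon(r3, REFS), r3)
  expect_equal(label_module(mods3[1, ], CATALOG), "unlabeled")

  # a ~99%-identical terC copy still labels as terC_dif
  mut <- mods[1, ]
  mut$module_sequence <- substitute_k(mut$module_sequence, 12, seed = 16)
  expect_equal(label_module(mut, CATALOG), "terC_dif")
})

test_that("overlapping sites violate the scanner contract", {
  sites <- data.frame(replicon_id = "x", start = c(100L, 110L),
                      end = c(127L, 137L), orientation = c("CD", "CD"),
                      identity = 1, matched_reference = "CD",
                      sequence = REFS$CD, xerC_arm = "a", central = "b",
                      xerD_arm = "c", stringsAsFactors = FALSE)
  expect_error(call_modules(sites, replicon("x", strrep("A", 500), "linear",
                                            "plasmid")), "overlap")
})
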