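test_that("variant LAF follows the folded allele-fraction definition", {
  expect_equal(variant_laf(50, 50), 0.5)
  expect_equal(variant_laf(0, 100), 0)
  expect_equal(variant_laf(25, 75), 0.25)
  expect_true(is.na(variant_laf(0, 0)))
  expect_error(variant_laf(-1, 5), "non-negative")
})

test_that("LAF windows take the median of fully called variants and tile the chromosome", {
  ci <- toy_chrom_info(c(chr1 = 3.5e5))
  v <- data.frame(chrom = "chr1",
                  pos = c(10, 20, 30, 150000, 210000),
                  ref = "A", alt = "G",
                  zygosity = c("het", "het", "hom", "het", "half-called"),
                  ref_depth = c(50, 40, 0, 30, 50),
                  alt_depth = c(50, 60, 100, 70, 50),
                  stringsAsFactors = FALSE)
  w <- compute_laf_windows(v, ci, bin = 1e5)
  expect_equal(nrow(w), 4)           # 3.5e5 tiled at 100 kb, partial kept
  expect_equal(w$end, c(1e5, 2e5, 3e5, 3.5e5))
  expect_equal(w$laf[1], 0.4)        # median of {0.5, 0.4, 0.0}
  expect_equal(w$laf[2], 0.3)
  expect_equal(w$n_variants[3], 0)   # half-called excluded
  expect_true(is.na(w$laf[3]))
  expect_true(is.na(w$laf[4]))

  no_depth <- v[, c("chrom", "pos", "ref", "alt", "zygosity")]
  expect_error(compute_laf_windows(no_depth, ci), "depth")
})

test_that("binomial sampling keeps balanced-het window LAF near 0.5", {
  set.seed(99)
  n <- 3000
  ci <- toy_chrom_info(c(chr1 = 3e6))
  v <- data.frame(chrom = "chr1", pos = sort(sample.int(3e6, n)),
                  ref = "A", alt = "G", zygosity = "het",
                  stringsAsFactors = FALSE)
  depth <- rpois(n, 100)
  v$alt_depth <- rbinom(n, depth, 0.5)
  v$ref_depth <- depth - v$alt_depth
  w <- compute_laf_windows(v, ci, bin = 1e5)
  frac_ok <- mean(w$laf >= 0.4 & w$laf <= 0.5, na.rm = TRUE)
  expect_gte(frac_ok, 0.95)
})

test_that("LOH segmentation enforces the strict >10 Mb rule", {
  w <- laf_frame(rep(0, 120))              # 12 Mb of zero LAF
  seg <- segment_loh(w)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 12e6)

  expect_equal(nrow(segment_loh(laf_frame(rep(0, 90)))), 0)    # 9 Mb
  expect_equal(nrow(segment_loh(laf_frame(rep(0, 100)))), 0)   # exactly 10 Mb
  expect_equal(nrow(segment_loh(laf_frame(rep(0.5, 150)))), 0)
})

test_that("variant-free gaps are bridged up to max_gap_windows and trimmed at edges", {
  laf <- c(NA, NA, rep(0, 60), rep(NA, 4), rep(0, 60), NA)
  seg <- segment_loh(laf_frame(laf), max_gap_windows = 5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 2e5 + 1)       # leading NAs trimmed
  expect_equal(seg$end, 126e5)           # trailing NA trimmed

  seg2 <- segment_loh(laf_frame(laf), max_gap_windows = 3)
  expect_equal(nrow(seg2), 0)            # each half is only 6 Mb
  laf3 <- c(rep(0, 110), rep(NA, 4), rep(0, 110))
  expect_equal(nrow(segment_loh(laf_frame(laf3), max_gap_windows = 3)), 2)
})

test_that("planted LOH is recovered with window-resolution bounds", {
  set.seed(12)
  ci <- toy_chrom_info(c(chr1 = 30e6))
  n <- 20000
  pos <- sort(sample.int(30e6, n))
  in_loh <- pos >= 8e6 & pos <= 21e6
  zyg <- ifelse(runif(n) < 0.6 & !in_loh, "het", "hom")
  depth <- rpois(n, 100)
  alt <- rbinom(n, depth, ifelse(zyg == "het", 0.5, 1))
  v <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                  zygosity = zyg, ref_depth = depth - alt, alt_depth = alt,
                  stringsAsFactors = FALSE)
  seg <- segment_loh(compute_laf_windows(v, ci, bin = 1e5))
  expect_equal(nrow(seg), 1)
  expect_lte(abs(seg$start - 8e6), 1e5)
  expect_lte(abs(seg$end - 21e6), 1e5)
})

test_that("LOH summary conserves totals and is invariant to segment splitting", {
  ci <- grch37_chromosomes()
  whole <- ci[ci$name %in% c("chr13", "chr22", "chrX"), ]
  segs <- data.frame(chrom = whole$name, start = 1, end = whole$length_bp)
  s <- summarize_loh(segs, ci)
  pc <- s$per_chromosome
  expect_equal(pc$loh_bp[pc$chrom == "chr13"], 115169878)
  expect_equal(pc$loh_bp[pc$chrom == "chr22"], 51304566)
  expect_equal(pc$loh_bp[pc$chrom == "chrX"], 155270560)
  expect_equal(pc$percent_loh[pc$chrom == "chr13"], 100)
  # full-chromosome LOH carries the chromosome's whole variant count
  expect_equal(pc$loh_variants[pc$chrom == "chr13"], 1814242)
  expect_equal(s$totals$loh_bp, sum(pc$loh_bp))
  expect_equal(s$totals$loh_variants, sum(pc$loh_variants))

  # splitting a segment into adjacent pieces changes nothing
  split_segs <- rbind(
    data.frame(chrom = "chr13", start = 1, end = 5e7),
    data.frame(chrom = "chr13", start = 5e7 + 1, end = 115169878),
    segs[segs$chrom != "chr13", ])
  s2 <- summarize_loh(split_segs, ci)
  expect_equal(s2$totals$percent_loh_by_bp, s$totals$percent_loh_by_bp)

  none <- summarize_loh(segs[0, ], ci)
  expect_equal(none$totals$loh_bp, 0)
  expect_equal(none$totals$percent_loh_by_bp, 0)

  expect_error(summarize_loh(
    data.frame(chrom = "chr22", start = 1, end = 6e7), ci), "beyond")
})

test_that("a positional variant catalog overrides proportional scaling", {
  ci <- toy_chrom_info(c(chr1 = 1e6), variants = 100)
  segs <- data.frame(chrom = "chr1", start = 1, end = 4e5)
  catalog <- data.frame(chrom = "chr1", pos = c(1e5, 2e5, 5e5, 9e5))
  s <- summarize_loh(segs, ci, variant_catalog = catalog)
  expect_equal(s$per_chromosome$loh_variants, 2)
  s2 <- summarize_loh(segs, ci)       # proportional: 100 * 0.4
  expect_equal(s2$per_chromosome$loh_variants, 40)
})

test_that("het/hom ratio reproduces the published per-library values", {
  stats <- bt474_genome_stats()
  r <- het_hom_ratio(stats$snv_het, stats$snv_hom)
  expect_equal(r$ratio_2dp, c(1.07, 0.86, 1.00))
  expect_equal(het_hom_ratio(5, 5)$ratio_2dp, 1.00)
  expect_error(het_hom_ratio(5, 0), "undefined")
})
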