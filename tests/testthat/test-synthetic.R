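test_that("the generator is deterministic and hits its stated targets", {
  p <- sim_params(seed = 2)
  m1 <- make_genome_model(p)
  m2 <- make_genome_model(p)
  expect_equal(m1, m2)

  # LOH target hit within 2% absolute
  expect_lte(abs(m1$realized_loh_fraction - 0.22), 0.02)
  # all planted LOH intervals exceed the >10 Mb detectability floor
  expect_true(all(m1$loh_intervals$end - m1$loh_intervals$start + 1 > 1e7))
  # LOH segments have exactly one surviving haplotype
  loh_seg <- m1$segments[m1$segments$is_loh, ]
  expect_true(all((loh_seg$hap1 == 0) != (loh_seg$hap2 == 0)))

  m0 <- make_genome_model(sim_params(seed = 2, loh_fraction = 0))
  expect_equal(nrow(m0$loh_intervals), 0)
  r <- sum(m0$variants$zygosity == "het") / sum(m0$variants$zygosity == "hom")
  expect_lte(abs(r - 1.6) / 1.6, 0.05)

  expect_error(sim_params(loh_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(breakpoint_jitter_bp = 6000), "5 kb")
})

test_that("read-depth draws match the local copy-fraction expectations", {
  m <- make_genome_model(small_params(seed = 10))
  vr <- simulate_variant_reads(m, libraries = "STD")
  truth <- m$variants
  cp <- aneukit:::copies_at(m, truth$chrom, truth$pos)
  balanced <- truth$zygosity == "het" & cp$hap1 == 2 & cp$hap2 == 2
  af <- vr$alt_depth / (vr$ref_depth + vr$alt_depth)
  expect_gt(sum(balanced), 1000)
  expect_lte(abs(mean(af[balanced], na.rm = TRUE) - 0.5), 0.02)

  # het on an amplified 3:1 background reads out near 0.25
  seg <- data.frame(chrom = "chr1", start = 1, end = 1e6,
                    hap1 = 3, hap2 = 1, is_loh = FALSE)
  amp_model <- structure(list(
    params = small_params(seed = 11),
    segments = seg,
    variants = data.frame(chrom = "chr1", pos = seq(1000, 999000, by = 500),
                          zygosity = "het", haplotype = 2,
                          alt_on_hap1 = FALSE, alt_on_hap2 = TRUE,
                          stringsAsFactors = FALSE)),
    class = "genome_model")
  va <- simulate_variant_reads(amp_model, libraries = "STD")
  af2 <- va$alt_depth / (va$ref_depth + va$alt_depth)
  expect_lte(abs(mean(af2, na.rm = TRUE) - 0.25), 0.03)

  # zero depth excludes every locus downstream
  m0 <- make_genome_model(small_params(seed = 10, depth = 0))
  v0 <- simulate_variant_reads(m0, libraries = "STD")
  expect_true(all(v0$ref_depth + v0$alt_depth == 0))
  w0 <- compute_laf_windows(v0, m0$chrom_info)
  expect_true(all(w0$n_variants == 0))
})

test_that("noise-free translocation tables cluster back to the planted events", {
  p <- small_params(seed = 12, dropout = 0, false_calls_per_library = 0)
  m <- make_genome_model(p)
  calls <- simulate_translocation_calls(m)
  expect_equal(nrow(calls), 3 * nrow(m$translocations))
  cl <- cluster_translocations(canonicalize_calls(calls), 5000)
  expect_equal(max(cl$cluster_id), nrow(m$translocations))
  # every cluster is pure: one planted event, seen in all three libraries
  by_cl <- split(cl, cl$cluster_id)
  expect_true(all(vapply(by_cl, function(g)
    length(unique(g$true_event)) == 1 &&
      setequal(g$library, c("STD", "LFR1", "LFR2")), TRUE)))

  gone <- simulate_translocation_calls(
    make_genome_model(small_params(seed = 12, dropout = 1,
                                   false_calls_per_library = 0)))
  expect_equal(nrow(gone), 0)
})

test_that("the planted sharing pattern survives dropout", {
  p <- small_params(seed = 13, n_translocations = 12, dropout = 0.3,
                    false_calls_per_library = 0)
  m <- make_genome_model(p)
  calls <- simulate_translocation_calls(m)
  cl <- cluster_translocations(canonicalize_calls(calls), 5000)
  ov <- library_overlap_counts(cl)
  truth_libs <- tapply(calls$library, calls$true_event,
                       function(x) length(unique(x)))
  expect_equal(ov$total, length(truth_libs))
  expect_equal(ov$shared_two_plus, sum(truth_libs >= 2))
})

test_that("fixture sets round-trip and regenerate byte-identically", {
  p <- small_params(seed = 15, variant_density = 1 / 20000,
                    fragments_per_well = 4)
  m <- make_genome_model(p)
  d1 <- withr::local_tempdir()
  man <- write_fixture_set(m, file.path(d1, "fix"), include_lfr = TRUE)
  expect_true(file.exists(file.path(d1, "fix", "manifest.json")))

  # reading back reproduces what was written
  calls <- simulate_translocation_calls(m)
  back <- read_translocation_table(file.path(d1, "fix", "translocations.tsv"))
  expect_equal(back[names(back) != "true_event"],
               calls[names(back)[names(back) != "true_event"]],
               ignore_attr = TRUE)
  v_tsv <- read_variant_table(file.path(d1, "fix", "variants.tsv"))
  expect_equal(nrow(v_tsv), 3 * nrow(m$variants))
  v_vcf <- read_variant_table(file.path(d1, "fix", "variants_STD.vcf"))
  expect_equal(nrow(v_vcf), nrow(m$variants))
  loh_bed <- read_segments_bed(file.path(d1, "fix", "loh_truth.bed"))
  expect_equal(nrow(loh_bed), nrow(m$loh_intervals))

  # regenerating from the manifest's seed is byte-identical
  man2 <- jsonlite::read_json(file.path(d1, "fix", "manifest.json"))
  m2 <- make_genome_model(small_params(seed = man2$seed,
                                       variant_density = 1 / 20000,
                                       fragments_per_well = 4))
  write_fixture_set(m2, file.path(d1, "fix2"), include_lfr = TRUE)
  for (f in setdiff(list.files(file.path(d1, "fix")), "manifest.json")) {
    expect_identical(readLines(file.path(d1, "fix", f)),
                     readLines(file.path(d1, "fix2", f)), label = f)
  }

  expect_error(write_fixture_set(m, file.path(d1, "fix")), "not empty")
})

test_that("end-to-end: the default-seed world is recovered by the pipeline", {
  m <- make_genome_model(sim_params(seed = 1))

  # LOH fraction back out of the LAF/segmentation path, within 0.02
  vr <- simulate_variant_reads(m, libraries = "STD")
  segs <- segment_loh(compute_laf_windows(vr, m$chrom_info, bin = 1e5))
  su <- summarize_loh(segs, m$chrom_info)
  recovered <- su$totals$loh_bp / sum(m$chrom_info$length_bp)
  expect_lte(abs(recovered - m$realized_loh_fraction), 0.02)

  # planted copy numbers from binned coverage, within 10% relative
  bins <- normalize_copy_number(
    bin_reads(simulate_read_positions(m), m$chrom_info, bin = 1e5),
    target_ploidy = 4)
  seg_err <- apply(m$segments, 1, function(s) {
    sel <- bins$chrom == s[["chrom"]] &
      bins$start >= as.numeric(s[["start"]]) &
      bins$end <= as.numeric(s[["end"]])
    if (sum(sel) < 5) return(NA)
    true_copy <- as.numeric(s[["hap1"]]) + as.numeric(s[["hap2"]])
    abs(mean(bins$normalized_copy[sel]) - true_copy) / true_copy
  })
  expect_true(all(stats::na.omit(seg_err) < 0.1))

  # >= 99% of injected polymerase errors flagged
  w <- simulate_lfr_wells(m, max_loci = 4000)
  tab <- merge(well_support_table(w$observations), w$loci, by = "locus_id")
  lab <- classify_well_support(tab$n_variant_wells, tab$shared_well_count,
                               tab$well_count, tab$zygosity)
  is_err <- tab$truth == "polymerase_error"
  expect_gte(mean(lab[is_err] == "polymerase_error_suspect"), 0.99)
})
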