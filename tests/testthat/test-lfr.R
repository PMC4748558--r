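test_that("hapLink IDs parse to contig and haplotype", {
  p <- parse_haplink(c("Phased_12_3_1", "", "Phased_4_7_0", NA))
  expect_equal(p$contig_a, c(12L, NA, 4L, NA))
  expect_equal(p$contig_b, c(3L, NA, 7L, NA))
  expect_equal(p$haplotype, c(1L, NA, 0L, NA))

  expect_error(parse_haplink("Phased_1_2_5"), "malformed")
  expect_error(parse_haplink("Phased_a_2_1"), "malformed")
})

test_that("well support statistics follow the field definitions", {
  obs <- data.frame(well = c(3, 17, 40, 7, 7),
                    allele = c("alt", "alt", "ref", "ref", "alt"))
  s <- compute_well_support(obs)
  expect_equal(s$well_count, 4)
  expect_equal(s$exclusive_well_count, 3)
  expect_equal(s$shared_well_count, 1)
  expect_equal(s$variant_well_ids, c(3, 7, 17))
  expect_equal(s$min_exclusive, 1)   # one ref-only well
  expect_equal(s$max_exclusive, 2)   # two alt-only wells

  empty <- compute_well_support(obs[0, ])
  expect_equal(empty$well_count, 0)
  expect_equal(empty$variant_well_ids, integer(0))

  expect_error(compute_well_support(data.frame(well = 1, allele = "alt2")),
               "ref")
  expect_error(compute_well_support(data.frame(well = 999, allele = "alt")),
               "\\[1, 384\\]")
})

test_that("vectorized table path equals the per-locus reference implementation", {
  set.seed(21)
  obs <- data.frame(
    locus_id = sample(paste0("L", 1:40), 600, replace = TRUE),
    well = sample.int(384, 600, replace = TRUE),
    allele = sample(c("ref", "alt"), 600, replace = TRUE,
                    prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE)
  tab <- well_support_table(obs)
  for (id in unique(obs$locus_id)) {
    ref <- compute_well_support(obs[obs$locus_id == id, ])
    row <- tab[tab$locus_id == id, ]
    expect_equal(row$well_count, ref$well_count, label = id)
    expect_equal(row$exclusive_well_count, ref$exclusive_well_count)
    expect_equal(row$shared_well_count, ref$shared_well_count)
    expect_equal(row$min_exclusive, ref$min_exclusive)
    expect_equal(row$max_exclusive, ref$max_exclusive)
    expect_equal(row$well_ids,
                 paste(ref$variant_well_ids, collapse = ","))
  }
  # decomposition identity holds for every locus
  expect_true(all(tab$well_count ==
                    tab$exclusive_well_count + tab$shared_well_count))
})

test_that("classification separates single-well errors from supported calls", {
  expect_equal(classify_well_support(1, 0, 20, "het"),
               "polymerase_error_suspect")
  expect_equal(classify_well_support(20, 0, 20, "het"), "supported")
  expect_equal(classify_well_support(10, 15, 20, "het"),
               "mapping_error_suspect")
  expect_equal(classify_well_support(10, 15, 20, "hom"), "supported")

  # monotone: more variant wells never demotes supported -> suspect
  labels <- classify_well_support(0:10, 0, 20, rep("het", 11))
  sup <- labels == "supported"
  expect_true(all(diff(as.integer(sup)) >= 0))
})

test_that("simulated LFR wells give true hets strong exclusive support", {
  m <- make_genome_model(small_params(seed = 5))
  w <- simulate_lfr_wells(m, max_loci = 1500)
  tab <- merge(well_support_table(w$observations), w$loci, by = "locus_id")
  het <- tab[tab$zygosity == "het" & tab$truth == "variant", ]
  expect_gt(nrow(het), 200)
  frac_exclusive <- het$exclusive_well_count / het$well_count
  expect_gte(mean(frac_exclusive >= 0.9), 0.95)
  expect_gte(mean(het$well_count), 10)
})

test_that("injected polymerase errors are flagged with near-perfect accuracy", {
  m <- make_genome_model(small_params(seed = 6,
                                      polymerase_error_rate = 0.05))
  w <- simulate_lfr_wells(m, max_loci = 2000)
  # by construction each injected error occupies exactly one well
  err_ids <- w$loci$locus_id[w$loci$truth == "polymerase_error"]
  expect_gt(length(err_ids), 30)
  alt_wells <- with(w$observations[w$observations$allele == "alt", ],
                    tapply(well, locus_id, function(x) length(unique(x))))
  expect_true(all(alt_wells[err_ids] == 1))

  tab <- merge(well_support_table(w$observations), w$loci, by = "locus_id")
  lab <- classify_well_support(tab$n_variant_wells, tab$shared_well_count,
                               tab$well_count, tab$zygosity)
  is_err <- tab$truth == "polymerase_error"
  sensitivity <- mean(lab[is_err] == "polymerase_error_suspect")
  specificity <- mean(lab[!is_err] != "polymerase_error_suspect")
  expect_gte(sensitivity, 0.99)
  expect_gte(specificity, 0.99)
})

test_that("phase groups are internally consistent against generator truth", {
  m <- make_genome_model(small_params(seed = 9))
  v <- assign_haplinks(m)
  rep <- check_phase_consistency(v)
  expect_gt(nrow(rep), 2)
  expect_true(all(rep$n_switch_errors == 0))

  # two variants sharing one ID fall in the same group
  two <- data.frame(haplink = c("Phased_4_7_0", "Phased_4_7_0"),
                    true_haplotype = c(1, 1))
  r2 <- check_phase_consistency(two)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_variants, 2)

  # corrupting one member's parentage creates one switch error
  three <- data.frame(haplink = rep("Phased_4_7_0", 3),
                      true_haplotype = c(1, 1, 2))
  expect_equal(check_phase_consistency(three)$n_switch_errors, 1)

  none <- check_phase_consistency(data.frame(haplink = c("", "")))
  expect_equal(nrow(none), 0)
})

test_that("nearby same-haplotype variants co-occur in at least one well", {
  m <- make_genome_model(small_params(seed = 14,
                                      variant_density = 1 / 500))
  w <- simulate_lfr_wells(m)
  v <- m$variants[m$variants$zygosity == "het", ]
  v$locus_id <- paste0(v$chrom, ":", v$pos)
  # pairs of het variants < 1.5 kb apart on the same parental haplotype
  pairs <- list()
  for (chr in unique(v$chrom)) {
    vv <- v[v$chrom == chr, ]
    close <- which(diff(vv$pos) < 1500)
    for (i in close) {
      if (!is.na(vv$haplotype[i]) && !is.na(vv$haplotype[i + 1]) &&
          vv$haplotype[i] == vv$haplotype[i + 1])
        pairs <- c(pairs, list(c(vv$locus_id[i], vv$locus_id[i + 1])))
    }
  }
  expect_gt(length(pairs), 50)
  alt_obs <- w$observations[w$observations$allele == "alt", ]
  wells_of <- split(alt_obs$well, alt_obs$locus_id)
  co <- vapply(pairs, function(p) {
    length(intersect(wells_of[[p[1]]], wells_of[[p[2]]])) > 0
  }, TRUE)
  expect_gte(mean(co), 0.95)
})
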