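#' Expected effect of LOH on diploid het/hom counts
#'
#' Deterministic thought experiment: if a fraction `loh_fraction` of a
#' diploid genome underwent loss of heterozygosity, the heterozygous
#' variants in the affected fraction would be observed as homozygous
#' (the surviving allele is called against the reference).  The number of
#' transferred variants is `round(het_count * loh_fraction)` (nearest
#' integer, ties away from zero); totals are conserved.
#'
#' @param hom_count,het_count Diploid genome-wide variant counts.
#' @param loh_fraction Fraction of the genome (or of its variants) in LOH,
#'   in `[0, 1]`.
#' @param mode Label recording which fraction was supplied
#'   (`"by_length"`, `"by_variants"`, or `"custom"`); the arithmetic is
#'   identical.
#' @return List with `mode, loh_fraction, hom_before, het_before,
#'   transferred, hom_after, het_after, ratio_before, ratio_after,
#'   ratio_before_2dp, ratio_after_2dp`.
#' @examples
#' r <- simulate_loh_expected(1306544, 2081141, 0.222, "by_length")
#' c(r$hom_after, r$het_after)  # 1768557 1619128
#' r$ratio_after_2dp            # 0.92
#' @export
simulate_loh_expected <- function(hom_count, het_count, loh_fraction,
                                  mode = c("custom", "by_length",
                                           "by_variants")) {
  mode <- match.arg(mode)
  hom_count <- unname(hom_count)
  het_count <- unname(het_count)
  if (loh_fraction < 0 || loh_fraction > 1)
    stop_fmt("loh_fraction must lie in [0, 1]")
  transferred <- round_half_up(het_count * loh_fraction)
  het_after <- het_count - transferred
  hom_after <- hom_count + transferred
  rb <- het_count / hom_count
  ra <- het_after / hom_after
  list(mode = mode, loh_fraction = loh_fraction,
       hom_before = hom_count, het_before = het_count,
       transferred = transferred,
       hom_after = hom_after, het_after = het_after,
       ratio_before = rb, ratio_after = ra,
       ratio_before_2dp = round_half_up(rb, 2),
       ratio_after_2dp = round_half_up(ra, 2))
}

#' Regional (stochastic) LOH simulation
#'
#' Monte-Carlo counterpart of [simulate_loh_expected()]: contiguous
#' regions are drawn without replacement — chromosome arm picked
#' proportional to its length, start uniform within the arm, length
#' exponential with mean `region_mean_bp` truncated at the arm end,
#' overlapping draws rejected — until at least `target_fraction` of the
#' genome is covered.  Heterozygous variants inside the drawn regions
#' become homozygous; counts are exact for the drawn regions.
#'
#' @param model A genome model (see [make_genome_model()]) or any list with
#'   `chrom_info` and a `variants` data.frame (`chrom, pos, zygosity`).
#' @param target_fraction Genome fraction to place into LOH, `[0, 1]`.
#' @param seed Optional seed for reproducible draws.
#' @param region_mean_bp Mean drawn-region length (default 30 Mb, the scale
#'   of observed LOH blocks).
#' @param max_tries Rejection-sampling budget; exceeding it signals that
#'   the target fraction is not achievable with non-overlapping regions.
#' @return As [simulate_loh_expected()], plus `realized_fraction` and a
#'   `regions` data.frame of the drawn intervals.
#' @export
simulate_loh_regions <- function(model, target_fraction, seed = NULL,
                                 region_mean_bp = 3e7, max_tries = 10000) {
  if (target_fraction < 0 || target_fraction > 1)
    stop_fmt("target_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ci <- model$chrom_info
  variants <- model$variants
  if (is.null(variants$zygosity))
    stop_fmt("model carries no variant zygosity")

  # chromosome arms: [1, centromere] and (centromere, length]
  arms <- do.call(rbind, lapply(seq_len(nrow(ci)), function(i) {
    cen <- round(ci$centromere_mbp[i] * 1e6)
    cen <- min(max(cen, 1), ci$length_bp[i] - 1)
    data.frame(chrom = ci$name[i], start = c(1, cen + 1),
               end = c(cen, ci$length_bp[i]), stringsAsFactors = FALSE)
  }))
  arms$len <- arms$end - arms$start + 1
  genome_bp <- sum(ci$length_bp)

  regions <- list()
  covered <- 0
  tries <- 0
  hom0 <- sum(variants$zygosity == "hom")
  het0 <- sum(variants$zygosity == "het")
  while (covered < target_fraction * genome_bp) {
    tries <- tries + 1
    if (tries > max_tries)
      stop_fmt("target fraction %.3f not achievable within %d draws",
               target_fraction, max_tries)
    a <- sample.int(nrow(arms), 1, prob = arms$len)
    start <- floor(stats::runif(1, arms$start[a], arms$end[a] + 1))
    len <- ceiling(stats::rexp(1, 1 / region_mean_bp))
    end <- min(start + len - 1, arms$end[a])
    overlaps <- any(vapply(regions, function(r)
      r$chrom == arms$chrom[a] && r$start <= end && r$end >= start, TRUE))
    if (overlaps) next
    regions <- c(regions, list(list(chrom = arms$chrom[a],
                                    start = start, end = end)))
    covered <- covered + (end - start + 1)
  }
  reg <- if (length(regions))
    do.call(rbind, lapply(regions, as.data.frame)) else
      data.frame(chrom = character(), start = numeric(), end = numeric())

  in_loh <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(reg))) {
    in_loh <- in_loh | (variants$chrom == reg$chrom[i] &
                        variants$pos >= reg$start[i] &
                        variants$pos <= reg$end[i])
  }
  transferred <- sum(in_loh & variants$zygosity == "het")
  het_after <- het0 - transferred
  hom_after <- hom0 + transferred
  rb <- het0 / hom0
  ra <- het_after / hom_after
  list(mode = "regional",
       loh_fraction = target_fraction,
       realized_fraction = covered / genome_bp,
       hom_before = hom0, het_before = het0,
       transferred = transferred,
       hom_after = hom_after, het_after = het_after,
       ratio_before = rb, ratio_after = ra,
       ratio_before_2dp = round_half_up(rb, 2),
       ratio_after_2dp = round_half_up(ra, 2),
       regions = reg)
}
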