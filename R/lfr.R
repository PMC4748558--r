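## LFR (Long Fragment Read) well annotation: ~40 kb genomic fragments are
## dispersed across a 384-well plate before amplification, so every read is
## attributable to a well.  A true variant is seen in many wells; a random
## polymerase error arises in one well only — the basis of the error filter.

#' Parse phasing-contig IDs
#'
#' LFR-phased variants carry an ID of the form `"Phased_a_b_h"`: `a` and
#' `b` identify the phasing contig, `h` (0 or 1) the haplotype within it.
#' All variants sharing the full ID belong to one haplotype.
#'
#' @param x Character vector; empty strings and `NA` mean unphased.
#' @return Data.frame with integer columns `contig_a, contig_b, haplotype`
#'   (`NA` for unphased entries).
#' @examples
#' parse_haplink(c("Phased_12_3_1", ""))
#' @export
parse_haplink <- function(x) {
  x <- as.character(x)
  out <- data.frame(contig_a = rep(NA_integer_, length(x)),
                    contig_b = NA_integer_, haplotype = NA_integer_)
  filled <- !is.na(x) & x != ""
  if (!any(filled)) return(out)
  m <- regmatches(x[filled],
                  regexec("^Phased_([0-9]+)_([0-9]+)_([01])$", x[filled]))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop_fmt("malformed hapLink ID '%s' (expected Phased_<int>_<int>_<0|1>)",
             x[filled][which(bad)[1]])
  mm <- do.call(rbind, m)
  out$contig_a[filled] <- as.integer(mm[, 2])
  out$contig_b[filled] <- as.integer(mm[, 3])
  out$haplotype[filled] <- as.integer(mm[, 4])
  out
}

#' Well-support statistics for one locus
#'
#' From per-well allele observations, computes the well statistics stored
#' in LFR variant files: `well_count` (wells with reads calling variant or
#' reference), `exclusive_well_count` (wells calling exactly one allele),
#' `shared_well_count` (wells calling both), the variant-bearing well IDs,
#' and the per-allele exclusive-well extremes (`min_exclusive`,
#' `max_exclusive`).
#'
#' @param obs Data.frame with columns `well` (integer index) and `allele`
#'   (`"ref"` or `"alt"`), one row per observed (well, allele).
#' @param n_wells Plate size for index validation (default 384).
#' @return List of the statistics above; `variant_well_ids` is a sorted
#'   integer vector.
#' @examples
#' obs <- data.frame(well = c(3, 17, 40, 7, 7),
#'                   allele = c("alt", "alt", "ref", "ref", "alt"))
#' compute_well_support(obs)$exclusive_well_count  # 3
#' @export
compute_well_support <- function(obs, n_wells = 384) {
  if (!nrow(obs))
    return(list(well_count = 0L, exclusive_well_count = 0L,
                shared_well_count = 0L, variant_well_ids = integer(0),
                min_exclusive = 0L, max_exclusive = 0L))
  if (any(!(obs$allele %in% c("ref", "alt"))))
    stop_fmt("allele observations must be 'ref' or 'alt'")
  if (any(obs$well < 1 | obs$well > n_wells))
    stop_fmt("well index outside [1, %d]", n_wells)
  has_ref <- unique(obs$well[obs$allele == "ref"])
  has_alt <- unique(obs$well[obs$allele == "alt"])
  shared <- intersect(has_ref, has_alt)
  ref_only <- setdiff(has_ref, shared)
  alt_only <- setdiff(has_alt, shared)
  list(well_count = length(union(has_ref, has_alt)),
       exclusive_well_count = length(ref_only) + length(alt_only),
       shared_well_count = length(shared),
       variant_well_ids = sort(has_alt),
       min_exclusive = min(length(ref_only), length(alt_only)),
       max_exclusive = max(length(ref_only), length(alt_only)))
}

#' Well-support statistics for a table of observations
#'
#' Applies [compute_well_support()] per locus.
#'
#' @param obs Data.frame with columns `locus_id, well, allele`.
#' @param n_wells Plate size (default 384).
#' @return Data.frame with one row per locus: the well statistics plus
#'   `well_ids` as a comma-joined string.
#' @export
well_support_table <- function(obs, n_wells = 384) {
  if (any(!(obs$allele %in% c("ref", "alt"))))
    stop_fmt("allele observations must be 'ref' or 'alt'")
  if (nrow(obs) && any(obs$well < 1 | obs$well > n_wells))
    stop_fmt("well index outside [1, %d]", n_wells)
  # vectorized equivalent of compute_well_support() applied per locus
  u <- unique(obs[c("locus_id", "well", "allele")])
  lw <- paste(u$locus_id, u$well, sep = "\r")
  shared_lw <- duplicated(lw) | duplicated(lw, fromLast = TRUE)
  first <- !duplicated(lw)
  locus <- factor(u$locus_id[first])
  agg <- function(x) as.integer(tapply(x, locus, sum, default = 0))
  is_ref <- u$allele[first] == "ref" & !shared_lw[first]
  is_alt <- u$allele[first] == "alt" & !shared_lw[first]
  ref_only <- agg(is_ref)
  alt_only <- agg(is_alt)
  shared <- agg(shared_lw[first])
  alt_rows <- u[u$allele == "alt", , drop = FALSE]
  wid <- vapply(split(alt_rows$well, factor(alt_rows$locus_id,
                                            levels = levels(locus))),
                function(w) paste(sort(w), collapse = ","), "")
  nvw <- as.integer(tapply(u$allele == "alt", factor(u$locus_id), sum,
                           default = 0))
  out <- data.frame(locus_id = levels(locus),
                    well_count = ref_only + alt_only + shared,
                    exclusive_well_count = ref_only + alt_only,
                    shared_well_count = shared,
                    min_exclusive = pmin(ref_only, alt_only),
                    max_exclusive = pmax(ref_only, alt_only),
                    n_variant_wells = nvw,
                    well_ids = as.character(wid),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify variant calls by well support
#'
#' Random polymerase errors are amplified within a single well, so a
#' variant observed in fewer than `min_variant_wells` distinct wells is a
#' polymerase-error suspect.  A heterozygous call whose wells
#' predominantly contain reads for *both* alleles (shared fraction above
#' `shared_frac_threshold`) is a mapping-error suspect: two different loci
#' are likely being stacked onto one position.  Everything else is
#' supported.
#'
#' @param n_variant_wells Wells containing reads calling the variant
#'   (vectorized).
#' @param shared_well_count,well_count Well statistics (vectorized).
#' @param zygosity `"het"`, `"hom"`, or `"half-called"` (vectorized).
#' @param min_variant_wells Minimum believable variant wells (default 2).
#' @param shared_frac_threshold Shared-well fraction above which a het is
#'   suspect (default 0.5).
#' @return Character vector in `{"supported", "polymerase_error_suspect",
#'   "mapping_error_suspect"}`.
#' @export
classify_well_support <- function(n_variant_wells, shared_well_count,
                                  well_count, zygosity,
                                  min_variant_wells = 2,
                                  shared_frac_threshold = 0.5) {
  n <- max(length(n_variant_wells), length(zygosity))
  lab <- rep("supported", n)
  shared_frac <- ifelse(well_count > 0, shared_well_count / well_count, 0)
  lab[zygosity == "het" & shared_frac > shared_frac_threshold] <-
    "mapping_error_suspect"
  lab[n_variant_wells < min_variant_wells] <- "polymerase_error_suspect"
  lab
}

#' Phasing-group consistency report
#'
#' Groups phased variants by contig and haplotype.  When a per-variant
#' true parental haplotype is supplied (synthetic truth), each group's
#' members are checked against the group majority; discordant members are
#' switch errors.
#'
#' @param variants Data.frame with a `haplink` column (or pre-parsed
#'   `contig_a, contig_b, haplotype` columns); optional `true_haplotype`
#'   column with parental haplotype codes.
#' @return Data.frame with one row per phasing group: `contig_a, contig_b,
#'   haplotype, n_variants` and, when truth is available,
#'   `majority_truth, n_switch_errors`.  Unphased records are ignored;
#'   an input with no phased records yields an empty report.
#' @export
check_phase_consistency <- function(variants) {
  if (!is.null(variants$haplink) && is.null(variants$contig_a)) {
    variants <- cbind(variants, parse_haplink(variants$haplink))
  }
  if (is.null(variants$contig_a))
    stop_fmt("no phasing information (haplink) in input")
  phased <- variants[!is.na(variants$haplotype), , drop = FALSE]
  if (!nrow(phased))
    return(data.frame(contig_a = integer(), contig_b = integer(),
                      haplotype = integer(), n_variants = integer()))
  key <- paste(phased$contig_a, phased$contig_b, phased$haplotype)
  groups <- split(phased, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- data.frame(contig_a = g$contig_a[1], contig_b = g$contig_b[1],
                      haplotype = g$haplotype[1], n_variants = nrow(g))
    if (!is.null(g$true_haplotype)) {
      tab <- sort(table(g$true_haplotype), decreasing = TRUE)
      row$majority_truth <- names(tab)[1]
      row$n_switch_errors <- nrow(g) - as.integer(tab[1])
    }
    row
  }))
  out <- out[order(out$contig_a, out$contig_b, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
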