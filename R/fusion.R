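#' Check fusion candidates against clustered translocations
#'
#' A fusion candidate (two genes on different chromosomes, typically from
#' RNA-seq) is *supported* iff some cluster has a chromosome pair matching
#' the candidate's gene chromosomes and each of the cluster's merged
#' breakpoint spans overlaps, or lies within `window` bp of, the
#' corresponding gene interval — under either assignment of the gene pair
#' to the cluster's A/B sides.  Orientation is not constrained: RNA
#' evidence does not fix the genomic junction geometry.
#'
#' @param clustered Output of [cluster_translocations()] (or a
#'   [sv_cluster_table()] summary).
#' @param candidates Data.frame with columns `gene_a, chrom_a, start_a,
#'   end_a, gene_b, chrom_b, start_b, end_b` (see
#'   [bt474_fusion_candidates()]).
#' @param window Slack in bp around each gene interval (default 5000,
#'   matching the breakpoint clustering window).
#' @return The candidate table plus `supported` (logical),
#'   `supporting_clusters` (comma-joined cluster IDs) and, when the calls
#'   carried a `sv_id` passthrough column, `supporting_sv_ids`.
#' @export
support_fusion_candidates <- function(clustered, candidates, window = 5000) {
  tab <- if ("n_members" %in% names(clustered)) clustered
         else sv_cluster_table(clustered)
  candidates$supported <- FALSE
  candidates$supporting_clusters <- ""
  candidates$supporting_sv_ids <- ""
  if (!nrow(tab) || !nrow(candidates)) return(candidates)

  for (k in seq_len(nrow(candidates))) {
    ca <- normalize_chrom(candidates$chrom_a[k])
    cb <- normalize_chrom(candidates$chrom_b[k])
    ga <- c(candidates$start_a[k], candidates$end_a[k])
    gb <- c(candidates$start_b[k], candidates$end_b[k])
    hit_one <- function(gene_first, gene_second) {
      tab$chrom_a == gene_first$chrom & tab$chrom_b == gene_second$chrom &
        interval_gap(tab$start_a, tab$end_a,
                     gene_first$iv[1], gene_first$iv[2]) <= window &
        interval_gap(tab$start_b, tab$end_b,
                     gene_second$iv[1], gene_second$iv[2]) <= window
    }
    hits <- hit_one(list(chrom = ca, iv = ga), list(chrom = cb, iv = gb)) |
            hit_one(list(chrom = cb, iv = gb), list(chrom = ca, iv = ga))
    if (any(hits)) {
      candidates$supported[k] <- TRUE
      candidates$supporting_clusters[k] <-
        paste(tab$cluster_id[hits], collapse = ",")
      if (!all(is.na(tab$sv_ids)))
        candidates$supporting_sv_ids[k] <-
          paste(unique(unlist(strsplit(tab$sv_ids[hits], ","))), collapse = ",")
    }
  }
  candidates
}
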