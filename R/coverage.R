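#' Bin read positions into fixed windows
#'
#' Counts reads per `bin`-sized window, windows anchored at position 1 and
#' tiling each chromosome of `chrom_info` (final partial window kept).
#'
#' @param positions Data.frame with columns `chrom, pos` (read start
#'   positions, 1-based).
#' @param chrom_info Chromosome table.
#' @param bin Window size in bp (default 100 kb).
#' @return Data.frame `chrom, bin_index, start, end, read_count`.
#' @examples
#' ci <- data.frame(name = "chr1", length_bp = 1e6, variant_count = 0,
#'                  centromere_mbp = 0.5)
#' bin_reads(data.frame(chrom = "chr1", pos = 250000), ci)$read_count[3]  # 1
#' @export
bin_reads <- function(positions, chrom_info, bin = 100000) {
  positions$chrom <- normalize_chrom(positions$chrom)
  m <- match(positions$chrom, chrom_info$name)
  if (anyNA(m))
    stop_fmt("read on chromosome %s absent from chrom_info",
             positions$chrom[which(is.na(m))[1]])
  beyond <- positions$pos > chrom_info$length_bp[m] | positions$pos < 1
  if (any(beyond))
    stop_fmt("read position %s:%d outside chromosome bounds",
             positions$chrom[which(beyond)[1]], positions$pos[which(beyond)[1]])

  out <- lapply(seq_len(nrow(chrom_info)), function(i) {
    chr <- chrom_info$name[i]
    len <- chrom_info$length_bp[i]
    n_win <- ceiling(len / bin)
    p <- positions$pos[positions$chrom == chr]
    counts <- tabulate(((p - 1) %/% bin) + 1, nbins = n_win)
    data.frame(chrom = chr, bin_index = seq_len(n_win),
               start = (seq_len(n_win) - 1) * bin + 1,
               end = pmin(seq_len(n_win) * bin, len),
               read_count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalize binned coverage to a stated ploidy
#'
#' Scales bin read counts so the median nonzero autosomal bin equals
#' `target_ploidy` haploid copies.  The median is robust against the
#' amplified tail that dominates highly rearranged genomes; sex chromosomes
#' are excluded from the baseline because their copy number need not track
#' the autosomal modal ploidy.
#'
#' @param bins Output of [bin_reads()] (or any data.frame with `chrom` and
#'   `read_count`).
#' @param target_ploidy Copy number assigned to the baseline (default 4).
#' @return `bins` with a `normalized_copy` column added.
#' @export
normalize_copy_number <- function(bins, target_ploidy = 4) {
  autosomal <- !(bins$chrom %in% c("chrX", "chrY"))
  base <- bins$read_count[autosomal & bins$read_count > 0]
  if (!length(base)) {
    base <- bins$read_count[bins$read_count > 0]  # all-sex-chromosome input
    if (!length(base))
      stop_fmt("all bins have zero coverage; cannot normalize")
  }
  bins$normalized_copy <- target_ploidy * bins$read_count /
    stats::median(base)
  bins
}

#' Plot a copy-number profile
#'
#' Genome-wide scatter of per-bin normalized copy number, chromosomes laid
#' end to end in canonical order.
#'
#' @param bins Output of [normalize_copy_number()].
#' @param ylim Y-axis limits (default `c(0, 2 * target ploidy scale)`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the bin table with an added genome-wide coordinate.
#' @export
plot_coverage_profile <- function(bins, ylim = NULL, ...) {
  bins <- bins[order(chrom_rank(bins$chrom), bins$start), , drop = FALSE]
  chroms <- unique(bins$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(c)
    max(bins$end[bins$chrom == c]), 0)))[seq_along(chroms)]
  names(offsets) <- chroms
  bins$genome_pos <- bins$start + offsets[bins$chrom]
  if (is.null(ylim))
    ylim <- c(0, max(8, stats::quantile(bins$normalized_copy, 0.999) * 1.1))
  graphics::plot(bins$genome_pos, bins$normalized_copy, pch = 16, cex = 0.3,
                 ylim = ylim, xlab = "genome position",
                 ylab = "haploid copy number", ...)
  graphics::abline(v = offsets[-1], col = "grey70", lty = 3)
  invisible(bins)
}
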