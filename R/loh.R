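#' Lesser-allele fraction of a variant
#'
#' `min(ref_depth, alt_depth) / (ref_depth + alt_depth)`: 0.5 for a
#' perfectly balanced heterozygote, 0 for a homozygote.  Sites with zero
#' total depth carry no allelic information and return `NA`.
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorized).
#' @return Numeric vector in `[0, 0.5]`, `NA` where total depth is zero.
#' @examples
#' variant_laf(50, 50)   # 0.5
#' variant_laf(0, 100)   # 0
#' variant_laf(25, 75)   # 0.25
#' @export
variant_laf <- function(ref_depth, alt_depth) {
  if (any(stats::na.omit(c(ref_depth, alt_depth)) < 0))
    stop_fmt("allele depths must be non-negative")
  tot <- ref_depth + alt_depth
  out <- pmin(ref_depth, alt_depth) / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Windowed lesser-allele fractions
#'
#' Tiles each chromosome with `bin`-sized windows anchored at position 1
#' (final partial window kept) and summarizes the per-variant LAF of the
#' fully called variants in each window by the median — robust against a
#' few mis-mapped sites.  Half-called variants and zero-depth sites are
#' excluded; a window without usable variants has `laf = NA`.
#'
#' @param variants Variant table (see [read_variant_table()]) with
#'   `ref_depth`/`alt_depth` populated.
#' @param chrom_info Chromosome table (see [read_chromosome_info()]).
#' @param bin Window size in bp (default 100 kb).
#' @return Data.frame with columns `chrom, window_index, start, end,
#'   n_variants, laf`, windows covering `[1, length]` of every chromosome
#'   in `chrom_info`.
#' @export
compute_laf_windows <- function(variants, chrom_info, bin = 100000) {
  if (is.null(variants$ref_depth) || is.null(variants$alt_depth) ||
      all(is.na(variants$ref_depth)))
    stop_fmt(paste("variant table carries no allele depths;",
                   "LAF/LOH analysis needs per-variant read counts"))
  use <- variants$zygosity != "half-called" &
    !is.na(variants$ref_depth) & !is.na(variants$alt_depth) &
    (variants$ref_depth + variants$alt_depth) > 0
  v <- variants[use, , drop = FALSE]
  v$laf <- variant_laf(v$ref_depth, v$alt_depth)

  out <- lapply(seq_len(nrow(chrom_info)), function(i) {
    chr <- chrom_info$name[i]
    len <- chrom_info$length_bp[i]
    n_win <- ceiling(len / bin)
    start <- (seq_len(n_win) - 1) * bin + 1
    end <- pmin(seq_len(n_win) * bin, len)
    vv <- v[v$chrom == chr, , drop = FALSE]
    if (nrow(vv) && any(vv$pos > len))
      stop_fmt("variant at %s:%d beyond chromosome length %d",
               chr, max(vv$pos), len)
    idx <- ((vv$pos - 1) %/% bin) + 1
    laf <- rep(NA_real_, n_win)
    n_var <- integer(n_win)
    if (nrow(vv)) {
      med <- tapply(vv$laf, idx, stats::median)
      cnt <- table(idx)
      laf[as.integer(names(med))] <- as.numeric(med)
      n_var[as.integer(names(cnt))] <- as.integer(cnt)
    }
    data.frame(chrom = chr, window_index = seq_len(n_win),
               start = start, end = end, n_variants = n_var, laf = laf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Segment LOH regions from LAF windows
#'
#' Finds, per chromosome, maximal runs of windows whose LAF is at or below
#' `epsilon`, tolerating up to `max_gap_windows` consecutive variant-free
#' (`NA`) windows inside a run (centromeric variant deserts would otherwise
#' split whole-arm LOH), and keeps runs whose genomic extent strictly
#' exceeds `min_length`.  Segment bounds snap to window bounds and are
#' trimmed to informative (non-`NA`) windows.
#'
#' @param windows Output of [compute_laf_windows()].
#' @param epsilon LAF at or below this counts as zero (default 0).
#' @param min_length Strict minimum segment extent in bp (default 1e7).
#' @param max_gap_windows Consecutive `NA` windows tolerated inside a
#'   segment (default 5).
#' @return Data.frame `chrom, start, end, length, n_windows`.
#' @export
segment_loh <- function(windows, epsilon = 0, min_length = 1e7,
                        max_gap_windows = 5) {
  segs <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$window_index), , drop = FALSE]
    zero <- !is.na(w$laf) & w$laf <= epsilon
    informative <- !is.na(w$laf)
    runs <- list()
    cur_start <- NA_integer_
    cur_end <- NA_integer_
    gap <- 0L
    for (i in seq_len(nrow(w))) {
      if (zero[i]) {
        if (is.na(cur_start)) cur_start <- i
        cur_end <- i
        gap <- 0L
      } else if (!informative[i] && !is.na(cur_start)) {
        gap <- gap + 1L
        if (gap > max_gap_windows) {
          runs <- c(runs, list(c(cur_start, cur_end)))
          cur_start <- NA_integer_; gap <- 0L
        }
      } else if (!is.na(cur_start)) {
        runs <- c(runs, list(c(cur_start, cur_end)))
        cur_start <- NA_integer_; gap <- 0L
      }
    }
    if (!is.na(cur_start)) runs <- c(runs, list(c(cur_start, cur_end)))
    if (!length(runs)) return(NULL)
    out <- do.call(rbind, lapply(runs, function(r) {
      data.frame(chrom = w$chrom[1], start = w$start[r[1]], end = w$end[r[2]],
                 stringsAsFactors = FALSE)
    }))
    out$length <- out$end - out$start + 1
    out$n_windows <- vapply(runs, function(r) r[2] - r[1] + 1L, 0L)
    out[out$length > min_length, , drop = FALSE]
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  if (is.null(segs))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  segs <- segs[order(chrom_rank(segs$chrom), segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Summarize LOH genome-wide
#'
#' Expresses LOH content per chromosome and genome-wide, both in base pairs
#' and in known-variant terms.  With a positional `variant_catalog`
#' (data.frame `chrom, pos`) the variants inside each segment are counted
#' directly; otherwise a chromosome fully in LOH contributes its whole
#' known-variant count, and partial LOH scales the count by the LOH
#' fraction of the chromosome (uniform-density assumption).
#'
#' @param segments Data.frame `chrom, start, end` (disjoint per
#'   chromosome), e.g. from [segment_loh()].
#' @param chrom_info Chromosome table covering every segment chromosome.
#' @param variant_catalog Optional data.frame of known variant positions.
#' @return List with `per_chromosome` (data.frame `chrom, length_bp,
#'   variant_count, loh_bp, loh_variants, percent_loh`) and `totals`
#'   (`total_bp, total_variants, loh_bp, loh_variants, percent_loh_by_bp,
#'   percent_loh_by_variants`).
#' @seealso [loh_summary()] for building the same summary from
#'   already-tabulated per-chromosome LOH content.
#' @export
summarize_loh <- function(segments, chrom_info, variant_catalog = NULL) {
  if (nrow(segments)) {
    m <- match(segments$chrom, chrom_info$name)
    if (anyNA(m))
      stop_fmt("segment chromosome %s absent from chrom_info",
               segments$chrom[which(is.na(m))[1]])
    beyond <- segments$end > chrom_info$length_bp[m]
    if (any(beyond))
      stop_fmt("segment %s:%d-%d extends beyond chromosome length",
               segments$chrom[which(beyond)[1]],
               segments$start[which(beyond)[1]],
               segments$end[which(beyond)[1]])
  }
  loh_bp <- vapply(chrom_info$name, function(chr) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    sum(s$end - s$start + 1)
  }, 0)
  if (!is.null(variant_catalog)) {
    loh_var <- vapply(chrom_info$name, function(chr) {
      s <- segments[segments$chrom == chr, , drop = FALSE]
      p <- variant_catalog$pos[variant_catalog$chrom == chr]
      if (!nrow(s) || !length(p)) return(0)
      sum(vapply(p, function(x) any(x >= s$start & x <= s$end), TRUE))
    }, 0)
  } else {
    frac <- loh_bp / chrom_info$length_bp
    loh_var <- ifelse(frac >= 1, chrom_info$variant_count,
                      round(chrom_info$variant_count * frac))
  }
  per_chrom <- data.frame(chrom = chrom_info$name,
                          loh_bp = loh_bp, loh_variants = loh_var,
                          stringsAsFactors = FALSE)
  loh_summary(per_chrom, chrom_info)
}

#' LOH summary from per-chromosome LOH content
#'
#' Builds the genome-wide LOH summary from explicit per-chromosome LOH base
#' pairs and variant counts (as printed in a published per-chromosome LOH
#' table), against a chromosome reference table.
#'
#' @param per_chrom Data.frame `chrom, loh_bp, loh_variants`.
#' @param chrom_info Chromosome table.
#' @return Same shape as [summarize_loh()].
#' @examples
#' s <- loh_summary(bt474_loh_by_chromosome(), grch37_chromosomes())
#' round(s$totals$percent_loh_by_bp, 1)        # 22.2
#' round(s$totals$percent_loh_by_variants, 1)  # 20.3
#' @export
loh_summary <- function(per_chrom, chrom_info) {
  m <- match(chrom_info$name, per_chrom$chrom)
  loh_bp <- ifelse(is.na(m), 0, per_chrom$loh_bp[m])
  loh_var <- ifelse(is.na(m), 0, per_chrom$loh_variants[m])
  if (any(loh_bp > chrom_info$length_bp))
    stop_fmt("per-chromosome LOH bp exceeds chromosome length")
  per_chromosome <- data.frame(
    chrom = chrom_info$name,
    length_bp = chrom_info$length_bp,
    variant_count = chrom_info$variant_count,
    loh_bp = loh_bp,
    loh_variants = loh_var,
    percent_loh = 100 * loh_bp / chrom_info$length_bp,
    stringsAsFactors = FALSE)
  totals <- list(
    total_bp = sum(chrom_info$length_bp),
    total_variants = sum(chrom_info$variant_count),
    loh_bp = sum(loh_bp),
    loh_variants = sum(loh_var),
    percent_loh_by_bp = 100 * sum(loh_bp) / sum(chrom_info$length_bp),
    percent_loh_by_variants = 100 * sum(loh_var) / sum(chrom_info$variant_count))
  list(per_chromosome = per_chromosome, totals = totals)
}

#' Heterozygous/homozygous variant ratio
#'
#' The het/hom ratio is about 1.6 in a typical diploid European-ancestry
#' genome; extensive LOH depresses it toward (or below) 1.  Reported at
#' full precision and at the 2-decimal rounding used in summary tables.
#'
#' @param het_count,hom_count Variant counts (vectorized).
#' @return List with `ratio` (full precision) and `ratio_2dp`.
#' @examples
#' het_hom_ratio(1635402, 1531723)$ratio_2dp  # 1.07
#' @export
het_hom_ratio <- function(het_count, hom_count) {
  if (any(hom_count == 0))
    stop_fmt("het/hom ratio undefined: homozygous count is zero")
  r <- het_count / hom_count
  list(ratio = r, ratio_2dp = round_half_up(r, 2))
}
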