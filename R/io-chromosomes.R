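#' Read a chromosome reference table
#'
#' A chromosome table carries, per chromosome, its length in base pairs,
#' the number of known variants it harbors (used to express LOH content in
#' variant terms), and the centromere position in Mbp.
#'
#' @param file Path to a TSV with columns `name, length_bp, variant_count,
#'   centromere_mbp`.
#' @return Data.frame with normalized `"chr"`-prefixed names, ordered by
#'   canonical chromosome order.
#' @seealso [grch37_chromosomes()] for the packaged human build-37 table.
#' @export
read_chromosome_info <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("name", "length_bp", "variant_count", "centromere_mbp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_fmt("chromosome table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  df$name <- normalize_chrom(df$name)
  if (anyDuplicated(df$name))
    stop_fmt("duplicate chromosome name: %s", df$name[duplicated(df$name)][1])
  if (any(df$length_bp <= 0))
    stop_fmt("chromosome length must be positive")
  if (any(df$centromere_mbp * 1e6 < 0 | df$centromere_mbp * 1e6 > df$length_bp))
    stop_fmt("centromere position outside chromosome bounds")
  df[order(chrom_rank(df$name)), , drop = FALSE]
}

#' Write genomic segments as BED
#'
#' Converts from the package-internal 1-based inclusive convention to BED's
#' 0-based half-open convention and writes BED3 (or BED4 when a `name`
#' column is present).
#'
#' @param segments Data.frame with columns `chrom, start, end` and
#'   optionally `name`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = 1, end = 100)
#' f <- tempfile(fileext = ".bed")
#' write_segments_bed(seg, f)
#' readLines(f)  # "chr1\t0\t100"
#' @export
write_segments_bed <- function(segments, file) {
  if (nrow(segments) && any(segments$end < segments$start))
    stop_fmt("refusing to write interval with end < start (row %d)",
             which(segments$end < segments$start)[1])
  cols <- list(segments$chrom,
               format(segments$start - 1, scientific = FALSE, trim = TRUE),
               format(segments$end, scientific = FALSE, trim = TRUE))
  if (!is.null(segments$name)) cols <- c(cols, list(segments$name))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Read BED segments
#'
#' Companion reader for [write_segments_bed()]; converts BED's 0-based
#' half-open records back to 1-based inclusive intervals.
#'
#' @param file Path to a BED3/BED4 file.
#' @return Data.frame with columns `chrom, start, end` (and `name` for BED4).
#' @export
read_segments_bed <- function(file) {
  lines <- readLines(file)
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 4)) df$name <- vapply(parts, `[`, "", 4)
  df
}

aneukit_extdata <- function(name) {
  path <- system.file("extdata", name, package = "aneukit", mustWork = TRUE)
  path
}

#' Packaged published tables
#'
#' Accessors for the summary tables of the published BT-474 whole-genome
#' study that this package re-implements, transcribed to plain text and
#' shipped under `inst/extdata`:
#'
#' * `bt474_translocations()`: all 430 raw per-library interchromosomal
#'   translocation calls (110 STD, 175 LFR1, 145 LFR2), with the published
#'   post-clustering `sv_id` retained as a passthrough column and
#'   spreadsheet-rounded coordinates flagged `coarse`.
#' * `grch37_chromosomes()`: the human build-37 chromosome table
#'   (23 chromosomes, chr1-22 + X; lengths, Ensembl release-68 known-variant
#'   counts, centromere positions).
#' * `bt474_loh_by_chromosome()`: the published per-chromosome LOH content
#'   (percent, base pairs, known variants).
#' * `bt474_fusion_candidates()`: five interchromosomal gene fusions
#'   reported by external RNA-seq studies of BT-474, with the published
#'   support verdicts.
#' * `bt474_genome_stats()`: per-library genome statistics, including
#'   het/hom SNV counts.
#' * `na12878_snv_counts()`: genome-wide het/hom SNV counts of the diploid
#'   reference individual NA12878, the input of the LOH thought experiment.
#'
#' @return A data.frame, except `na12878_snv_counts()` which returns a
#'   named numeric vector with elements `hom` and `het`.
#' @name packaged-tables
#' @examples
#' nrow(bt474_translocations())  # 430
#' sum(grch37_chromosomes()$length_bp)  # 3,036,303,846
NULL

#' @rdname packaged-tables
#' @export
bt474_translocations <- function() {
  read_translocation_table(aneukit_extdata("bt474_translocations.tsv"))
}

#' @rdname packaged-tables
#' @export
grch37_chromosomes <- function() {
  read_chromosome_info(aneukit_extdata("grch37_chromosomes.tsv"))
}

#' @rdname packaged-tables
#' @export
bt474_loh_by_chromosome <- function() {
  df <- utils::read.delim(aneukit_extdata("bt474_loh_by_chromosome.tsv"),
                          stringsAsFactors = FALSE)
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' @rdname packaged-tables
#' @export
bt474_fusion_candidates <- function() {
  df <- utils::read.delim(aneukit_extdata("bt474_fusion_candidates.tsv"),
                          stringsAsFactors = FALSE)
  df$chrom_a <- normalize_chrom(df$chrom_a)
  df$chrom_b <- normalize_chrom(df$chrom_b)
  df
}

#' @rdname packaged-tables
#' @export
bt474_genome_stats <- function() {
  utils::read.delim(aneukit_extdata("bt474_genome_stats.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname packaged-tables
#' @export
na12878_snv_counts <- function() {
  df <- utils::read.delim(aneukit_extdata("na12878_snv_counts.tsv"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$count), df$zygosity)
}
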