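## Variant tables: biallelic SNVs with zygosity, per-allele read depths and
## optional LFR (384-well linked-compartment) annotation fields.  Two dialects
## are supported: a flat TSV, and a VCF-4.x subset whose per-sample extension
## fields mirror the LFR variant-file additions (WC, EWC, SWC, MINEWC,
## MAXEWC, HAPLINK, WIDS).

VARIANT_CORE_COLS <- c("chrom", "pos", "ref", "alt", "zygosity")
LFR_COLS <- c("haplink", "well_count", "exclusive_well_count",
              "shared_well_count", "min_exclusive", "max_exclusive",
              "well_ids")
ZYGOSITY_LEVELS <- c("het", "hom", "half-called")

validate_variants <- function(df) {
  missing_cols <- setdiff(VARIANT_CORE_COLS, names(df))
  if (length(missing_cols))
    stop_fmt("variant table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  bad <- !(df$zygosity %in% ZYGOSITY_LEVELS)
  if (any(bad))
    stop_fmt("unknown zygosity '%s' at row %d (expected het/hom/half-called)",
             df$zygosity[which(bad)[1]], which(bad)[1])
  if (!is.null(df$ref_depth) &&
      any(stats::na.omit(c(df$ref_depth, df$alt_depth)) < 0))
    stop_fmt("allele depths must be non-negative")
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Read a variant table
#'
#' Reads biallelic SNV records with zygosity and per-allele read depths,
#' plus optional LFR well/phasing annotation, from either a flat TSV or a
#' VCF-4.x subset.  Half-called genotypes (only one allele confidently
#' called) are preserved as their own zygosity class, not coerced to het or
#' hom; downstream LAF and het/hom-ratio computations exclude them.
#'
#' @param file Path to the table.
#' @param dialect `"auto"` (by file extension), `"tsv"`, or `"vcf"`.
#' @return Data.frame with columns `chrom, pos, ref, alt, zygosity,
#'   ref_depth, alt_depth` and, when present in the input, `library` and the
#'   LFR columns `haplink, well_count, exclusive_well_count,
#'   shared_well_count, min_exclusive, max_exclusive, well_ids`
#'   (`well_ids` is a comma-joined string of well indices).
#' @seealso [write_variant_table()], [parse_haplink()]
#' @export
read_variant_table <- function(file, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", file)) "vcf" else "tsv"
  if (dialect == "tsv") read_variants_tsv(file) else read_variants_vcf(file)
}

read_variants_tsv <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(df$well_ids)) {
    df$well_ids <- as.character(df$well_ids)
    df$well_ids[is.na(df$well_ids)] <- ""
  }
  if (!is.null(df$haplink)) {
    df$haplink <- as.character(df$haplink)
    df$haplink[is.na(df$haplink)] <- ""
  }
  validate_variants(df)
}

## VCF genotype string -> zygosity class
gt_to_zygosity <- function(gt) {
  z <- rep(NA_character_, length(gt))
  z[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  z[gt %in% c("1/1", "1|1")] <- "hom"
  z[grepl("\\.", gt)] <- "half-called"
  if (anyNA(z))
    stop_fmt("unsupported genotype '%s' (biallelic SNV subset)",
             gt[which(is.na(z))[1]])
  z
}

read_variants_vcf <- function(file) {
  vcf <- VariantAnnotation::readVcf(file, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt_list) != 1L))
    stop_fmt("multi-allelic records are outside the supported VCF subset")
  g <- VariantAnnotation::geno(vcf)
  if (ncol(vcf) != 1L)
    stop_fmt("expected a single-sample VCF (one library per file)")
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_list)),
    zygosity = gt_to_zygosity(as.character(g$GT[, 1])),
    stringsAsFactors = FALSE
  )
  if (!is.null(g$AD)) {
    ad <- g$AD
    # Number=R fields arrive as a list-matrix or an array
    if (is.list(ad)) {
      df$ref_depth <- vapply(ad[, 1], function(x) as.integer(x[1]), 0L)
      df$alt_depth <- vapply(ad[, 1], function(x) as.integer(x[2]), 0L)
    } else {
      df$ref_depth <- as.integer(ad[, 1, 1])
      df$alt_depth <- as.integer(ad[, 1, 2])
    }
  }
  df$library <- colnames(vcf)[1]
  if (!is.null(g$HAPLINK)) {
    hl <- as.character(g$HAPLINK[, 1])
    hl[hl == "." | is.na(hl)] <- ""
    df$haplink <- hl
  }
  int_field <- function(id) if (is.null(g[[id]])) NULL else as.integer(g[[id]][, 1])
  for (pair in list(c("WC", "well_count"), c("EWC", "exclusive_well_count"),
                    c("SWC", "shared_well_count"), c("MINEWC", "min_exclusive"),
                    c("MAXEWC", "max_exclusive"))) {
    v <- int_field(pair[1])
    if (!is.null(v)) df[[pair[2]]] <- v
  }
  if (!is.null(g$WIDS)) {
    w <- as.character(g$WIDS[, 1])
    w[w == "." | is.na(w)] <- ""
    df$well_ids <- gsub("|", ",", w, fixed = TRUE)
  }
  validate_variants(df)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()].  The VCF dialect writes a
#' single-sample VCF-4.2 subset (the sample column is the library) whose
#' FORMAT extension fields carry the LFR well statistics: `WC` (wells with
#' reads calling variant or reference), `EWC` (wells calling only one
#' allele), `SWC` (wells calling both), `MINEWC`/`MAXEWC` (per-allele
#' exclusive-well extremes), `HAPLINK` (phasing contig/haplotype ID) and
#' `WIDS` (`|`-separated variant well indices).
#'
#' @param variants Data.frame as returned by [read_variant_table()].
#' @param file Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Invisibly, `file`.
#' @export
write_variant_table <- function(variants, file, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  variants <- validate_variants(variants)
  if (dialect == "tsv") {
    keep <- intersect(c(VARIANT_CORE_COLS, "ref_depth", "alt_depth",
                        "library", LFR_COLS), names(variants))
    utils::write.table(variants[keep], file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(file))
  }
  write_variants_vcf(variants, file)
}

write_variants_vcf <- function(variants, file) {
  lib <- unique(variants$library %||% "SAMPLE")
  if (length(lib) != 1L)
    stop_fmt("VCF output holds one library per file; found: %s",
             paste(lib, collapse = ", "))
  has <- function(col) !is.null(variants[[col]])
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=aneukit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Read depth per allele">')
  fmt_ids <- c("GT", "AD")
  opt <- list(
    HAPLINK = '##FORMAT=<ID=HAPLINK,Number=1,Type=String,Description="Phasing contig and haplotype (Phased_a_b_h)">',
    WC = '##FORMAT=<ID=WC,Number=1,Type=Integer,Description="Wells with reads calling variant or reference">',
    EWC = '##FORMAT=<ID=EWC,Number=1,Type=Integer,Description="Wells calling exactly one allele">',
    SWC = '##FORMAT=<ID=SWC,Number=1,Type=Integer,Description="Wells calling both alleles">',
    MINEWC = '##FORMAT=<ID=MINEWC,Number=1,Type=Integer,Description="Minimum per-allele exclusive well count">',
    MAXEWC = '##FORMAT=<ID=MAXEWC,Number=1,Type=Integer,Description="Maximum per-allele exclusive well count">',
    WIDS = '##FORMAT=<ID=WIDS,Number=1,Type=String,Description="Variant well indices, |-separated">')
  col_of <- c(HAPLINK = "haplink", WC = "well_count", EWC = "exclusive_well_count",
              SWC = "shared_well_count", MINEWC = "min_exclusive",
              MAXEWC = "max_exclusive", WIDS = "well_ids")
  for (id in names(opt)) {
    if (has(col_of[[id]])) {
      hdr <- c(hdr, opt[[id]])
      fmt_ids <- c(fmt_ids, id)
    }
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", lib, sep = "\t"))

  gt <- c(het = "0/1", hom = "1/1", `half-called` = "1/.")[variants$zygosity]
  ad <- if (has("ref_depth"))
    paste0(variants$ref_depth, ",", variants$alt_depth) else
      rep(".", nrow(variants))
  sample_parts <- list(gt, ad)
  for (id in setdiff(fmt_ids, c("GT", "AD"))) {
    v <- variants[[col_of[[id]]]]
    v <- as.character(v)
    v[is.na(v) | v == ""] <- "."
    if (id == "WIDS") v <- gsub(",", "|", v, fixed = TRUE)
    sample_parts <- c(sample_parts, list(v))
  }
  sample_col <- do.call(paste, c(sample_parts, sep = ":"))
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", paste(fmt_ids, collapse = ":"),
                sample_col, sep = "\t")[ord]
  writeLines(c(hdr, body), file)
  invisible(file)
}
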