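#' Read a translocation call table
#'
#' Reads a tab-separated table of raw per-library interchromosomal
#' translocation calls.  Each row is one breakpoint-pair call: a window on
#' side A, a window on side B, a two-letter orientation code (`f` = forward,
#' `r` = reverse relative to the reference; first letter side A, second
#' side B) and the library the call came from.
#'
#' Coordinates given in scientific notation (as happens when a table has
#' passed through a spreadsheet, e.g. `"2.32E+08"`) are parsed to integers
#' and the affected rows are flagged `coarse = TRUE`: such coordinates have
#' been rounded to roughly 1 Mb precision, far coarser than the 5 kb
#' clustering window, and downstream precision-sensitive comparisons may
#' want to exclude them.  An explicit `coarse` column in the input takes
#' precedence.  A `sv_id` column, when present, is retained as an inert
#' passthrough (it is never consulted by [cluster_translocations()]).
#'
#' @param file Path (or connection) to a TSV with columns
#'   `chrA, chrA_start, chrA_end, chrB, chrB_start, chrB_end, orientation,
#'   library` and optionally `sv_id` and `coarse`.
#' @return A data.frame with columns `chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b, orientation, library, coarse` (plus `sv_id` if present),
#'   chromosome names normalized to `"chr"`-prefixed form, coordinates
#'   1-based inclusive.
#' @seealso [bt474_translocations()] for the packaged published call table.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrA\tchrA_start\tchrA_end\tchrB\tchrB_start\tchrB_end\torientation\tlibrary",
#'              "chr1\t5715019\t5715320\tchr12\t34295113\t34295399\trf\tLFR1"), tf)
#' read_translocation_table(tf)
#' @export
read_translocation_table <- function(file) {
  raw <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrA", "chrA_start", "chrA_end", "chrB", "chrB_start",
            "chrB_end", "orientation", "library")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_fmt("translocation table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))

  parse_coord <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop_fmt("non-numeric %s at row %d", col, which(is.na(v))[1])
    v
  }
  is_sci <- function(x) grepl("[eE]", x)

  out <- data.frame(
    chrom_a = normalize_chrom(raw$chrA),
    start_a = parse_coord(raw$chrA_start, "chrA_start"),
    end_a = parse_coord(raw$chrA_end, "chrA_end"),
    chrom_b = normalize_chrom(raw$chrB),
    start_b = parse_coord(raw$chrB_start, "chrB_start"),
    end_b = parse_coord(raw$chrB_end, "chrB_end"),
    orientation = trimws(raw$orientation),
    library = trimws(raw$library),
    stringsAsFactors = FALSE
  )
  if ("coarse" %in% names(raw)) {
    out$coarse <- as.logical(raw$coarse)
  } else {
    out$coarse <- is_sci(raw$chrA_start) | is_sci(raw$chrA_end) |
      is_sci(raw$chrB_start) | is_sci(raw$chrB_end)
  }
  if ("sv_id" %in% names(raw))
    out$sv_id <- as.integer(raw$sv_id)

  bad_or <- !(out$orientation %in% c("ff", "fr", "rf", "rr"))
  if (any(bad_or))
    stop_fmt("unknown orientation code '%s' at row %d",
             out$orientation[which(bad_or)[1]], which(bad_or)[1])
  intra <- out$chrom_a == out$chrom_b
  if (any(intra))
    stop_fmt("intrachromosomal call at row %d (%s); only interchromosomal calls are supported",
             which(intra)[1], out$chrom_a[which(intra)[1]])
  bad_win <- out$start_a > out$end_a | out$start_b > out$end_b
  if (any(bad_win))
    stop_fmt("breakpoint window with start > end at row %d", which(bad_win)[1])
  out
}

#' Write a translocation call table
#'
#' Inverse of [read_translocation_table()]; column order follows the
#' published table schema.
#'
#' @param calls Data.frame as returned by [read_translocation_table()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_translocation_table <- function(calls, file) {
  df <- data.frame(chrA = calls$chrom_a,
                   chrA_start = format(calls$start_a, scientific = FALSE, trim = TRUE),
                   chrA_end = format(calls$end_a, scientific = FALSE, trim = TRUE),
                   chrB = calls$chrom_b,
                   chrB_start = format(calls$start_b, scientific = FALSE, trim = TRUE),
                   chrB_end = format(calls$end_b, scientific = FALSE, trim = TRUE),
                   orientation = calls$orientation,
                   library = calls$library,
                   stringsAsFactors = FALSE)
  if (!is.null(calls$coarse)) df$coarse <- calls$coarse
  if (!is.null(calls$sv_id)) df <- cbind(sv_id = calls$sv_id, df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
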