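#' @keywords internal
"_PACKAGE"

## Rounding used wherever a table-style 2-decimal figure is reported:
## nearest, ties away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

## Canonical chromosome order: 1..22, X, Y.
CHROM_LEVELS <- paste0("chr", c(1:22, "X", "Y"))

#' Normalize chromosome names
#'
#' Accepts `"1"`, `"chr1"`, `"X"`, `"chrX"` and returns the `"chr"`-prefixed
#' form used internally throughout the package.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of `"chr"`-prefixed names.
#' @examples
#' normalize_chrom(c("1", "chrX", "chr22"))
#' @export
normalize_chrom <- function(x) {
  if (!length(x)) return(character(0))
  x <- trimws(as.character(x))
  bare <- toupper(sub("^[Cc][Hh][Rr]", "", x))
  bad <- !(bare %in% c(as.character(1:22), "X", "Y", "M", "MT"))
  if (any(bad))
    stop_fmt("unrecognized chromosome name(s): %s",
             paste(unique(x[bad]), collapse = ", "))
  paste0("chr", bare)
}

## Integer rank in canonical chromosome order (chrM/MT sort last).
chrom_rank <- function(x) {
  r <- match(x, CHROM_LEVELS)
  r[is.na(r)] <- length(CHROM_LEVELS) + 1L
  r
}

## Gap between two 1-based inclusive intervals: 0 when they overlap or touch,
## otherwise the number of bases separating them.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

## Minimal union-find for single-linkage closure.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}
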