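#' Variant identity keys
#'
#' A variant's identity is its site and alleles — `chrom:pos:ref:alt` —
#' with genotype deliberately excluded: in an aneuploid genome the same
#' variant can be called het in one library and hom in another without
#' being a different variant.
#'
#' @param variants Variant table (or any data.frame with `chrom, pos, ref,
#'   alt`).
#' @return Character vector of keys.
#' @export
variant_keys <- function(variants) {
  paste(normalize_chrom(variants$chrom), variants$pos,
        variants$ref, variants$alt, sep = ":")
}

#' Overlap of variant call sets across libraries
#'
#' Counts every intersection region of 2 or 3 named call sets (the regions
#' of a Venn diagram).  Duplicate keys within one set are deduplicated with
#' a warning.
#'
#' @param call_sets Named list of character key vectors (see
#'   [variant_keys()]) or variant data.frames.
#' @return Data.frame with columns `region` (`"&"`-joined set names) and
#'   `count`; region counts sum to the union size.
#' @examples
#' overlap_variants(list(A = c("k1", "k2"), B = c("k2", "k3")))
#' @export
overlap_variants <- function(call_sets) {
  if (length(call_sets) < 2 || length(call_sets) > 3)
    stop_fmt("overlap_variants expects 2 or 3 named call sets")
  if (is.null(names(call_sets)) || any(names(call_sets) == ""))
    stop_fmt("call sets must be named")
  sets <- lapply(names(call_sets), function(nm) {
    x <- call_sets[[nm]]
    if (is.data.frame(x)) x <- variant_keys(x)
    if (anyDuplicated(x)) {
      warning(sprintf("set '%s' contains %d duplicate keys; deduplicated",
                      nm, sum(duplicated(x))), call. = FALSE)
      x <- unique(x)
    }
    x
  })
  names(sets) <- names(call_sets)

  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(names(sets)[row], collapse = "&"))

  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = combos))
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Recall against an external variant panel
#'
#' The fraction of panel variants also present in the call set — the
#' quality check used when comparing whole-genome calls against a targeted
#' cancer cell-line panel.
#'
#' @param calls Character keys (or variant data.frame) of the call set.
#' @param panel Character keys (or variant data.frame) of the panel;
#'   must be nonempty.
#' @return List with `recall`, `n_panel`, `n_found`, and `missing` (panel
#'   keys absent from the calls).
#' @export
panel_recall <- function(calls, panel) {
  if (is.data.frame(calls)) calls <- variant_keys(calls)
  if (is.data.frame(panel)) panel <- variant_keys(panel)
  panel <- unique(panel)
  if (!length(panel))
    stop_fmt("panel recall undefined for an empty panel")
  calls <- unique(calls)
  found <- panel %in% calls
  list(recall = mean(found), n_panel = length(panel),
       n_found = sum(found), missing = panel[!found])
}
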