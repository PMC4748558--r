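#' Canonicalize translocation calls
#'
#' Puts every call's chromosome pair in the fixed chromosome order
#' (1..22, X, Y).  When sides are swapped the two orientation letters are
#' exchanged (letter order reversed, letters not complemented): the letters
#' are defined per side relative to the reference, so swapping sides swaps
#' which letter belongs to which region but gives no grounds for flipping
#' f to r.
#'
#' @param calls Data.frame from [read_translocation_table()].
#' @return The same data.frame with `chrom_a` preceding `chrom_b`
#'   everywhere.
#' @examples
#' x <- data.frame(chrom_a = "chr12", start_a = 10, end_a = 20,
#'                 chrom_b = "chr2", start_b = 5, end_b = 6,
#'                 orientation = "fr", library = "STD")
#' canonicalize_calls(x)$orientation  # "rf"
#' @export
canonicalize_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  swap <- chrom_rank(calls$chrom_a) > chrom_rank(calls$chrom_b)
  if (any(calls$chrom_a == calls$chrom_b))
    stop_fmt("intrachromosomal call cannot be canonicalized")
  if (any(swap)) {
    tmp <- calls[swap, c("chrom_a", "start_a", "end_a")]
    calls[swap, c("chrom_a", "start_a", "end_a")] <-
      calls[swap, c("chrom_b", "start_b", "end_b")]
    calls[swap, c("chrom_b", "start_b", "end_b")] <- tmp
    ori <- calls$orientation[swap]
    calls$orientation[swap] <- paste0(substr(ori, 2, 2), substr(ori, 1, 1))
  }
  calls
}

is_canonical <- function(calls) {
  all(chrom_rank(calls$chrom_a) < chrom_rank(calls$chrom_b))
}

#' Cluster translocation calls across libraries
#'
#' Merges raw per-library breakpoint-pair calls into events by single
#' linkage: two calls are directly linked iff they share the canonical
#' chromosome pair and orientation, their side-A breakpoint windows lie
#' within `window` bp of each other (gap between intervals; overlapping
#' windows have gap 0), and their side-B windows likewise.  Clusters are
#' the transitive closure of this relation, so within- and between-library
#' aggregation happen under one rule.
#'
#' Cluster IDs are assigned deterministically by (chromosome pair in
#' canonical order, minimal side-A start).  A `sv_id` column, if present,
#' is never consulted.
#'
#' @param calls Canonicalized calls (see [canonicalize_calls()]); input that
#'   is not canonical is refused.
#' @param window Linkage window in bp (default 5000).
#' @return The input data.frame with an integer `cluster_id` column added;
#'   the `window` used is attached as an attribute.
#' @seealso [sv_cluster_table()], [library_overlap_counts()]
#' @export
cluster_translocations <- function(calls, window = 5000) {
  if (!is.numeric(window) || window < 0)
    stop_fmt("window must be a non-negative number of base pairs")
  if (!nrow(calls)) {
    calls$cluster_id <- integer(0)
    return(calls)
  }
  if (!is_canonical(calls))
    stop_fmt("calls are not canonical; apply canonicalize_calls() first")

  n <- nrow(calls)
  parent <- uf_new(n)
  groups <- split(seq_len(n),
                  paste(calls$chrom_a, calls$chrom_b, calls$orientation))
  for (idx in groups) {
    if (length(idx) < 2) next
    idx <- idx[order(calls$start_a[idx])]
    sa <- calls$start_a[idx]; ea <- calls$end_a[idx]
    sb <- calls$start_b[idx]; eb <- calls$end_b[idx]
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq((i + 1), length(idx))) {
        if (sa[j] - max(ea[i], sa[i]) > window) break  # sorted by start_a
        if (interval_gap(sa[i], ea[i], sa[j], ea[j]) <= window &&
            interval_gap(sb[i], eb[i], sb[j], eb[j]) <= window)
          parent <- uf_union(parent, idx[i], idx[j])
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)

  # deterministic ids: canonical chromosome pair, then minimal side-A start
  min_start <- tapply(calls$start_a, root, min)
  roots <- as.integer(names(min_start))
  ord <- order(chrom_rank(calls$chrom_a[roots]),
               chrom_rank(calls$chrom_b[roots]),
               min_start,
               tapply(calls$start_b, root, min),
               calls$orientation[roots])
  id_of <- stats::setNames(seq_along(roots), roots[ord])
  calls$cluster_id <- as.integer(id_of[as.character(root)])
  attr(calls, "window") <- window
  calls
}

#' Summarize clusters
#'
#' One row per cluster: canonical chromosome pair, orientation, merged
#' breakpoint spans, member and library counts.  When the input carries a
#' `sv_id` passthrough column the distinct IDs are joined into `sv_ids`.
#'
#' @param clustered Output of [cluster_translocations()].
#' @return Data.frame with one row per `cluster_id`.
#' @export
sv_cluster_table <- function(clustered) {
  if (!nrow(clustered))
    return(data.frame(cluster_id = integer(), chrom_a = character(),
                      start_a = numeric(), end_a = numeric(),
                      chrom_b = character(), start_b = numeric(),
                      end_b = numeric(), orientation = character(),
                      n_members = integer(), n_libraries = integer(),
                      libraries = character(), sv_ids = character(),
                      stringsAsFactors = FALSE))
  idx <- split(seq_len(nrow(clustered)), clustered$cluster_id)
  rows <- lapply(idx, function(i) {
    libs <- sort(unique(clustered$library[i]))
    data.frame(
      cluster_id = clustered$cluster_id[i[1]],
      chrom_a = clustered$chrom_a[i[1]],
      start_a = min(clustered$start_a[i]),
      end_a = max(clustered$end_a[i]),
      chrom_b = clustered$chrom_b[i[1]],
      start_b = min(clustered$start_b[i]),
      end_b = max(clustered$end_b[i]),
      orientation = clustered$orientation[i[1]],
      n_members = length(i),
      n_libraries = length(libs),
      libraries = paste(libs, collapse = ","),
      sv_ids = if (is.null(clustered$sv_id)) NA_character_ else
        paste(sort(unique(clustered$sv_id[i])), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library overlap of clustered events
#'
#' Counts, per library, the clusters containing at least one call from that
#' library; the clusters shared by two or more libraries; and the full
#' membership-pattern region counts of an overlap (Venn) diagram.
#'
#' @param clustered Output of [cluster_translocations()].
#' @return List with elements `total` (number of clusters), `per_library`
#'   (named integer vector), `shared_two_plus`, and `regions` (counts named
#'   by `"&"`-joined library combinations, summing to `total`).
#' @export
library_overlap_counts <- function(clustered) {
  lib_sets <- lapply(split(clustered$library, clustered$cluster_id),
                     function(x) sort(unique(x)))
  libs <- sort(unique(clustered$library))
  per_library <- vapply(libs, function(l)
    sum(vapply(lib_sets, function(s) l %in% s, TRUE)), 0L)
  pattern <- vapply(lib_sets, paste, "", collapse = "&")
  regions <- table(pattern)
  list(total = length(lib_sets),
       per_library = per_library,
       shared_two_plus = sum(lengths(lib_sets) >= 2),
       regions = stats::setNames(as.integer(regions), names(regions)))
}
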