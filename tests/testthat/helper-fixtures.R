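# Shared builders for synthetic test inputs, plus an independent
# brute-force clustering oracle.

toy_chrom_info <- function(lengths = c(chr1 = 30e6, chr2 = 30e6),
                           variants = 0) {
  data.frame(name = names(lengths), length_bp = as.numeric(lengths),
             variant_count = rep_len(variants, length(lengths)),
             centromere_mbp = as.numeric(lengths) * 0.45 / 1e6,
             stringsAsFactors = FALSE)
}

# random interchromosomal calls (already canonical), clumped so that some
# pairs fall within linking distance and some do not
random_calls <- function(n, seed, n_centers = max(2, n %/% 3),
                         spread = 8000) {
  set.seed(seed)
  chrom_pairs <- rbind(c("chr1", "chr2"), c("chr1", "chr3"),
                       c("chr2", "chr3"))
  centers <- data.frame(
    pair = sample(nrow(chrom_pairs), n_centers, replace = TRUE),
    a = sample.int(2e7, n_centers), b = sample.int(2e7, n_centers),
    orientation = sample(c("ff", "fr", "rf", "rr"), n_centers,
                         replace = TRUE))
  pick <- sample(n_centers, n, replace = TRUE)
  off_a <- sample(-spread:spread, n, replace = TRUE)
  off_b <- sample(-spread:spread, n, replace = TRUE)
  w_a <- sample(100:800, n, replace = TRUE)
  w_b <- sample(100:800, n, replace = TRUE)
  data.frame(
    chrom_a = chrom_pairs[centers$pair[pick], 1],
    start_a = centers$a[pick] + off_a,
    end_a = centers$a[pick] + off_a + w_a,
    chrom_b = chrom_pairs[centers$pair[pick], 2],
    start_b = centers$b[pick] + off_b,
    end_b = centers$b[pick] + off_b + w_b,
    orientation = centers$orientation[pick],
    library = sample(c("STD", "LFR1", "LFR2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# brute-force oracle: explicit pairwise linkage graph + transitive closure
# by repeated expansion (no union-find, no sorting shortcuts)
cluster_bruteforce <- function(calls, window) {
  n <- nrow(calls)
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- calls$chrom_a[i] == calls$chrom_a[j] &&
        calls$chrom_b[i] == calls$chrom_b[j] &&
        calls$orientation[i] == calls$orientation[j] &&
        gap(calls$start_a[i], calls$end_a[i],
            calls$start_a[j], calls$end_a[j]) <= window &&
        gap(calls$start_b[i], calls$end_b[i],
            calls$start_b[j], calls$end_b[j]) <= window
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1
      comp[which(reach[i, ])] <- k
    }
  }
  comp
}

# compare two partitions given as membership vectors
same_partition <- function(a, b) {
  pa <- lapply(split(seq_along(a), a), sort)
  pb <- lapply(split(seq_along(b), b), sort)
  setequal(lapply(pa, paste, collapse = ","),
           lapply(pb, paste, collapse = ","))
}

# LAF window frame with given laf values on one chromosome (100 kb bins)
laf_frame <- function(laf, chrom = "chr1", bin = 1e5) {
  n <- length(laf)
  data.frame(chrom = chrom, window_index = seq_len(n),
             start = (seq_len(n) - 1) * bin + 1, end = seq_len(n) * bin,
             n_variants = ifelse(is.na(laf), 0L, 10L), laf = laf,
             stringsAsFactors = FALSE)
}

small_params <- function(seed = 7, ...) {
  defaults <- list(seed = seed,
                   chrom_lengths = c(chr1 = 8e6, chr2 = 8e6),
                   variant_density = 1 / 2000,
                   n_cn_segments = 2, cn_segment_mean_bp = 1.5e6,
                   loh_fraction = 0, n_translocations = 6,
                   fragments_per_well = 30)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
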