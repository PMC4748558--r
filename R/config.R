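#' Pipeline configuration
#'
#' Collects the tunable constants of the pipeline in one validated list.
#' The defaults are the values used throughout the published analysis this
#' package re-implements: 5 kb breakpoint-clustering windows, 100 kb
#' lesser-allele-fraction and coverage bins, a strict >10 Mb minimum length
#' for LOH segments, an exact-zero LAF threshold, tetraploid normalization,
#' and a two-well minimum for believing an LFR variant call.
#'
#' @param cluster_window_bp Breakpoint linkage window in bp (default 5000).
#' @param laf_bin_bp Window size for LAF and coverage binning (default 1e5).
#' @param loh_min_length_bp Strict minimum genomic extent of an LOH segment
#'   (default 1e7; segments must exceed this).
#' @param laf_zero_epsilon LAF at or below this value counts as "zero" when
#'   segmenting LOH (default 0; real depth noise may warrant e.g. 0.02).
#' @param target_ploidy Ploidy that coverage is normalized to (default 4).
#' @param min_variant_wells Minimum number of distinct LFR wells that must
#'   contain reads calling a variant before it is believed (default 2).
#' @param max_gap_windows Number of consecutive variant-free LAF windows
#'   tolerated inside an LOH segment (default 5, i.e. 0.5 Mb at 100 kb bins;
#'   bridges centromeric variant deserts).
#' @param mapping_error_shared_frac Heterozygous calls whose shared-well
#'   fraction exceeds this are flagged as likely mapping errors (default 0.5).
#' @param random_seed Optional integer seed recorded for simulation runs.
#' @return A named list with class `"aneukit_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$cluster_window_bp
#' @export
pipeline_config <- function(cluster_window_bp = 5000,
                            laf_bin_bp = 100000,
                            loh_min_length_bp = 10000000,
                            laf_zero_epsilon = 0,
                            target_ploidy = 4,
                            min_variant_wells = 2,
                            max_gap_windows = 5,
                            mapping_error_shared_frac = 0.5,
                            random_seed = NULL) {
  for (nm in c("cluster_window_bp", "laf_bin_bp", "loh_min_length_bp",
               "target_ploidy")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop_fmt("%s must be a single positive number", nm)
  }
  if (laf_zero_epsilon < 0 || laf_zero_epsilon >= 0.5)
    stop_fmt("laf_zero_epsilon must lie in [0, 0.5)")
  if (min_variant_wells < 0 || max_gap_windows < 0)
    stop_fmt("counts must be non-negative")
  structure(list(cluster_window_bp = cluster_window_bp,
                 laf_bin_bp = laf_bin_bp,
                 loh_min_length_bp = loh_min_length_bp,
                 laf_zero_epsilon = laf_zero_epsilon,
                 target_ploidy = target_ploidy,
                 min_variant_wells = min_variant_wells,
                 max_gap_windows = max_gap_windows,
                 mapping_error_shared_frac = mapping_error_shared_frac,
                 random_seed = random_seed),
            class = "aneukit_config")
}
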