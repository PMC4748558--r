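## Synthetic aneuploid-genome generator.  The default stated world: a
## desk-scale near-tetraploid genome (3 toy chromosomes x 30 Mb) carrying
## megabase-sized copy-number segments, ~22% of the genome in LOH, a
## het/hom variant ratio of 1.6 outside LOH, ~100x read depth, three
## libraries with jittered translocation calls, and a 384-well LFR layer
## with ~40 kb fragments and single-well polymerase errors.

#' Simulation parameters
#'
#' @param seed Master seed; every generator derives its own substream from
#'   it (`seed + k` for small fixed `k`), so partial regeneration is
#'   reproducible.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param ploidy Baseline total copy number (default 4: two copies of each
#'   parental haplotype).
#' @param n_cn_segments Number of planted copy-number segments.
#' @param cn_segment_mean_bp Mean planted-segment length (exponential).
#' @param cn_copies Total copy numbers sampled for planted segments.
#' @param loh_fraction Target genome fraction in LOH.
#' @param loh_region_mean_bp Mean LOH interval length.
#' @param het_hom_ratio Het/hom variant ratio outside LOH (default 1.6,
#'   the typical European-ancestry diploid value).
#' @param variant_density Variants per bp (default 1/1500).
#' @param depth Mean read depth at baseline ploidy (default 100).
#' @param half_called_rate Fraction of reported records left half-called.
#' @param libraries Library names.
#' @param n_translocations Planted interchromosomal translocation events.
#' @param breakpoint_jitter_bp Max per-library breakpoint jitter (< 5 kb
#'   clustering window; default 2000).
#' @param call_window_bp Range of reported breakpoint-window widths.
#' @param dropout Per-library probability of missing a true event.
#' @param false_calls_per_library Library-specific spurious calls added.
#' @param n_wells LFR plate size (default 384).
#' @param fragment_length_bp Mean LFR fragment length (default 40 kb).
#' @param fragments_per_well Fragments per well (default 300).
#' @param polymerase_error_rate Injected single-well false variants, as a
#'   fraction of true variant loci (default 0.01).
#' @return Validated list with class `"sim_params"`.
#' @export
sim_params <- function(seed = 1,
                       chrom_lengths = stats::setNames(rep(30e6, 3),
                                                       paste0("chr", 1:3)),
                       ploidy = 4,
                       n_cn_segments = 6,
                       cn_segment_mean_bp = 3e6,
                       cn_copies = c(2, 3, 5, 6, 8),
                       loh_fraction = 0.22,
                       loh_region_mean_bp = 15e6,
                       het_hom_ratio = 1.6,
                       variant_density = 1 / 1500,
                       depth = 100,
                       half_called_rate = 0.01,
                       libraries = c("STD", "LFR1", "LFR2"),
                       n_translocations = 25,
                       breakpoint_jitter_bp = 2000,
                       call_window_bp = c(100, 1000),
                       dropout = 0.1,
                       false_calls_per_library = 2,
                       n_wells = 384,
                       fragment_length_bp = 40000,
                       fragments_per_well = 300,
                       polymerase_error_rate = 0.01) {
  if (!is.numeric(seed) || seed < 0 || seed > 2^30)
    stop_fmt("seed must be an integer in [0, 2^30]")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  for (r in c(loh_fraction, dropout, half_called_rate,
              polymerase_error_rate)) {
    if (r < 0 || r > 1) stop_fmt("rates must lie in [0, 1]")
  }
  if (breakpoint_jitter_bp >= 5000)
    stop_fmt("breakpoint jitter must stay below the 5 kb clustering window")
  p <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
            ploidy = ploidy, n_cn_segments = n_cn_segments,
            cn_segment_mean_bp = cn_segment_mean_bp, cn_copies = cn_copies,
            loh_fraction = loh_fraction,
            loh_region_mean_bp = loh_region_mean_bp,
            het_hom_ratio = het_hom_ratio,
            variant_density = variant_density, depth = depth,
            half_called_rate = half_called_rate, libraries = libraries,
            n_translocations = n_translocations,
            breakpoint_jitter_bp = breakpoint_jitter_bp,
            call_window_bp = call_window_bp, dropout = dropout,
            false_calls_per_library = false_calls_per_library,
            n_wells = n_wells, fragment_length_bp = fragment_length_bp,
            fragments_per_well = fragments_per_well,
            polymerase_error_rate = polymerase_error_rate)
  structure(p, class = "sim_params")
}

## Piecewise-constant per-haplotype copy lookup.
copies_at <- function(model, chrom, pos) {
  h1 <- numeric(length(pos))
  h2 <- numeric(length(pos))
  for (chr in unique(chrom)) {
    seg <- model$segments[model$segments$chrom == chr, , drop = FALSE]
    sel <- chrom == chr
    idx <- findInterval(pos[sel], seg$start)
    h1[sel] <- seg$hap1[idx]
    h2[sel] <- seg$hap2[idx]
  }
  data.frame(hap1 = h1, hap2 = h2)
}

## Draw disjoint intervals on the genome by rejection sampling.  With
## trim_to_target, the total lands exactly on n_target_bp: the residual
## below min_bp is added by extending an already-placed interval, so every
## interval stays at least min_bp long (keeps planted LOH above the >10 Mb
## detectability floor).
draw_disjoint <- function(chrom_lengths, n_target_bp, mean_bp, taken,
                          min_bp = 1e6, trim_to_target = TRUE,
                          max_tries = 5000) {
  out <- list()
  covered <- 0
  tries <- 0
  chroms <- names(chrom_lengths)
  clash_with <- function(ivs, chr, start, end) {
    any(vapply(ivs, function(r)
      r$chrom == chr && r$start <= end + 1 && r$end >= start - 1, TRUE))
  }
  while (covered < n_target_bp) {
    remaining <- n_target_bp - covered
    if (trim_to_target && remaining < min_bp && length(out)) {
      # extend an existing interval by the residual
      extended <- FALSE
      for (k in seq_along(out)) {
        r <- out[[k]]
        new_end <- r$end + remaining
        others <- c(taken, out[-k])
        if (new_end <= chrom_lengths[[r$chrom]] &&
            !clash_with(others, r$chrom, r$start, new_end)) {
          out[[k]]$end <- new_end
          covered <- covered + remaining
          extended <- TRUE
          break
        }
        new_start <- r$start - remaining
        if (new_start >= 1 &&
            !clash_with(others, r$chrom, new_start, r$end)) {
          out[[k]]$start <- new_start
          covered <- covered + remaining
          extended <- TRUE
          break
        }
      }
      if (extended) next
    }
    tries <- tries + 1
    if (tries > max_tries)
      stop_fmt("could not place %d bp of disjoint intervals", n_target_bp)
    chr <- sample(chroms, 1, prob = chrom_lengths)
    len <- max(min_bp, round(stats::rexp(1, 1 / mean_bp)))
    if (trim_to_target && remaining >= min_bp)
      len <- max(min_bp, min(len, remaining))
    len <- min(len, chrom_lengths[[chr]])
    start <- floor(stats::runif(1, 1, chrom_lengths[[chr]] - len + 1))
    end <- start + len - 1
    if (clash_with(c(taken, out), chr, start, end)) next
    out <- c(out, list(list(chrom = chr, start = start, end = end)))
    covered <- covered + len
  }
  out
}

#' Build a synthetic aneuploid genome model
#'
#' Generates the planted truth: per-chromosome per-haplotype copy-number
#' segments, LOH intervals (exactly one surviving parental haplotype;
#' realized fraction matches the target up to interval trimming), a
#' variant list with zygosity and haplotype assignment (het variants
#' inside LOH are dropped when they sat on the lost haplotype and become
#' homozygous otherwise), and a translocation truth list.  Deterministic
#' given `params$seed`.
#'
#' @param params A [sim_params()] list.
#' @return List of class `"genome_model"` with elements `params`,
#'   `chrom_info`, `segments`, `loh_intervals`, `variants`,
#'   `translocations`, `realized_loh_fraction`.
#' @export
make_genome_model <- function(params = sim_params()) {
  set.seed(params$seed)
  cl <- params$chrom_lengths
  genome_bp <- sum(cl)
  base_hap <- params$ploidy / 2

  # LOH intervals first (they own their territory), then CN segments.
  loh_iv <- if (params$loh_fraction > 0)
    draw_disjoint(cl, round(params$loh_fraction * genome_bp),
                  params$loh_region_mean_bp, taken = list(),
                  min_bp = 1.2e7) else list()
  cn_iv <- if (params$n_cn_segments > 0)
    draw_disjoint(cl, params$n_cn_segments * params$cn_segment_mean_bp,
                  params$cn_segment_mean_bp, taken = loh_iv,
                  trim_to_target = FALSE) else list()

  events <- c(
    lapply(loh_iv, function(r) {
      surv <- sample(1:2, 1)
      c(r, list(hap1 = if (surv == 1) base_hap else 0,
                hap2 = if (surv == 2) base_hap else 0, is_loh = TRUE))
    }),
    lapply(cn_iv, function(r) {
      total <- sample(params$cn_copies, 1)
      h1 <- if (total >= 2) sample(seq_len(total - 1), 1) else total
      c(r, list(hap1 = h1, hap2 = total - h1, is_loh = FALSE))
    }))

  segments <- do.call(rbind, lapply(names(cl), function(chr) {
    ev <- Filter(function(e) e$chrom == chr, events)
    ev <- ev[order(vapply(ev, `[[`, 0, "start"))]
    starts <- c(1)
    rows <- list()
    cursor <- 1
    for (e in ev) {
      if (e$start > cursor)
        rows <- c(rows, list(data.frame(chrom = chr, start = cursor,
                                        end = e$start - 1, hap1 = base_hap,
                                        hap2 = base_hap, is_loh = FALSE)))
      rows <- c(rows, list(data.frame(chrom = chr, start = e$start,
                                      end = e$end, hap1 = e$hap1,
                                      hap2 = e$hap2, is_loh = e$is_loh)))
      cursor <- e$end + 1
    }
    if (cursor <= cl[[chr]])
      rows <- c(rows, list(data.frame(chrom = chr, start = cursor,
                                      end = cl[[chr]], hap1 = base_hap,
                                      hap2 = base_hap, is_loh = FALSE)))
    do.call(rbind, rows)
  }))
  rownames(segments) <- NULL

  loh_intervals <- if (length(loh_iv))
    do.call(rbind, lapply(loh_iv, as.data.frame)) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
  realized <- sum(loh_intervals$end - loh_intervals$start + 1) / genome_bp

  # variants: density * length per chromosome, het:hom ratio outside LOH
  p_het <- params$het_hom_ratio / (1 + params$het_hom_ratio)
  variants <- do.call(rbind, lapply(names(cl), function(chr) {
    n <- stats::rpois(1, params$variant_density * cl[[chr]])
    pos <- sort(sample.int(cl[[chr]], n))
    zyg <- ifelse(stats::runif(n) < p_het, "het", "hom")
    hap <- ifelse(zyg == "het", sample(1:2, n, replace = TRUE), NA)
    data.frame(chrom = chr, pos = pos, zygosity = zyg, haplotype = hap,
               stringsAsFactors = FALSE)
  }))
  cp <- copies_at(list(segments = segments), variants$chrom, variants$pos)
  hap_copies <- ifelse(is.na(variants$haplotype), NA,
                       ifelse(variants$haplotype == 1, cp$hap1, cp$hap2))
  in_loh <- cp$hap1 == 0 | cp$hap2 == 0
  variants$loh_converted <- FALSE
  lost <- variants$zygosity == "het" & in_loh & hap_copies == 0
  conv <- variants$zygosity == "het" & in_loh & hap_copies > 0
  variants$zygosity[conv] <- "hom"
  variants$loh_converted[conv] <- TRUE
  variants <- variants[!lost, , drop = FALSE]
  # alt-bearing haplotypes (true homs sit on both)
  variants$alt_on_hap1 <- is.na(variants$haplotype) | variants$haplotype == 1
  variants$alt_on_hap2 <- is.na(variants$haplotype) | variants$haplotype == 2
  rownames(variants) <- NULL

  # translocation truth: breakpoints well separated so 5 kb clustering
  # cannot merge distinct events even after 2 kb jitter
  trans <- NULL
  if (params$n_translocations > 0) {
    if (length(cl) < 2)
      stop_fmt("translocations need at least two chromosomes")
    repeat {
      pair <- t(replicate(params$n_translocations,
                          sort(sample(seq_along(cl), 2))))
      pos_a <- floor(stats::runif(params$n_translocations, 1e5,
                                  cl[pair[, 1]] - 1e5))
      pos_b <- floor(stats::runif(params$n_translocations, 1e5,
                                  cl[pair[, 2]] - 1e5))
      sep_ok <- TRUE
      pts <- rbind(data.frame(chr = pair[, 1], pos = pos_a),
                   data.frame(chr = pair[, 2], pos = pos_b))
      for (chr in unique(pts$chr)) {
        p <- sort(pts$pos[pts$chr == chr])
        if (length(p) > 1 && min(diff(p)) < 2e4) sep_ok <- FALSE
      }
      if (sep_ok) break
    }
    trans <- data.frame(
      event_id = seq_len(params$n_translocations),
      chrom_a = names(cl)[pair[, 1]], pos_a = pos_a,
      chrom_b = names(cl)[pair[, 2]], pos_b = pos_b,
      orientation = sample(c("ff", "fr", "rf", "rr"),
                           params$n_translocations, replace = TRUE),
      stringsAsFactors = FALSE)
  } else {
    trans <- data.frame(event_id = integer(), chrom_a = character(),
                        pos_a = numeric(), chrom_b = character(),
                        pos_b = numeric(), orientation = character())
  }

  chrom_info <- data.frame(name = names(cl), length_bp = as.numeric(cl),
                           variant_count = as.integer(table(
                             factor(variants$chrom, levels = names(cl)))),
                           centromere_mbp = as.numeric(cl) * 0.45 / 1e6,
                           stringsAsFactors = FALSE)

  structure(list(params = params, chrom_info = chrom_info,
                 segments = segments, loh_intervals = loh_intervals,
                 variants = variants, translocations = trans,
                 realized_loh_fraction = realized),
            class = "genome_model")
}

#' Simulate per-library variant call tables
#'
#' For every library and every surviving model variant, draws a total read
#' depth Poisson around `depth * local_copy / ploidy` and allele depths
#' binomially from the local allele copy fractions; the called zygosity is
#' the model truth, with a small fraction of records left half-called.
#'
#' @param model A [make_genome_model()] result.
#' @param libraries Library names (default from the model's params).
#' @return Variant table (see [read_variant_table()]) with one record per
#'   variant and library; zero-depth sites keep depth 0 and are excluded
#'   downstream.
#' @export
simulate_variant_reads <- function(model,
                                   libraries = model$params$libraries) {
  params <- model$params
  set.seed(params$seed + 1L)
  v <- model$variants
  cp <- copies_at(model, v$chrom, v$pos)
  total_copy <- cp$hap1 + cp$hap2
  alt_copy <- cp$hap1 * v$alt_on_hap1 + cp$hap2 * v$alt_on_hap2
  out <- lapply(libraries, function(lib) {
    depth <- stats::rpois(nrow(v), params$depth * total_copy / params$ploidy)
    alt <- stats::rbinom(nrow(v), depth, ifelse(total_copy > 0,
                                                alt_copy / total_copy, 0))
    zyg <- v$zygosity
    half <- stats::runif(nrow(v)) < params$half_called_rate
    zyg[half] <- "half-called"
    data.frame(chrom = v$chrom, pos = v$pos,
               ref = "A", alt = "G",
               zygosity = zyg,
               ref_depth = depth - alt, alt_depth = alt,
               library = lib, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate per-library translocation call tables
#'
#' Every true event appears in every library with probability
#' `1 - dropout`; reported breakpoint windows are jittered independently
#' per library (uniform, up to `breakpoint_jitter_bp`) with widths drawn
#' from `call_window_bp`.  Library-specific false events are added at the
#' stated per-library count, placed far from true breakpoints.
#'
#' @param model A [make_genome_model()] result.
#' @return Call table in [read_translocation_table()] layout (already
#'   canonical), with a `true_event` passthrough column (`NA` for false
#'   calls).
#' @export
simulate_translocation_calls <- function(model) {
  params <- model$params
  set.seed(params$seed + 2L)
  tr <- model$translocations
  cl <- params$chrom_lengths
  jitter_window <- function(chrom, pos) {
    j <- floor(stats::runif(length(pos), -params$breakpoint_jitter_bp,
                            params$breakpoint_jitter_bp + 1))
    w <- floor(stats::runif(length(pos), params$call_window_bp[1],
                            params$call_window_bp[2] + 1))
    center <- pmax(1 + w, pmin(pos + j, cl[chrom] - w))
    data.frame(start = center - floor(w / 2), end = center + ceiling(w / 2))
  }
  rows <- list()
  for (lib in params$libraries) {
    keep <- stats::runif(nrow(tr)) >= params$dropout
    t2 <- tr[keep, , drop = FALSE]
    if (nrow(t2)) {
      wa <- jitter_window(t2$chrom_a, t2$pos_a)
      wb <- jitter_window(t2$chrom_b, t2$pos_b)
      rows <- c(rows, list(data.frame(
        chrom_a = t2$chrom_a, start_a = wa$start, end_a = wa$end,
        chrom_b = t2$chrom_b, start_b = wb$start, end_b = wb$end,
        orientation = t2$orientation, library = lib, coarse = FALSE,
        true_event = t2$event_id, stringsAsFactors = FALSE)))
    }
    n_false <- params$false_calls_per_library
    if (n_false > 0) {
      pair <- t(replicate(n_false, sort(sample(seq_along(cl), 2)),
                          simplify = TRUE))
      if (n_false == 1) pair <- matrix(pair, ncol = 2)
      pa <- floor(stats::runif(n_false, 1e5, cl[pair[, 1]] - 1e5))
      pb <- floor(stats::runif(n_false, 1e5, cl[pair[, 2]] - 1e5))
      # stay >10 kb clear of true breakpoints so false calls never cluster
      # onto true events
      clear <- function(chr, p) {
        all(abs(p - c(tr$pos_a[tr$chrom_a == chr],
                      tr$pos_b[tr$chrom_b == chr])) > 1e4)
      }
      ok <- vapply(seq_len(n_false), function(i)
        clear(names(cl)[pair[i, 1]], pa[i]) &&
          clear(names(cl)[pair[i, 2]], pb[i]), TRUE)
      pair <- pair[ok, , drop = FALSE]; pa <- pa[ok]; pb <- pb[ok]
      if (nrow(pair)) {
        wa <- jitter_window(names(cl)[pair[, 1]], pa)
        wb <- jitter_window(names(cl)[pair[, 2]], pb)
        rows <- c(rows, list(data.frame(
          chrom_a = names(cl)[pair[, 1]], start_a = wa$start, end_a = wa$end,
          chrom_b = names(cl)[pair[, 2]], start_b = wb$start, end_b = wb$end,
          orientation = sample(c("ff", "fr", "rf", "rr"), nrow(pair),
                               replace = TRUE),
          library = lib, coarse = FALSE, true_event = NA_integer_,
          stringsAsFactors = FALSE)))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom_a = character(), start_a = numeric(),
                      end_a = numeric(), chrom_b = character(),
                      start_b = numeric(), end_b = numeric(),
                      orientation = character(), library = character(),
                      coarse = logical(), true_event = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate read start positions
#'
#' Read density proportional to local total copy number; used to exercise
#' the coverage-binning profile against planted copy numbers.
#'
#' @param model A [make_genome_model()] result.
#' @param n_reads Total reads to draw (default 1e6, which puts roughly a
#'   thousand reads in every 100 kb bin of the default toy genome — ample
#'   for percent-level copy estimates).
#' @return Data.frame `chrom, pos`.
#' @export
simulate_read_positions <- function(model, n_reads = 1e6) {
  params <- model$params
  set.seed(params$seed + 4L)
  seg <- model$segments
  weight <- (seg$end - seg$start + 1) * (seg$hap1 + seg$hap2) / params$ploidy
  pick <- sample.int(nrow(seg), n_reads, replace = TRUE, prob = weight)
  pos <- floor(stats::runif(n_reads, seg$start[pick], seg$end[pick] + 1))
  data.frame(chrom = seg$chrom[pick], pos = pos, stringsAsFactors = FALSE)
}

#' Simulate LFR well observations
#'
#' Samples ~40 kb fragments (per parental haplotype, proportional to local
#' copy number), scatters them across the 384-well plate, and derives each
#' variant's per-well allele observations from the overlapping fragments.
#' Polymerase errors are injected as novel single-well alt calls at loci
#' without a true variant.
#'
#' @param model A [make_genome_model()] result.
#' @param max_loci Optionally subsample this many true variant loci (keeps
#'   test fixtures small); `NULL` uses all.
#' @return List with `observations` (data.frame `locus_id, chrom, pos,
#'   well, allele`), `loci` (per-locus truth: `locus_id, chrom, pos, truth,
#'   zygosity`), and `fragments`.
#' @export
simulate_lfr_wells <- function(model, max_loci = NULL) {
  params <- model$params
  set.seed(params$seed + 3L)
  cl <- params$chrom_lengths
  n_frag <- params$n_wells * params$fragments_per_well

  chr_idx <- sample.int(length(cl), n_frag, replace = TRUE, prob = cl)
  start <- floor(stats::runif(n_frag, 1, cl[chr_idx]))
  len <- pmax(1000, round(stats::rexp(n_frag, 1 / params$fragment_length_bp)))
  end <- pmin(start + len - 1, cl[chr_idx])
  cp <- copies_at(model, names(cl)[chr_idx], start)
  tot <- cp$hap1 + cp$hap2
  hap <- ifelse(stats::runif(n_frag) * ifelse(tot > 0, tot, 1) < cp$hap1, 1L, 2L)
  frag <- data.frame(chrom = names(cl)[chr_idx], start = start, end = end,
                     hap = hap,
                     well = sample.int(params$n_wells, n_frag, replace = TRUE),
                     stringsAsFactors = FALSE)
  frag <- frag[tot > 0, , drop = FALSE]  # no template in homozygously lost DNA

  v <- model$variants
  if (!is.null(max_loci) && nrow(v) > max_loci) {
    v <- v[sort(sample.int(nrow(v), max_loci)), , drop = FALSE]
  }
  v$locus_id <- paste0(v$chrom, ":", v$pos)
  n_err <- round(params$polymerase_error_rate * nrow(v))
  err <- NULL
  if (n_err > 0) {
    err_chr <- sample(names(cl), n_err, replace = TRUE, prob = cl)
    err_pos <- floor(stats::runif(n_err, 1, cl[err_chr]))
    err <- data.frame(chrom = err_chr, pos = err_pos,
                      well = sample.int(params$n_wells, n_err, replace = TRUE),
                      stringsAsFactors = FALSE)
    err$locus_id <- paste0(err$chrom, ":", err$pos)
    err <- err[!(err$locus_id %in% v$locus_id), , drop = FALSE]
  }

  obs_for <- function(pts, alt_fun) {
    # pts: data.frame chrom,pos,locus_id; alt_fun(rows of pts, frag rows)
    out <- lapply(unique(pts$chrom), function(chr) {
      p <- pts[pts$chrom == chr, , drop = FALSE]
      f <- frag[frag$chrom == chr, , drop = FALSE]
      if (!nrow(p) || !nrow(f)) return(NULL)
      hits <- IRanges::findOverlaps(IRanges::IRanges(p$pos, p$pos),
                                    IRanges::IRanges(f$start, f$end))
      pi <- S4Vectors::queryHits(hits)
      fi <- S4Vectors::subjectHits(hits)
      data.frame(locus_id = p$locus_id[pi], chrom = chr, pos = p$pos[pi],
                 well = f$well[fi],
                 allele = alt_fun(p[pi, , drop = FALSE],
                                  f[fi, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  true_obs <- obs_for(v, function(p, f)
    ifelse((f$hap == 1 & p$alt_on_hap1) | (f$hap == 2 & p$alt_on_hap2),
           "alt", "ref"))
  err_ref <- if (!is.null(err) && nrow(err))
    obs_for(err, function(p, f) rep("ref", nrow(p))) else NULL
  err_alt <- if (!is.null(err) && nrow(err))
    data.frame(locus_id = err$locus_id, chrom = err$chrom, pos = err$pos,
               well = err$well, allele = "alt", stringsAsFactors = FALSE)
  else NULL
  obs <- unique(rbind(true_obs, err_ref, err_alt))
  rownames(obs) <- NULL

  loci <- rbind(
    data.frame(locus_id = v$locus_id, chrom = v$chrom, pos = v$pos,
               truth = "variant", zygosity = v$zygosity,
               stringsAsFactors = FALSE),
    if (!is.null(err) && nrow(err))
      data.frame(locus_id = err$locus_id, chrom = err$chrom, pos = err$pos,
                 truth = "polymerase_error", zygosity = "het",
                 stringsAsFactors = FALSE))
  list(observations = obs, loci = loci, fragments = frag)
}

#' Assign phasing-contig IDs from truth
#'
#' Gives every heterozygous variant a `"Phased_a_b_h"` hapLink derived
#' from its true parental haplotype: contigs are (chromosome, 2 Mb block)
#' units and the parental-to-0/1 mapping is randomized per contig (phase
#' within a contig is arbitrary).  The parental truth is retained in
#' `true_haplotype` for switch-error scoring.
#'
#' @param model A [make_genome_model()] result.
#' @param block_bp Contig block size (default 2 Mb).
#' @return The model's variant table with `haplink` and `true_haplotype`
#'   columns (`haplink` empty for homozygous records).
#' @export
assign_haplinks <- function(model, block_bp = 2e6) {
  set.seed(model$params$seed + 5L)
  v <- model$variants
  chr_num <- match(v$chrom, model$chrom_info$name)
  block <- ((v$pos - 1) %/% block_bp) + 1
  contig_key <- paste(chr_num, block)
  flip <- stats::setNames(sample(0:1, length(unique(contig_key)),
                                 replace = TRUE), unique(contig_key))
  het <- v$zygosity == "het" & !is.na(v$haplotype)
  h <- ifelse(het, (v$haplotype - 1L + flip[contig_key]) %% 2L, NA)
  v$haplink <- ifelse(het, paste0("Phased_", chr_num, "_", block, "_", h), "")
  v$true_haplotype <- ifelse(het, v$haplotype, NA)
  v
}

#' Write a complete fixture set
#'
#' Emits every table dialect the pipeline reads — chromosome table,
#' per-library variant TSV and VCFs, translocation calls, LOH truth BED,
#' copy-number segments, LFR well observations — plus a JSON manifest
#' (seed, parameters, planted truth summary).  Regenerating with the
#' manifest's seed reproduces the tables byte-identically.
#'
#' @param model A [make_genome_model()] result.
#' @param dir Output directory; an existing non-empty directory is refused
#'   unless `force = TRUE`.
#' @param include_lfr Also write the (large) LFR well-observation table.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_set <- function(model, dir, include_lfr = TRUE,
                              force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop_fmt("directory %s exists and is not empty (use force = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- model$params

  ci <- model$chrom_info
  utils::write.table(ci, file.path(dir, "chromosomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  variants <- simulate_variant_reads(model)
  write_variant_table(variants, file.path(dir, "variants.tsv"), "tsv")
  for (lib in params$libraries) {
    write_variant_table(variants[variants$library == lib, , drop = FALSE],
                        file.path(dir, paste0("variants_", lib, ".vcf")),
                        "vcf")
  }
  calls <- simulate_translocation_calls(model)
  write_translocation_table(calls, file.path(dir, "translocations.tsv"))
  write_segments_bed(model$loh_intervals, file.path(dir, "loh_truth.bed"))
  utils::write.table(model$segments, file.path(dir, "cn_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (include_lfr) {
    wells <- simulate_lfr_wells(model)
    utils::write.table(wells$observations,
                       file.path(dir, "well_observations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(wells$loci, file.path(dir, "well_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = params$seed,
    params = params[setdiff(names(params), "chrom_lengths")],
    chrom_lengths = as.list(params$chrom_lengths),
    realized_loh_fraction = model$realized_loh_fraction,
    n_variants = nrow(model$variants),
    n_translocations = nrow(model$translocations),
    translocations = model$translocations,
    loh_intervals = model$loh_intervals,
    files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
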