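---
title: "Methods: characterizing an aneuploid cancer genome from multi-library calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an aneuploid cancer genome from multi-library calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneukit)
```

# Scope

aneukit re-implements, as reusable and tested functions, the downstream
characterization of a highly aneuploid breast-cancer cell-line genome
(BT-474, near-tetraploid) sequenced with three libraries: one standard
short mate-pair library (STD) and two Long Fragment Read libraries (LFR1,
LFR2) in which ~40 kb genomic fragments are partitioned across a 384-well
plate before amplification, so every read is attributable to a physical
compartment.  The package covers breakpoint clustering of interchromosomal
translocation calls, loss-of-heterozygosity (LOH) quantification from
lesser-allele fractions, a diploid het/hom-ratio LOH simulation,
ploidy-normalized coverage profiles, multi-library variant concordance,
gene-fusion support checks, and the LFR well-count error filter.  Upstream
base calling, mapping, assembly and small-variant calling are out of
scope: the package consumes *call-level* tables, and a synthetic generator
with planted truth stands in for the raw sequencing data.

# Translocation clustering

A raw call is a pair of breakpoint windows on two different chromosomes
with a two-letter orientation code (`f`/`r` per side, relative to the
reference).  Calls are first canonicalized so the chromosome pair follows
the fixed order 1..22, X, Y; swapping sides exchanges the two orientation
letters without complementing them — each letter is defined per side
against the reference, and side order carries no strand information.

Clustering is single linkage: two calls are directly linked iff they share
the canonical chromosome pair and the orientation, and on *both* sides the
gap between their breakpoint windows is at most the clustering window
(default 5 kb; overlapping windows have gap zero).  Events are the
transitive closure, which makes within-library aggregation and
between-library matching a single rule.  Cluster IDs are deterministic
(chromosome pair, then minimal side-A start).

Two design points were genuinely open and were settled as follows:

* *Gap vs midpoint.* "Within 5 kb" is read as an interval-gap bound, not a
  midpoint-distance bound.  On the full-precision rows of the packaged
  published call table the resulting partition reproduces the published
  event grouping exactly, which is the only available arbiter; a midpoint
  rule reproduces it as well on that subset, so the choice is not
  empirically distinguishable there and the gap rule was kept as the more
  conventional interval semantics.
* *Orientation under side swap.* Letters are exchanged, never
  complemented; no published rule forces complementation, and the
  reproduced grouping confirms the choice.

## Printed-precision coordinates

The packaged published call table passed through a spreadsheet at some
point in its life: 108 of its 430 rows carry coordinates in scientific
notation, i.e. rounded to roughly 1 Mb.  The reader parses these to
integers but flags the rows `coarse`, because a 1 Mb quantization is three
orders of magnitude coarser than the 5 kb linkage window.  One consequence
is irreversible: two published events on the same chromosome pair and
orientation whose A-side windows are 2.2 kb apart print identical rounded
B-side coordinates, so any clustering of the printed values merges them
and the algorithmic event total on the printed table is 290 rather than
the published 291.  Precision-sensitive analyses should restrict to
`!coarse` rows, where the published grouping is reproduced exactly.

# LOH from lesser-allele fractions

At a fully called variant site with allele depths $(d_{ref}, d_{alt})$ the
lesser-allele fraction is
$\mathrm{LAF} = \min(d_{ref}, d_{alt}) / (d_{ref}+d_{alt}) \in [0, 0.5]$:
0.5 for a balanced heterozygote, 0 for a homozygote.  Windows of 100 kb
(anchored at position 1, final partial window kept) summarize member sites
by the *median* LAF — robust to a few mis-mapped sites; half-called
records and zero-depth sites are excluded, and a window without usable
sites is missing rather than zero.

LOH segments are maximal runs of windows with LAF at or below `epsilon`
(default exactly 0; real depth noise may warrant ~0.02) whose genomic
extent strictly exceeds 10 Mb.  Up to `max_gap_windows` (default 5, i.e.
0.5 Mb) consecutive missing windows are tolerated inside a run so that
centromeric variant deserts do not split whole-arm LOH; segment bounds
snap to window bounds and are trimmed to informative windows.  LOH content
is then expressed per chromosome and genome-wide both in base pairs and in
known-variant terms; with no positional variant catalog, a partial-LOH
chromosome scales its known-variant count by the LOH length fraction
(uniform-density assumption), while full-chromosome LOH uses the whole
count.

The het/hom ratio — heterozygous over homozygous SNV counts, ~1.6 in a
typical European-ancestry diploid genome — is the package's summary
statistic for genome-wide LOH pressure; two-decimal figures use
round-half-away-from-zero, matching how the published tables were rounded.

# The diploid LOH thought experiment

`simulate_loh_expected()` answers: if a fraction $f$ of a diploid genome
went through LOH, what happens to its het/hom counts?  Heterozygous
variants in the affected fraction are observed as homozygous (the
surviving allele is still called against the reference), so
$\mathrm{round}(f \cdot n_{het})$ variants transfer from the het to the
hom column and the total is conserved.  `simulate_loh_regions()` is its
stochastic counterpart: contiguous regions (exponential lengths, default
mean 30 Mb — the scale of observed LOH blocks — truncated to chromosome
arms) are drawn without replacement until the target fraction is covered,
and the transfer is counted exactly for the drawn regions.  With uniformly
placed variants the two modes agree in expectation; the test suite checks
this over 200 seeds at three standard errors, drawing a fresh variant
realization per seed (with a fixed realization, the arm-end bias of
truncated draws couples all seeds to the same spatial fluctuation of het
density and the seed-mean is no longer an unbiased estimate).

# Coverage profiles

Read positions are counted in 100 kb windows and scaled so that the
*median* nonzero autosomal bin equals the target ploidy (4 for this
near-tetraploid genome).  The median was chosen over the mean because
megabase amplifications give the count distribution a heavy right tail;
whether the original analysis used mean, median or mode is not stated
anywhere, and the median is the most defensible default.  Sex chromosomes
are excluded from the baseline.  No GC correction is applied (none is
described for the original profile); the configuration object keeps a slot
for one.

# LFR well statistics and error filtering

For every variant locus the package recomputes, from per-well allele
observations: `well_count` (wells with reads calling variant or
reference), `exclusive_well_count` (wells calling exactly one allele),
`shared_well_count` (wells calling both), the variant-bearing well IDs,
and the per-allele exclusive extremes.  The identity
`well_count = exclusive + shared` holds by construction and is re-checked
on every computed annotation.

The error filter rests on the physics of the plate: a random polymerase
error is amplified within a single well, while a true variant is sampled
into many.  A variant seen in fewer than `min_variant_wells` wells
(default 2 — the principle is published, the threshold is not; 2 is the
weakest setting that implements it) is a polymerase-error suspect.  A
heterozygote whose shared-well fraction exceeds 0.5 (again a stated
principle, "high", without a published number) is a mapping-error
suspect, since wells should rarely contain both alleles of a true het.
The published remark that homozygous variants concentrate their wells in
the shared field is treated as descriptive and is not enforced.

Phasing bookkeeping follows the `Phased_a_b_h` ID convention: `a`,`b`
identify a phasing contig, `h` (0/1) the haplotype within it; all records
sharing an ID must derive from one parental haplotype, which the package
verifies against synthetic truth (switch errors = members discordant with
their group majority).  Reconstructing contigs from raw observations is
out of scope.

# The synthetic world

`make_genome_model()` generates the stated world the tests run in: three
30 Mb toy chromosomes at baseline ploidy 4 (two copies per parental
haplotype); six megabase-scale copy-number segments (exponential lengths,
mean 3 Mb; totals drawn from {2,3,5,6,8}, split so both haplotypes keep at
least one copy); LOH intervals targeting 22% of the genome (exponential,
mean 15 Mb, every interval above 12 Mb so planted LOH stays above the
>10 Mb detectability floor — the published LOH blocks are themselves tens
of Mb); variants at one per 1.5 kb with a het/hom ratio of 1.6 outside
LOH; read depth 100 at baseline ploidy with Poisson totals and binomial
allele splits from local copy fractions; three libraries; 25 planted
translocations with per-library dropout 0.1, uniform breakpoint jitter up
to 2 kb (below the 5 kb window by construction), reported window widths
100–1000 bp and 2 spurious calls per library; and an LFR layer of 384
wells, 300 fragments per well of exponential ~40 kb length, with
single-well polymerase errors injected at 1% of true loci.  Values stated
by the original analysis (ploidy, window sizes, plate size, fragment
length, ratio 1.6, LOH fraction ~22%) are used as-is; the remaining sizes
(toy chromosome scale, densities, fragment and error counts) were chosen
once to be realistic at desk scale — e.g. the fragment count gives true
het variants ~25–50 supporting wells, the regime the filter is designed
for — and keep the full suite under a minute of simulation time.

All randomness flows from one seed through fixed per-generator offsets
(`seed + k`, k ≤ 5), so any stage can be regenerated independently and
fixture sets are byte-reproducible from their manifest.

What a green synthetic test does *not* establish: the generator plants
biallelic SNVs with exact depths-from-copy-fractions and no sequencing
error, mapping bias, GC waves or segmental duplications; translocation
windows are symmetric and honest; LFR wells have no cross-contamination.
Recovery results on this world bound algorithmic correctness, not
performance on real libraries.

# Degenerate inputs and numerical conventions

Internal coordinates are 1-based inclusive everywhere; only BED output is
0-based half-open.  Chromosome names are normalized to `chr`-prefixed
form on input.  Zero-depth sites are "missing", never LAF 0.  A window
holding no fully called variant is missing, never zero.  Ratios with a
zero homozygous denominator are an error, not `Inf`.  Empty call tables,
empty cluster sets and empty panels either pass through as empty results
or raise explicit errors (empty panel recall), never silent zeros.
Two-decimal reporting uses round-half-away-from-zero throughout.

# Known limitations

* Copy-neutral LOH and hemizygous deletion are not distinguished; that
  would need joint modeling of LAF and coverage.
* The LOH variant scaling without a positional catalog assumes uniform
  variant density along the chromosome.
* Clustering of printed-precision (coarse) coordinates can merge events
  that full-precision data keeps apart; see above.
* The concordance module compares variant identity only (site + alleles);
  genotype agreement across libraries is deliberately not required, since
  aneuploidy makes zygosity calls library-noise-sensitive.
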