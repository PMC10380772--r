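---
title: "Methods: the alternative-splicing census and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the alternative-splicing census and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceCensus)
library(data.table)
```

`spliceCensus` implements the downstream analysis of alternative splicing
(AS) across a cotton fiber developmental time course: PSI-based retention
filtering of rMATS-style event tables, a census of AS genes and events over
tissues, stages and the At/Dt subgenomes of allotetraploid cotton,
sequence-feature and splice-junction GC comparisons, TPM expression summaries
and term enrichment, and context-resolved DNA-methylation profiles of AS
versus constitutively spliced genes. This vignette records the models,
parameter choices and numerical conventions, and what the synthetic testbed
does and does not establish.

## PSI and the retention filter

rMATS reports, per event and sample, inclusion and skipping junction counts
(IJC, SJC) and the effective lengths of the two isoform forms. PSI is the
form-length-normalized inclusion fraction

$$\psi = \frac{I/l_I}{I/l_I + S/l_S}.$$

Counts from replicate columns are summed before PSI, not averaged: junction
counts are Poisson-like and additive, and summing preserves the estimator's
precision at low depth. The unnormalized ratio $I/(I+S)$ is available via
`filter_config(normalized = FALSE)` for tables without meaningful form
lengths.

Retention uses three thresholds, applied per sample: $0.1 < \psi < 0.9$ with
*strict* inequalities, and $SJC \ge 5$ *non-strict* — exactly the published
convention, with the boundary behaviour unit-tested. PSI is missing when a
sample has zero junction reads for the event; missing-PSI rows are dropped,
never imputed, because zero coverage carries no evidence about isoform
proportions. The filter is monotone in its thresholds (tightening `min_sjc`
never adds events; widening the PSI interval never removes any), which the
property suite checks on randomized inputs.

## Census conventions

Two readings of "AS gene" coexist deliberately. Dataset-level totals treat a
gene as alternatively spliced if it has at least one retained event in at
least one sample; per-sample tables count retention sample by sample. Both
readings are needed to reproduce the two kinds of summary a census report
contains, so `build_census()` carries both and labels them explicitly.

Event identity across samples is the tuple (event type, chromosome, strand,
full anchor coordinates). rMATS coordinates are stable across runs on the
same annotation, so this key is reliable; it also survives a write/read
round trip of the tables.

Period groups are tissue × stage with stages defined on the DPA axis:
stage 1 (initiation/primary elongation) −3..5, stage 2 (elongation) 10..15,
stage 3 (secondary wall thickening) 20..25. There are five groups, not six:
fibers are only sampled from 10 DPA on, so a fiber stage 1 does not exist,
and the design reader rejects fiber samples before 10 DPA outright.
Conservative = member of every group; specific = member of exactly one; the
full intersection-degree table (upset counts) is emitted, and the suite
checks that the cells always sum to the union.

The subgenome comparison labels genes At/Dt by chromosome prefix and runs a
two-sided Student's t-test on per-sample counts. The pairing of At against Dt
within each sample is a design choice — the natural pairing given that both
subgenomes are measured in the same library — with an unpaired switch
(`paired = FALSE`) since the convention is not dictated by the data.

## Homology

Reciprocal best hit ranks hits by bitscore (length-corrected, hence
preferred over percent identity), breaking ties by smaller e-value and then
lexicographic subject id so the output is fully deterministic. Strict 1:1
RBH drives the homoeolog-pair universe; a `one_to_many` mode relaxes
reciprocity on the query side (the target's best hit must be the query, the
query need only hit the target) for homolog-family expansion, where one
query legitimately collects several paralogous targets. No similarity
cut-off is imposed beyond reciprocity; callers can pre-filter the hit tables
if they want one.

## Junction windows

A splice site is stored as the 0-based coordinate of the intronic base
adjacent to the exon/intron boundary plus the genomic side the intron lies
on; donor/acceptor labels are strand-aware (donor = exon then intron in
transcript order). SE events contribute their skipped exon's two boundaries
(acceptor A at the transcript-upstream edge, donor B downstream); RI events
contribute the retained intron's donor C and acceptor D; normal multi-exon
genes contribute every internal boundary as the comparison population.

The full window is 51 bp: the boundary base ± 25 bp. Within each 25 bp
flank, a 20 bp sub-window is analysed; its placement inside the flank is not
dictated by the underlying convention, so the windows *abut the junction* —
the mechanistically relevant choice, since splice-site recognition acts on
the sequence immediately at the boundary — and the width is configurable.
Sites closer than 25 bp to a contig end are excluded and counted. Group
comparisons match donor to donor and acceptor to acceptor, with pooled
("Student's") t-tests by default and Welch by flag; pooled matches the
convention of the figure legends this analysis style descends from.

Gene-level GC uses the genomic span (introns included), case-insensitive,
with N bases excluded from the denominator: the SE/RI/normal comparison
concerns gene bodies as annotated in the GTF, not spliced transcripts. A
gene hosting both SE and RI events is a member of both AS groups.

## Expression and enrichment

TPM uses merged-exon effective lengths (standard TPM semantics, not the
genomic span) and every column sums to $10^6$ by construction. The
splicing-factor panel is row-z-scored over design-ordered samples; fold
changes between sample groups are descriptive — group-mean TPM with a
pseudocount of 1, flagged at $|\log_2 FC| \ge 1$ — because proper
differential testing belongs to a count-model package and is out of scope
here. Enrichment is the exact upper-tail hypergeometric test per term with
Benjamini–Hochberg adjustment across tested terms; terms without background
genes are skipped. The test suite checks the p-values against brute-force
tail enumeration.

## Methylation profiles

Levels are read-weighted: $\sum n_{meth} / \sum n_{total}$ over the covered
cytosines of a context in a region, not the mean of per-site levels —
robust to coverage variation, which per-site averaging is not. The pooled
"m5C" level runs over all three contexts and always lies between the
per-context extremes. Symmetric CpG sites are counted on both strands
independently, matching per-cytosine caller output.

Gene bodies and 2 kb flanks are profiled with fractional sliding windows:
width $0.02L$, step $0.01L$. Window boundaries are computed in real
arithmetic and rounded half-up per window (base R's banker's rounding would
make boundaries depend on parity), which guarantees *exactly* 99 windows per
segment for every gene of length ≥ 50 bp — shorter genes would have
sub-basepair windows and are excluded with a count. Junction neighborhoods
(±50 bp, 101 bp total) use fixed 10 bp windows stepping 5 bp: 19 windows.
Profiles are strand-oriented so "upstream" is always the biological 5′ end.

Group profiles average per-gene window levels, ignoring missing windows;
pooling raw counts across genes is available by flag
(`profile_config(pool_genes = TRUE)`). Per-gene averaging weights every gene
equally regardless of its coverage, which is what a metagene figure is
usually taken to show; pooling would let deeply covered genes dominate.

## The synthetic testbed

The generator emulates the statistical structure the analysis assumes, at
the study's design: 13 samples (ovules at −3, 0, 1, 3, 5, 10, 15, 20, 25
DPA; fibers at 10, 15, 20, 25 DPA) and, by default, 500 genes — 300
never-spliced, 100 SE-hosting, 100 RI-hosting. Group targets follow the
reported normal/AS contrasts: mean length ≈ 1868 bp (normal) vs ≈ 4450 bp
(AS) from log-normals; shifted-Poisson exon counts with means ≈ 3.3 vs
9.4–10.0 (SE genes forced to ≥ 3 exons so a skippable internal exon exists,
RI to ≥ 2); per-gene GC ≈ 0.40 vs 0.36. Junction deltas of 0.08 are written
into the sequence itself (SE exon-side lowered, RI intron-side raised) —
large enough to be detected at ~200 planted sites against ~800 constitutive
ones, small enough not to distort gene-level GC appreciably. Six contigs
(three At, three Dt) are sized to fit the realized genes plus margins; AS
genes are placed on At contigs with probability 0.55, planting the reported
subgenome asymmetry.

Events draw a Beta(2, 2) true PSI with binomial junction reads at mean
depth 50 after form-length adjustment (inclusion form length 2, skipping 1 —
simplified constants recorded in the truth table). Thirty percent of events
are planted conservative (counts redrawn until retained in every sample),
thirty percent group-specific (zero coverage outside their group), and the
rest are free-running, with a tenth of those forced outside the retention
interval so the filter is genuinely exercised. The methylome assigns every
cytosine of the generated sequence a context read from the sequence itself
and a region-specific rate — gene-body CpG 0.7 (AS) vs 0.4 (normal) with
CHG/CHH equal across groups, and junction ±50 bp overrides of CHH 0.02 and
CHG 0.10 in AS genes — then draws Poisson(20) coverage and binomial
methylated counts.

What passing tests show — and what they do not. The planted-effect suite
demonstrates that the pipeline *recovers known structure*: filter decisions
equal the predicate, set algebra recovers the planted conservative/specific
events exactly, group contrasts come out in the planted directions at
p < 0.01, RBH recovers the planted orthologs completely. It does not show
that real cotton data would yield the published magnitudes: the generator
has no transposon/centromere structure (chromosomal hotspot patterns are not
emulated), one event per AS gene (so hotspot and multiplicity statistics are
degenerate by construction), independent genes (no linkage or shared
regulation), and clean rMATS tables (no annotation errors or multi-mapping
artifacts). Test problem sizes are the package's defaults: 500 genes for
planted-effect recovery, 10,000 random pairs for the filter oracle, depth
1,000 for PSI consistency, 100 pairs plus decoys for RBH.

## Degenerate inputs and tie-breaks

Empty retained sets build an (empty) census with a warning; single-member
groups skip their t-test with a warning; identical groups report t = 0,
p = 1 rather than erroring on zero variance. Zero-coverage methylation
windows are missing, not zero, and drop out of group means. Junction sites
too close to contig ends are excluded and counted in the output's
`n_excluded` attribute and the pipeline manifest. All orderings that affect
output files (RBH tie-breaks, table sort orders) are deterministic, so rerun
manifests are byte-identical.
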