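# Event/gene census and all counting statistics derived from it:
# per-sample tables, hotspots, event-type breakdowns, chromosome distribution,
# At/Dt subgenome comparison and the stage/tissue set algebra.
#
# Two readings of "AS gene" coexist deliberately: dataset-level totals use the
# union over samples (a gene is an AS gene if it has >= 1 retained event in
# >= 1 sample), while per-sample tables count retention sample by sample.
# Both kinds of summary are needed to reproduce census-style reports.

#' Build the AS census from retained events
#'
#' @param retained retained long events table (output of [filter_events()]).
#' @param design design table from [read_design()].
#' @return an object of class `as_census`: a list with
#'   `events` (distinct events: `event_key`, `gene_id`, `event_type`, `chrom`,
#'   `strand`, `junc_start`, `junc_end`, `n_samples`),
#'   `genes` (per gene: `n_events` distinct retained events, `n_types`
#'   distinct event types, `chrom`),
#'   `per_sample_genes` (sample x event type distinct-gene counts plus the
#'   per-sample total of distinct AS genes, the classic census-table shape),
#'   `per_sample_events` (same for event records),
#'   `membership` (long (sample_id, event_key, gene_id, event_type) retention
#'   pairs driving all set algebra), `design`, and `totals`.
#' @export
build_census <- function(retained, design) {
  ev <- as.data.table(retained)
  design <- as.data.table(design)
  if (nrow(ev) == 0L)
    warnf("census built from zero retained events")
  membership <- unique(ev[, .(sample_id, event_key, gene_id, event_type)])

  events <- ev[, .(gene_id = gene_id[1], event_type = event_type[1],
                   chrom = chrom[1], strand = strand[1],
                   junc_start = junc_start[1], junc_end = junc_end[1],
                   n_samples = uniqueN(sample_id)),
               by = event_key]
  genes <- events[, .(n_events = .N, n_types = uniqueN(event_type),
                      chrom = chrom[1]), by = gene_id]

  per_sample_genes <- dcast(
    membership[, .(n = uniqueN(gene_id)), by = .(sample_id, event_type)],
    sample_id ~ event_type, value.var = "n", fill = 0L)
  tot_g <- membership[, .(total_genes = uniqueN(gene_id)), by = sample_id]
  per_sample_genes <- merge(per_sample_genes, tot_g, by = "sample_id",
                            all = TRUE)
  per_sample_events <- dcast(
    membership[, .(n = uniqueN(event_key)), by = .(sample_id, event_type)],
    sample_id ~ event_type, value.var = "n", fill = 0L)
  tot_e <- membership[, .(total_events = uniqueN(event_key)), by = sample_id]
  per_sample_events <- merge(per_sample_events, tot_e, by = "sample_id",
                             all = TRUE)

  totals <- list(
    n_as_genes = nrow(genes),
    n_as_events = nrow(events),
    events_per_gene = events_per_gene(nrow(events), nrow(genes))
  )
  structure(list(events = events, genes = genes,
                 per_sample_genes = per_sample_genes,
                 per_sample_events = per_sample_events,
                 membership = membership, design = design, totals = totals),
            class = "as_census")
}

#' @export
print.as_census <- function(x, ...) {
  cat(sprintf("AS census: %d AS genes, %d AS events (%.2f events/gene) over %d samples\n",
              x$totals$n_as_genes, x$totals$n_as_events,
              x$totals$events_per_gene, nrow(x$design)))
  invisible(x)
}

#' Census summary arithmetic
#'
#' The scalar summary formulas used throughout the census reports, exposed so
#' they can be applied to any pair of totals: mean distinct events per AS
#' gene, a share expressed as a percentage, and the max/min ratio of a range.
#'
#' @param n_events,n_genes totals of distinct AS events and AS genes.
#' @return `events_per_gene()`: `n_events / n_genes`.
#' @export
events_per_gene <- function(n_events, n_genes) {
  if (n_genes == 0) return(NA_real_)
  n_events / n_genes
}

#' @rdname events_per_gene
#' @param k,n numerator and denominator counts.
#' @return `percent_of()`: `100 * k / n`.
#' @export
percent_of <- function(k, n) 100 * k / n

#' @rdname events_per_gene
#' @param hi,lo extremes of a per-sample range.
#' @return `range_ratio()`: `hi / lo`.
#' @export
range_ratio <- function(hi, lo) hi / lo

#' Splicing hotspot genes
#'
#' Hotspots are genes producing strictly more than `min_events` distinct
#' retained events across the dataset (default: more than four).
#'
#' @param census an `as_census`.
#' @param min_events strict lower bound on the distinct-event count.
#' @return `data.table` of hotspot genes with their event counts, ordered by
#'   decreasing `n_events`.
#' @export
hotspots <- function(census, min_events = 4L) {
  stopifnot(inherits(census, "as_census"))
  h <- census$genes[n_events > min_events]
  setorder(h, -n_events, gene_id)
  h[]
}

#' Per-sample event-type proportions
#'
#' For every sample, the share of each event type among its retained event
#' records, plus the across-sample min/max range per type and the ratio of
#' the range extremes (a measure of temporal/tissue variability of a type).
#'
#' @param census an `as_census`.
#' @return list with `per_sample` (sample_id, event_type, n, pct) and
#'   `ranges` (event_type, min_pct, max_pct, ratio = max/min).
#' @export
type_breakdown <- function(census) {
  stopifnot(inherits(census, "as_census"))
  m <- census$membership
  per_sample <- m[, .(n = uniqueN(event_key)), by = .(sample_id, event_type)]
  per_sample[, pct := percent_of(n, sum(n)), by = sample_id]
  ranges <- per_sample[, .(min_pct = min(pct), max_pct = max(pct)),
                       by = event_type]
  ranges[, ratio := range_ratio(max_pct, min_pct)]
  list(per_sample = per_sample[], ranges = ranges[])
}

#' Genes by number of distinct event types
#'
#' @param census an `as_census`.
#' @return `data.table` (`n_types` in 1..5, `n_genes`, `pct` of all AS genes).
#' @export
gene_type_multiplicity <- function(census) {
  stopifnot(inherits(census, "as_census"))
  tab <- census$genes[, .(n_genes = .N), by = .(n_types)]
  setorder(tab, n_types)
  tab[, pct := percent_of(n_genes, census$totals$n_as_genes)]
  tab[]
}

#' Chromosome distribution of AS genes and events
#'
#' Per-chromosome totals (with argmax/argmin chromosomes) and fixed-width
#' window tallies suitable for track export. A gene or event is assigned to
#' the window containing its start coordinate (gene 5'-most base, event
#' `junc_start`); windows are 0-based half-open.
#'
#' @param census an `as_census`.
#' @param gene_models gene models from [read_gtf()] (supplies gene positions
#'   and total gene density).
#' @param window_bp window width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum annotated gene end per chromosome.
#' @return list with `per_chrom` (chrom, n_as_genes, n_as_events, n_genes),
#'   `windows` (chrom, start, end, n_as_genes, n_as_events, n_genes),
#'   `argmax_chrom`, `argmin_chrom` (by AS gene count).
#' @export
chromosome_density <- function(census, gene_models, window_bp = 1e6,
                               chrom_lengths = NULL) {
  stopifnot(inherits(census, "as_census"), window_bp >= 1)
  gm <- as.data.table(gene_models)[, .(gene_id, chrom, start, end)]
  if (is.null(chrom_lengths)) {
    cl <- gm[, .(len = max(end)), by = chrom]
  } else {
    cl <- data.table(chrom = names(chrom_lengths),
                     len = as.numeric(chrom_lengths))
  }
  as_genes <- merge(census$genes[, .(gene_id)], gm, by = "gene_id")
  as_events <- census$events
  # event position: junc_start when present, else the host gene's start
  epos <- merge(as_events, gm[, .(gene_id, gstart = start)], by = "gene_id",
                all.x = TRUE)
  epos[, pos := ifelse(is.na(junc_start), gstart, junc_start)]

  per_chrom <- merge(
    merge(as_genes[, .(n_as_genes = .N), by = chrom],
          epos[, .(n_as_events = .N), by = chrom],
          by = "chrom", all = TRUE),
    gm[, .(n_genes = .N), by = chrom], by = "chrom", all = TRUE)
  for (col in c("n_as_genes", "n_as_events", "n_genes"))
    per_chrom[is.na(get(col)), (col) := 0L]

  windows <- rbindlist(lapply(seq_len(nrow(cl)), function(i) {
    starts <- seq(0L, max(0L, cl$len[i] - 1L), by = window_bp)
    data.table(chrom = cl$chrom[i], start = starts,
               end = pmin(starts + window_bp, cl$len[i]))
  }))
  bin_of <- function(pos0, chroms) {
    # pos0: 0-based coordinate
    paste0(chroms, ":", (pos0 %/% window_bp))
  }
  windows[, key_ := paste0(chrom, ":", start %/% window_bp)]
  gtab <- as_genes[, .N, by = .(key_ = bin_of(start - 1L, chrom))]
  etab <- epos[, .N, by = .(key_ = bin_of(pos, chrom))]
  dtab <- gm[, .N, by = .(key_ = bin_of(start - 1L, chrom))]
  windows[, n_as_genes := gtab[windows, on = "key_", x.N]]
  windows[, n_as_events := etab[windows, on = "key_", x.N]]
  windows[, n_genes := dtab[windows, on = "key_", x.N]]
  for (col in c("n_as_genes", "n_as_events", "n_genes"))
    windows[is.na(get(col)), (col) := 0L]
  windows[, key_ := NULL]

  list(per_chrom = per_chrom[],
       windows = windows[],
       argmax_chrom = per_chrom$chrom[which.max(per_chrom$n_as_genes)],
       argmin_chrom = per_chrom$chrom[which.min(per_chrom$n_as_genes)])
}

#' Label genes by subgenome from the chromosome name
#'
#' Chromosomes prefixed `chrA`/`A` belong to the At subgenome, `chrD`/`D` to
#' Dt; anything else is `NA`.
#'
#' @param chrom character vector of chromosome names.
#' @return factor-like character vector `"At"`, `"Dt"` or `NA`.
#' @export
subgenome_of <- function(chrom) {
  s <- rep(NA_character_, length(chrom))
  s[grepl("^(chr)?A", chrom)] <- "At"
  s[grepl("^(chr)?D", chrom)] <- "Dt"
  s
}

#' Compare alternative splicing between the At and Dt subgenomes
#'
#' Dataset-level totals (AS genes, AS events, mean events per AS gene) per
#' subgenome, shares relative to a homoeolog-pair universe when one is
#' supplied, and a two-sided Student's t-test of per-sample At vs Dt counts
#' (paired within sample by default).
#'
#' @param census an `as_census`.
#' @param pairs optional homoeolog pairs (`gene_a` = At, `gene_b` = Dt, as
#'   from [rbh()]); when given, the comparison is restricted to genes in the
#'   pair universe and percentages use the number of pairs as denominator.
#' @param paired pair At/Dt counts within sample (default) or run an
#'   unpaired test.
#' @return list with `totals` (per subgenome: n_as_genes, n_as_events,
#'   events_per_gene, pct_of_universe), `per_sample` (sample x subgenome
#'   gene/event counts), `t_genes`, `t_events` (htest objects).
#' @export
subgenome_compare <- function(census, pairs = NULL, paired = TRUE) {
  stopifnot(inherits(census, "as_census"))
  genes <- copy(census$genes)[, subgenome := subgenome_of(chrom)]
  events <- copy(census$events)[, subgenome := subgenome_of(chrom)]
  membership <- merge(census$membership,
                      unique(events[, .(event_key, subgenome)]),
                      by = "event_key")
  n_universe <- NA_integer_
  if (!is.null(pairs)) {
    universe <- unique(c(pairs$gene_a, pairs$gene_b))
    genes <- genes[gene_id %in% universe]
    events <- events[gene_id %in% universe]
    membership <- membership[gene_id %in% universe]
    n_universe <- nrow(pairs)
  }
  genes <- genes[!is.na(subgenome)]
  events <- events[!is.na(subgenome)]
  membership <- membership[!is.na(subgenome)]

  totals <- merge(genes[, .(n_as_genes = .N), by = subgenome],
                  events[, .(n_as_events = .N), by = subgenome],
                  by = "subgenome")
  totals[, events_per_gene := mapply(events_per_gene, n_as_events, n_as_genes)]
  totals[, pct_of_universe := if (is.na(n_universe)) NA_real_ else
    percent_of(n_as_genes, n_universe)]

  per_sample <- membership[, .(n_genes = uniqueN(gene_id),
                               n_events = uniqueN(event_key)),
                           by = .(sample_id, subgenome)]
  wide_g <- dcast(per_sample, sample_id ~ subgenome, value.var = "n_genes",
                  fill = 0L)
  wide_e <- dcast(per_sample, sample_id ~ subgenome, value.var = "n_events",
                  fill = 0L)
  run_t <- function(w) {
    if (!all(c("At", "Dt") %in% names(w)) || nrow(w) < 2) return(NULL)
    if (paired && all(w$At == w$Dt))
      return(structure(list(statistic = c(t = 0), p.value = 1,
                            method = "degenerate paired t (identical counts)"),
                       class = "htest"))
    stats::t.test(w$At, w$Dt, paired = paired, var.equal = !paired)
  }
  list(totals = totals[], per_sample = per_sample[],
       t_genes = run_t(wide_g), t_events = run_t(wide_e))
}

#' Stage/tissue set algebra: conservative and specific AS genes and events
#'
#' Samples are grouped into tissue-stage period groups (ovule stages 1-3,
#' fiber stages 2-3; fibers are not sampled before 10 DPA so a fiber stage 1
#' group does not exist). A gene or event is a member of a group when it is
#' retained in at least one sample of the group. Conservative = member of
#' every group; specific = member of exactly one. The full intersection
#' structure (upset counts over all non-empty group combinations) is
#' returned for genes and events separately.
#'
#' @param census an `as_census`.
#' @return list with, for `genes` and `events` each: `membership` (item x
#'   group long table), `conservative` (item vector), `specific` (item,
#'   group), `upset` (combo string of sorted group names, degree, n), and
#'   `n_union`.
#' @export
stage_sets <- function(census) {
  stopifnot(inherits(census, "as_census"))
  m <- merge(census$membership, census$design[, .(sample_id, group)],
             by = "sample_id")
  one <- function(item_col) {
    mem <- unique(m[, .(item = get(item_col), group)])
    combos <- mem[, .(combo = paste(sort(unique(group)), collapse = "+"),
                      degree = uniqueN(group)), by = item]
    n_groups <- uniqueN(mem$group)
    upset <- combos[, .(n = .N), by = .(combo, degree)]
    setorder(upset, -degree, combo)
    list(membership = mem[],
         conservative = combos[degree == n_groups, item],
         specific = merge(combos[degree == 1L, .(item)],
                          mem, by = "item")[, .(item, group)],
         upset = upset[],
         n_union = nrow(combos),
         n_groups = n_groups)
  }
  list(genes = one("gene_id"), events = one("event_key"))
}
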