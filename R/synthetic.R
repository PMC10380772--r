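# Synthetic-data generator: emulates the statistical structure of the study
# inputs (multi-exon genes with group-dependent length/exon-count/GC,
# binomial junction counts around a true PSI, per-context methylation rates
# with planted AS-vs-normal differences, planted 1:1 orthologs for RBH) so
# the full pipeline runs and is testable with no sequencing data.
#
# Every generator is a pure function of its config (which carries the seed).

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline is designed around:
#' 500 genes (300 never-spliced, 100 SE-hosting, 100 RI-hosting) on six
#' contigs (three At, three Dt), 13 samples (ovules at -3..25 DPA, fibers at
#' 10..25 DPA), group-dependent gene features targeting normal/AS means of
#' about 1868/4450 bp length, 3.3/9.4-10 exons and 0.40/0.36 GC, junction
#' GC deltas planting E' < E for SE and I' > I for RI, binomial junction
#' counts around a Beta(2,2) true PSI at mean depth 50, and per-context
#' methylation rates planting a gene-body CpG increase and a junction
#' CHH/CHG decrease in AS genes.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_normal,n_se,n_ri gene counts per group.
#' @param len_mean_normal,len_mean_as,len_sdlog log-normal gene-length
#'   parameters (arithmetic means in bp).
#' @param exon_mean_normal,exon_mean_se,exon_mean_ri mean exon counts
#'   (shifted Poisson; SE genes are forced to >= 3 exons, RI to >= 2).
#' @param gc_normal,gc_as,gc_sd per-gene GC targets.
#' @param se_exon_delta,ri_intron_delta planted GC shifts of the 20 bp
#'   exon-side (SE, subtracted) and intron-side (RI, added) junction windows.
#' @param depth_mean mean junction-read depth per event per sample.
#' @param frac_conservative,frac_specific,frac_extreme planted shares of
#'   conservative events (retained in every period group), group-specific
#'   events (zero coverage elsewhere) and extreme-PSI events (outside the
#'   retention interval, to exercise the filter).
#' @param meth_body_cpg_as,meth_body_cpg_normal,meth_body_chg,meth_body_chh
#'   gene-body methylation rates; CpG differs by group, CHG/CHH do not.
#' @param meth_junction_as junction-neighborhood (+/- 50 bp) rates for AS
#'   genes, named `CpG`/`CHG`/`CHH`.
#' @param meth_intergenic intergenic rates, same names.
#' @param meth_coverage mean per-cytosine coverage (Poisson).
#' @param n_ortholog_pairs,decoy_frac RBH plant: number of 1:1 At/Dt
#'   ortholog pairs and share of pairs that also receive lower-scoring
#'   decoy hits.
#' @param n_sf_panel size of the synthetic splicing-factor expression panel.
#' @param at_bias probability that an AS gene is placed on an At contig
#'   (plants the subgenome asymmetry).
#' @param gap_mean mean intergenic gap in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_normal = 300L, n_se = 100L, n_ri = 100L,
                       len_mean_normal = 1868, len_mean_as = 4450,
                       len_sdlog = 0.45,
                       exon_mean_normal = 3.3, exon_mean_se = 9.44,
                       exon_mean_ri = 10.03,
                       gc_normal = 0.40, gc_as = 0.36, gc_sd = 0.02,
                       se_exon_delta = 0.08, ri_intron_delta = 0.08,
                       depth_mean = 50,
                       frac_conservative = 0.3, frac_specific = 0.3,
                       frac_extreme = 0.1,
                       meth_body_cpg_as = 0.7, meth_body_cpg_normal = 0.4,
                       meth_body_chg = 0.3, meth_body_chh = 0.1,
                       meth_junction_as = c(CpG = 0.7, CHG = 0.10,
                                            CHH = 0.02),
                       meth_intergenic = c(CpG = 0.3, CHG = 0.2, CHH = 0.08),
                       meth_coverage = 20,
                       n_ortholog_pairs = 20L, decoy_frac = 0.5,
                       n_sf_panel = 30L,
                       at_bias = 0.55, gap_mean = 500) {
  structure(as.list(environment()), class = "sim_config")
}

#' The study's sample design
#'
#' Nine ovule time points (-3, 0, 1, 3, 5, 10, 15, 20, 25 DPA) and four
#' fiber time points (10, 15, 20, 25 DPA): 13 samples over five period
#' groups (fibers are not sampled before 10 DPA, so fiber stage 1 does not
#' exist).
#'
#' @return design `data.table` as from [read_design()].
#' @export
default_design <- function() {
  d <- data.table(
    sample_id = c("ovule_m3", "ovule_00", "ovule_01", "ovule_03", "ovule_05",
                  "ovule_10", "ovule_15", "ovule_20", "ovule_25",
                  "fiber_10", "fiber_15", "fiber_20", "fiber_25"),
    tissue = c(rep("ovule", 9), rep("fiber", 4)),
    dpa = c(-3L, 0L, 1L, 3L, 5L, 10L, 15L, 20L, 25L, 10L, 15L, 20L, 25L))
  read_design(d)
}

# draw an exon/intron layout for a gene of length L with k exons
# (1-based local coordinates); minimum exon 50 bp, minimum intron 80 bp
gene_layout <- function(L, k) {
  min_exon <- 50L; min_intron <- 80L
  k <- max(1L, min(k, (L + min_intron) %/% (min_exon + min_intron)))
  n_intron <- k - 1L
  slack <- L - k * min_exon - n_intron * min_intron
  w <- stats::rgamma(2L * k - 1L, shape = 1)
  extra <- floor(slack * w / sum(w))
  extra[1] <- extra[1] + (slack - sum(extra))
  widths <- integer(2L * k - 1L)
  widths[seq(1, 2 * k - 1, by = 2)] <- min_exon
  if (n_intron) widths[seq(2, 2 * k - 2, by = 2)] <- min_intron
  widths <- widths + extra
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  exon_idx <- seq(1, 2 * k - 1, by = 2)
  cbind(start = starts[exon_idx], end = ends[exon_idx])
}

#' Generate the synthetic genome, annotation and per-gene truth
#'
#' Draws gene groups, lengths, exon counts and GC targets; chooses each AS
#' gene's event site (a skipped internal exon for SE, a retained intron for
#' RI); places genes without overlap on six contigs (chrA01-03, chrD01-03,
#' AS genes biased towards At); and samples sequence whose per-base GC
#' follows the gene's target, with the planted junction-window deltas
#' (SE exon-side lowered, RI intron-side raised) written into the sequence.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `gene_models` (as
#'   [read_gtf()] plus `group`), `events_plan` (per AS gene: type and the
#'   0-based half-open alternative segment), `truth` (per-gene group and
#'   targets).
#' @export
make_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "genome"))
  cfg <- config
  n <- cfg$n_normal + cfg$n_se + cfg$n_ri
  group <- c(rep("normal", cfg$n_normal), rep("SE", cfg$n_se),
             rep("RI", cfg$n_ri))
  is_as <- group != "normal"
  meanlog <- ifelse(is_as, log(cfg$len_mean_as), log(cfg$len_mean_normal)) -
    cfg$len_sdlog^2 / 2
  len <- as.integer(round(stats::rlnorm(n, meanlog, cfg$len_sdlog)))
  len <- pmax(len, ifelse(is_as, 1600L, 300L))
  k <- 1L + stats::rpois(n, ifelse(group == "normal", cfg$exon_mean_normal,
                            ifelse(group == "SE", cfg$exon_mean_se,
                                   cfg$exon_mean_ri)) - 1)
  k[group == "SE"] <- pmax(k[group == "SE"], 3L)
  k[group == "RI"] <- pmax(k[group == "RI"], 2L)
  gc <- pmin(0.8, pmax(0.2, stats::rnorm(
    n, ifelse(is_as, cfg$gc_as, cfg$gc_normal), cfg$gc_sd)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # contig assignment: AS genes biased to At
  chroms <- c("chrA01", "chrA02", "chrA03", "chrD01", "chrD02", "chrD03")
  sub <- ifelse(is_as,
                ifelse(stats::runif(n) < cfg$at_bias, "At", "Dt"),
                sample(c("At", "Dt"), n, replace = TRUE))
  chrom <- ifelse(sub == "At", sample(chroms[1:3], n, replace = TRUE),
                  sample(chroms[4:6], n, replace = TRUE))

  gene_id <- sprintf("Gh_%s_%04d", ifelse(sub == "At", "A", "D"), seq_len(n))
  ord <- sample(n)       # shuffle placement order within chromosomes

  margin <- 3000L
  rows <- vector("list", n)
  offsets <- stats::setNames(rep(margin, length(chroms)), chroms)
  for (j in ord) {
    ch <- chrom[j]
    layout <- gene_layout(len[j], k[j])
    glen <- layout[nrow(layout), "end"]
    gstart <- offsets[[ch]] + 1L
    rows[[j]] <- data.table(
      gene_id = gene_id[j], chrom = ch, strand = strand[j],
      start = gstart, end = gstart + glen - 1L,
      exon_count = nrow(layout),
      exons = list(cbind(start = layout[, "start"] + gstart - 1L,
                         end = layout[, "end"] + gstart - 1L)),
      group = group[j], gc_target = gc[j])
    offsets[[ch]] <- gstart + glen - 1L +
      as.integer(stats::rpois(1, cfg$gap_mean)) + 200L
  }
  gm <- rbindlist(rows)
  gm[, gene_length := end - start + 1L]
  gm[, intron_count := exon_count - 1L]

  # event sites: SE = one internal exon; RI = one intron
  plan <- gm[group != "normal"]
  events_plan <- rbindlist(lapply(seq_len(nrow(plan)), function(i) {
    ex <- plan$exons[[i]]
    if (plan$group[i] == "SE") {
      ei <- if (nrow(ex) > 2L) sample(2:(nrow(ex) - 1L), 1L) else 2L
      data.table(gene_id = plan$gene_id[i], event_type = "SE",
                 junc_start = ex[ei, "start"] - 1L, junc_end = ex[ei, "end"],
                 up_start = ex[ei - 1L, "start"] - 1L,
                 up_end = ex[ei - 1L, "end"],
                 down_start = ex[ei + 1L, "start"] - 1L,
                 down_end = ex[ei + 1L, "end"])
    } else {
      ii <- sample.int(nrow(ex) - 1L, 1L)
      data.table(gene_id = plan$gene_id[i], event_type = "RI",
                 junc_start = ex[ii, "end"], junc_end = ex[ii + 1L, "start"] - 1L,
                 up_start = ex[ii, "start"] - 1L, up_end = ex[ii, "end"],
                 down_start = ex[ii + 1L, "start"] - 1L,
                 down_end = ex[ii + 1L, "end"])
    }
  }))

  # sample sequence: per-base GC probability vector per contig
  chrom_len <- stats::setNames(as.integer(offsets + margin), chroms)
  seqs <- list()
  gc_intergenic <- 0.35
  for (ch in chroms) {
    L <- chrom_len[[ch]]
    p <- rep(gc_intergenic, L)
    sub_gm <- gm[chrom == ch]
    for (i in seq_len(nrow(sub_gm)))
      p[sub_gm$start[i]:sub_gm$end[i]] <- sub_gm$gc_target[i]
    # planted junction-window deltas (20 bp adjacent to each event boundary)
    epl <- merge(events_plan, gm[, .(gene_id, chrom, gc_target)],
                 by = "gene_id")[chrom == ch]
    for (i in seq_len(nrow(epl))) {
      g0 <- epl$gc_target[i]
      s1 <- epl$junc_start[i] + 1L    # 1-based first base of the segment
      e1 <- epl$junc_end[i]           # 1-based last base of the segment
      if (epl$event_type[i] == "SE") {
        # exon-side windows just inside the skipped exon
        p[s1:(s1 + 19L)] <- max(0.02, g0 - cfg$se_exon_delta)
        p[(e1 - 19L):e1] <- max(0.02, g0 - cfg$se_exon_delta)
      } else {
        # intron-side windows just inside the retained intron
        p[s1:(s1 + 19L)] <- min(0.98, g0 + cfg$ri_intron_delta)
        p[(e1 - 19L):e1] <- min(0.98, g0 + cfg$ri_intron_delta)
      }
    }
    u <- stats::runif(L)
    v <- stats::runif(L)
    base <- ifelse(u < p, ifelse(v < 0.5, "G", "C"),
                   ifelse(v < 0.5, "A", "T"))
    seqs[[ch]] <- paste(base, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  truth <- gm[, .(gene_id, chrom, strand, start, end, gene_length,
                  exon_count, group, gc_target)]
  setkey(gm, gene_id)
  list(genome = genome, gene_models = gm, events_plan = events_plan,
       truth = truth)
}

# retention predicate used when planting guaranteed-retained cells
retained_cell <- function(ijc, sjc, ifl, sfl, cfgf = filter_config()) {
  psi <- compute_psi(ijc, sjc, ifl, sfl)
  !is.na(psi) && psi > cfgf$psi_low && psi < cfgf$psi_high &&
    sjc >= cfgf$min_sjc
}

#' Generate rMATS-style junction-count tables with known truth
#'
#' Each AS gene hosts one event at its true junctions. Events are assigned a
#' presence category: conservative events are guaranteed retained in every
#' sample (counts redrawn until the retention predicate holds), specific
#' events are retained only in the samples of one period group and have zero
#' coverage elsewhere, and the remaining events draw a Beta(2,2) true PSI
#' (a planted fraction of them forced outside the retention interval) with
#' Poisson depth, so the filter is genuinely exercised. Junction reads are
#' binomial around the true PSI after form-length adjustment (inclusion form
#' length 2, skipping form length 1).
#'
#' @param config a [sim_config()].
#' @param sim output of [make_genome_and_annotation()].
#' @param design design table (default [default_design()]).
#' @return list with `events` (long table as from [read_rmats_table()]) and
#'   `truth` (per event: category, planted group, true PSI).
#' @export
make_events <- function(config, sim, design = default_design()) {
  stopifnot(inherits(config, "sim_config"))
  force(sim); force(design)    # arguments may consume RNG; force before seeding
  set.seed(child_seed(config$seed, "events"))
  ep <- merge(sim$events_plan,
              sim$gene_models[, .(gene_id, chrom, strand)], by = "gene_id")
  n_ev <- nrow(ep)
  groups <- unique(design$group)
  cat_draw <- stats::runif(n_ev)
  category <- ifelse(cat_draw < config$frac_conservative, "conservative",
              ifelse(cat_draw < config$frac_conservative +
                       config$frac_specific, "specific", "random"))
  planted_group <- ifelse(category == "specific",
                          sample(groups, n_ev, replace = TRUE), NA)
  ifl <- 2; sfl <- 1
  cfgf <- filter_config()

  draw_counts <- function(psi_true, depth) {
    ntot <- stats::rpois(1L, depth)
    p_inc <- psi_true * ifl / (psi_true * ifl + (1 - psi_true) * sfl)
    ijc <- stats::rbinom(1L, ntot, p_inc)
    c(ijc = ijc, sjc = ntot - ijc)
  }
  draw_retained <- function(psi_true, depth) {
    for (try in 1:200) {
      cnt <- draw_counts(psi_true, depth)
      if (retained_cell(cnt["ijc"], cnt["sjc"], ifl, sfl, cfgf)) return(cnt)
    }
    # deterministic fallback at the expected counts
    ijc <- round(depth * psi_true * ifl /
                   (psi_true * ifl + (1 - psi_true) * sfl))
    c(ijc = ijc, sjc = max(5, round(depth) - ijc))
  }

  rows <- vector("list", n_ev * nrow(design))
  truth_rows <- vector("list", n_ev)
  ri <- 0L
  for (i in seq_len(n_ev)) {
    cat_i <- category[i]
    psi_true <- switch(cat_i,
      conservative = stats::runif(1, 0.35, 0.65),
      specific = stats::runif(1, 0.35, 0.65),
      random = if (stats::runif(1) < config$frac_extreme)
        sample(c(stats::runif(1, 0.91, 0.99), stats::runif(1, 0.01, 0.09)), 1)
      else stats::rbeta(1, 2, 2))
    depth <- max(20, config$depth_mean)
    # anchors in the coordinate-column order of the written tables, so the
    # event key survives a write/read round trip
    anchors <- if (ep$event_type[i] == "SE")
      paste(ep$junc_start[i], ep$junc_end[i], ep$up_start[i],
            ep$up_end[i], ep$down_start[i], ep$down_end[i], sep = ":")
    else
      paste(ep$up_start[i], ep$down_end[i], ep$up_start[i],
            ep$junc_start[i], ep$junc_end[i], ep$down_end[i], sep = ":")
    key <- paste(ep$event_type[i], ep$chrom[i], ep$strand[i], anchors,
                 sep = "|")
    for (s in seq_len(nrow(design))) {
      in_group <- design$group[s] == planted_group[i]
      cnt <- if (cat_i == "conservative" || (cat_i == "specific" && in_group))
        draw_retained(psi_true, depth)
      else if (cat_i == "specific") c(ijc = 0, sjc = 0)
      else draw_counts(psi_true, stats::rpois(1, config$depth_mean))
      ri <- ri + 1L
      rows[[ri]] <- data.table(
        event_key = key, event_id = as.character(i), gene_id = ep$gene_id[i],
        event_type = ep$event_type[i], chrom = ep$chrom[i],
        strand = ep$strand[i], anchors = anchors,
        junc_start = ep$junc_start[i], junc_end = ep$junc_end[i],
        up_start = ep$up_start[i], up_end = ep$up_end[i],
        down_start = ep$down_start[i], down_end = ep$down_end[i],
        sample_id = design$sample_id[s],
        ijc = unname(cnt["ijc"]), sjc = unname(cnt["sjc"]),
        inc_form_len = ifl, skip_form_len = sfl)
    }
    truth_rows[[i]] <- data.table(
      event_key = key, gene_id = ep$gene_id[i], event_type = ep$event_type[i],
      category = cat_i, planted_group = planted_group[i], psi_true = psi_true)
  }
  events <- rbindlist(rows)
  events[, psi := compute_psi(ijc, sjc, inc_form_len, skip_form_len)]
  list(events = events[], truth = rbindlist(truth_rows))
}

#' Write events as per-sample rMATS-style tables
#'
#' One tab-separated file per (sample, event type) named
#' `<sample>.<TYPE>.txt`, with the type's coordinate columns and the
#' sample's counts in `IJC_SAMPLE_1`/`SJC_SAMPLE_1` as two comma-separated
#' pseudo-replicates (summed again on read).
#'
#' @param events long events table from [make_events()].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_rmats_tables <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- as.data.table(events)
  paths <- character()
  for (s in unique(ev$sample_id)) {
    for (ty in unique(ev[sample_id == s, event_type])) {
      sub <- ev[sample_id == s & event_type == ty]
      r1 <- floor(sub$ijc / 2); r2 <- sub$ijc - r1
      s1 <- floor(sub$sjc / 2); s2 <- sub$sjc - s1
      base_cols <- data.table(ID = sub$event_id, GeneID = sub$gene_id,
                              geneSymbol = sub$gene_id, chr = sub$chrom,
                              strand = sub$strand)
      coords <- if (ty == "SE") data.table(
        exonStart_0base = sub$junc_start, exonEnd = sub$junc_end,
        upstreamES = sub$up_start, upstreamEE = sub$up_end,
        downstreamES = sub$down_start, downstreamEE = sub$down_end)
      else data.table(
        riExonStart_0base = sub$up_start, riExonEnd = sub$down_end,
        upstreamES = sub$up_start, upstreamEE = sub$junc_start,
        downstreamES = sub$junc_end, downstreamEE = sub$down_end)
      counts <- data.table(IJC_SAMPLE_1 = paste(r1, r2, sep = ","),
                           SJC_SAMPLE_1 = paste(s1, s2, sep = ","),
                           IncFormLen = sub$inc_form_len,
                           SkipFormLen = sub$skip_form_len)
      out <- cbind(base_cols, coords, counts)
      path <- file.path(dir, sprintf("%s.%s.txt", s, ty))
      fwrite(out, path, sep = "\t", quote = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Generate a per-cytosine methylome with planted group differences
#'
#' Walks every cytosine of the synthetic genome (both strands, context read
#' from the sequence), assigns each a context- and region-specific true
#' rate — intergenic baseline, gene-body rates with the planted AS CpG
#' increase, and junction-neighborhood overrides (+/- 50 bp around AS event
#' boundaries) with the planted CHH/CHG decrease — then draws Poisson
#' coverage and binomial methylated counts. Zero-coverage sites are not
#' emitted.
#'
#' @param config a [sim_config()].
#' @param sim output of [make_genome_and_annotation()].
#' @return list with `records` (as [read_methylation()]) and `truth_rates`
#'   (per group/region/context planted rates).
#' @export
make_methylome <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  force(sim)
  set.seed(child_seed(config$seed, "methylome"))
  gm <- sim$gene_models
  ep <- merge(sim$events_plan, gm[, .(gene_id, chrom)], by = "gene_id")
  out <- vector("list", length(sim$genome))
  for (ci in seq_along(sim$genome)) {
    ch <- names(sim$genome)[ci]
    v <- strsplit(as.character(sim$genome[[ci]]), "")[[1]]
    L <- length(v)
    rate <- list(
      CpG = rep(config$meth_intergenic[["CpG"]], L),
      CHG = rep(config$meth_intergenic[["CHG"]], L),
      CHH = rep(config$meth_intergenic[["CHH"]], L))
    sub_gm <- gm[chrom == ch]
    for (i in seq_len(nrow(sub_gm))) {
      span <- sub_gm$start[i]:sub_gm$end[i]
      rate$CpG[span] <- if (sub_gm$group[i] == "normal")
        config$meth_body_cpg_normal else config$meth_body_cpg_as
      rate$CHG[span] <- config$meth_body_chg
      rate$CHH[span] <- config$meth_body_chh
    }
    sub_ep <- ep[chrom == ch]
    for (i in seq_len(nrow(sub_ep))) {
      for (p0 in c(sub_ep$junc_start[i], sub_ep$junc_end[i])) {
        span <- max(1L, p0 + 1L - 50L):min(L, p0 + 1L + 50L)
        rate$CpG[span] <- config$meth_junction_as[["CpG"]]
        rate$CHG[span] <- config$meth_junction_as[["CHG"]]
        rate$CHH[span] <- config$meth_junction_as[["CHH"]]
      }
    }
    vp2 <- c(v[-1], "N"); vp3 <- c(v[-(1:2)], "N", "N")
    vm2 <- c("N", v[-L]); vm3 <- c("N", "N", v[-((L - 1):L)])
    plus <- which(v == "C")
    ctx_p <- ifelse(vp2[plus] == "G", "CpG",
                    ifelse(vp3[plus] == "G", "CHG", "CHH"))
    minus <- which(v == "G")
    ctx_m <- ifelse(vm2[minus] == "C", "CpG",
                    ifelse(vm3[minus] == "C", "CHG", "CHH"))
    site <- data.table(
      chrom = ch,
      pos = c(plus, minus),
      strand = c(rep("+", length(plus)), rep("-", length(minus))),
      context = c(ctx_p, ctx_m))
    site[, r := rate[["CpG"]][pos] * (context == "CpG") +
            rate[["CHG"]][pos] * (context == "CHG") +
            rate[["CHH"]][pos] * (context == "CHH")]
    site[, n_total := stats::rpois(.N, config$meth_coverage)]
    site <- site[n_total > 0L]
    site[, n_meth := stats::rbinom(.N, n_total, r)]
    site[, r := NULL]
    out[[ci]] <- site
  }
  records <- rbindlist(out)
  setkey(records, chrom, pos)
  truth_rates <- rbindlist(list(
    data.table(region = "body", group = "AS", context = "CpG",
               rate = config$meth_body_cpg_as),
    data.table(region = "body", group = "normal", context = "CpG",
               rate = config$meth_body_cpg_normal),
    data.table(region = "junction", group = "AS", context = c("CHG", "CHH"),
               rate = c(config$meth_junction_as[["CHG"]],
                        config$meth_junction_as[["CHH"]])),
    data.table(region = "junction", group = "normal",
               context = c("CHG", "CHH"),
               rate = c(config$meth_body_chg, config$meth_body_chh))))
  list(records = records[, .(chrom, pos, strand, context, n_meth, n_total)],
       truth_rates = truth_rates)
}

#' Generate forward/reverse BLAST tables with planted 1:1 orthologs
#'
#' Pairs the first `n_ortholog_pairs` At genes with as many Dt genes; each
#' planted pair receives mutual top hits, and a configurable share of pairs
#' also receives random decoy hits at strictly lower bitscore, so reciprocal
#' best hit must recover exactly the plant.
#'
#' @param config a [sim_config()].
#' @param sim output of [make_genome_and_annotation()].
#' @return list with `forward`, `reverse` (outfmt-6 `data.table`s) and
#'   `truth` (gene_a, gene_b planted pairs).
#' @export
make_blast <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  force(sim)
  set.seed(child_seed(config$seed, "blast"))
  gm <- sim$gene_models
  at <- sort(gm[grepl("^chrA", chrom), gene_id])
  dt_ <- sort(gm[grepl("^chrD", chrom), gene_id])
  np <- min(config$n_ortholog_pairs, length(at), length(dt_))
  pairs <- data.table(gene_a = at[seq_len(np)], gene_b = dt_[seq_len(np)])
  hit_row <- function(q, s, bits) data.table(
    query_id = q, subject_id = s, identity = round(stats::runif(1, 70, 99), 2),
    aln_length = sample(200:900, 1), mismatches = sample(0:40, 1),
    gap_opens = sample(0:5, 1), q_start = 1L, q_end = 500L,
    s_start = 1L, s_end = 500L,
    evalue = signif(10^(-bits / 10), 3), bitscore = round(bits, 1))
  fwd <- list(); rev <- list()
  for (i in seq_len(np)) {
    bits <- stats::runif(1, 500, 900)
    fwd[[length(fwd) + 1L]] <- hit_row(pairs$gene_a[i], pairs$gene_b[i], bits)
    rev[[length(rev) + 1L]] <- hit_row(pairs$gene_b[i], pairs$gene_a[i],
                                       bits * stats::runif(1, 0.95, 1.05))
    if (stats::runif(1) < config$decoy_frac) {
      decoy_b <- sample(setdiff(dt_[seq_len(np)], pairs$gene_b[i]), 1)
      fwd[[length(fwd) + 1L]] <- hit_row(pairs$gene_a[i], decoy_b,
                                         bits * stats::runif(1, 0.3, 0.8))
      decoy_a <- sample(setdiff(at[seq_len(np)], pairs$gene_a[i]), 1)
      rev[[length(rev) + 1L]] <- hit_row(pairs$gene_b[i], decoy_a,
                                         bits * stats::runif(1, 0.3, 0.8))
    }
  }
  list(forward = rbindlist(fwd), reverse = rbindlist(rev), truth = pairs)
}

#' Generate a counts matrix and enrichment fixtures
#'
#' Negative-binomial counts for every gene over the 13 samples; a synthetic
#' splicing-factor panel whose expression is down-regulated in 25 DPA ovules
#' and in all fiber samples; and a term map with one term enriched for AS
#' genes plus random background terms.
#'
#' @param config a [sim_config()].
#' @param sim output of [make_genome_and_annotation()].
#' @param design design table.
#' @return list with `counts` (gene x sample matrix), `sf_panel` (gene ids),
#'   `term_map` (term, gene), `down_samples` (sample ids with the planted
#'   down-regulation).
#' @export
make_counts <- function(config, sim, design = default_design()) {
  stopifnot(inherits(config, "sim_config"))
  force(sim); force(design)
  set.seed(child_seed(config$seed, "counts"))
  gm <- sim$gene_models
  n <- nrow(gm)
  base_mu <- stats::rlnorm(n, log(200), 0.6)
  counts <- sapply(seq_len(nrow(design)), function(s)
    stats::rnbinom(n, mu = base_mu, size = 10))
  dimnames(counts) <- list(gm$gene_id, design$sample_id)
  sf_panel <- sample(gm$gene_id, min(config$n_sf_panel, n))
  down_samples <- design[tissue == "fiber" | (tissue == "ovule" & dpa == 25),
                         sample_id]
  counts[sf_panel, down_samples] <-
    stats::rnbinom(length(sf_panel) * length(down_samples),
                   mu = rep(base_mu[match(sf_panel, gm$gene_id)] * 0.15,
                            length(down_samples)), size = 10)
  as_genes <- gm[group != "normal", gene_id]
  term_as <- data.table(term = "T_AS_biased",
                        gene = sample(as_genes,
                                      min(80L, length(as_genes))))
  other <- rbindlist(lapply(1:9, function(t)
    data.table(term = sprintf("T_rand_%02d", t),
               gene = sample(gm$gene_id, min(60L, n)))))
  list(counts = counts, sf_panel = sf_panel,
       term_map = rbind(term_as, other), down_samples = down_samples)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator and writes all standard-format inputs under `dir`:
#' `genome.fa`, `annotation.gtf`, `design.tsv`, per-sample rMATS-style
#' tables under `events/`, `methylation.tsv`, `blast_fwd.tsv`,
#' `blast_rev.tsv`, `counts.tsv`, `term_map.tsv`, `sf_panel.txt`, and the
#' truth tables `truth_genes.tsv` / `truth_events.tsv`.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return (invisibly) list of the in-memory objects and written paths.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- default_design()
  sim <- make_genome_and_annotation(config)
  ev <- make_events(config, sim, design)
  meth <- make_methylome(config, sim)
  bl <- make_blast(config, sim)
  cnt <- make_counts(config, sim, design)

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(sim$gene_models, gtf)
  write_design_tsv(design, file.path(dir, "design.tsv"))
  write_rmats_tables(ev$events, file.path(dir, "events"))
  write_methylation_tsv(meth$records, file.path(dir, "methylation.tsv"))
  write_blast_tsv(bl$forward, file.path(dir, "blast_fwd.tsv"))
  write_blast_tsv(bl$reverse, file.path(dir, "blast_rev.tsv"))
  cdt <- data.table(gene_id = rownames(cnt$counts))
  for (s in colnames(cnt$counts)) cdt[[s]] <- cnt$counts[, s]
  fwrite(cdt, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE)
  fwrite(cnt$term_map, file.path(dir, "term_map.tsv"), sep = "\t",
         quote = FALSE)
  writeLines(cnt$sf_panel, file.path(dir, "sf_panel.txt"))
  fwrite(sim$truth, file.path(dir, "truth_genes.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(ev$truth, file.path(dir, "truth_events.tsv"), sep = "\t",
         quote = FALSE)
  invisible(list(dir = dir, design = design, sim = sim, events = ev,
                 methylome = meth, blast = bl, expression = cnt))
}

#' Write gene models as a GTF file
#'
#' Emits one exon feature per merged exon with `gene_id` and a single
#' derived `transcript_id`, 1-based inclusive coordinates.
#'
#' @param gene_models gene models table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  gm <- as.data.table(gene_models)
  lines <- unlist(lapply(seq_len(nrow(gm)), function(i) {
    ex <- gm$exons[[i]]
    sprintf('%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
            gm$chrom[i], ex[, "start"], ex[, "end"], gm$strand[i],
            gm$gene_id[i], gm$gene_id[i])
  }))
  writeLines(lines, path)
  invisible(path)
}
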