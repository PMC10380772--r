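# End-to-end orchestration: read every input from a directory of
# standard-format files, run all stages, write plain TSV outputs and a
# deterministic JSON manifest.

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full alternative-splicing analysis pipeline
#'
#' Expects under `input_dir` the file layout written by
#' [simulate_dataset()]: `genome.fa`, `annotation.gtf`, `design.tsv`,
#' `events/` with per-sample rMATS-style tables, `methylation.tsv`,
#' `blast_fwd.tsv`/`blast_rev.tsv`, `counts.tsv`, `term_map.tsv`,
#' `sf_panel.txt`. Every stage's result is written as TSV under `out_dir`
#' together with `manifest.json` (parameters and row counts; identical
#' across reruns on identical inputs). A failing stage aborts with the
#' stage named; outputs written before the failure are retained.
#'
#' @param input_dir directory of inputs.
#' @param out_dir output directory (created).
#' @param filter a [filter_config()].
#' @param profile a [profile_config()].
#' @param window_bp chromosome-density window width.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_pipeline <- function(input_dir, out_dir, filter = filter_config(),
                         profile = profile_config(), window_bp = 1e5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)
  res <- list()

  design <- stage_try("formats_io",
                      read_design(file.path(input_dir, "design.tsv")))
  events <- stage_try("formats_io",
                      read_events_dir(file.path(input_dir, "events"), design))
  gm <- stage_try("formats_io", read_gtf(file.path(input_dir,
                                                   "annotation.gtf")))
  fa_path <- file.path(input_dir, "genome.fa")
  if (!file.exists(fa_path))
    stopf("pipeline stage 'seq_features' failed: missing FASTA %s", fa_path)
  genome <- stage_try("seq_features", Biostrings::readDNAStringSet(fa_path))
  names(genome) <- sub("\\s.*$", "", names(genome))

  retained <- stage_try("psi_filter", filter_events(events, filter))
  write_events_tsv(retained, out("retained_events.tsv"))

  census <- stage_try("census_sets", build_census(retained, design))
  fwrite(census$per_sample_genes, out("census_genes_per_sample.tsv"),
         sep = "\t")
  fwrite(census$per_sample_events, out("census_events_per_sample.tsv"),
         sep = "\t")
  fwrite(census$genes, out("census_genes.tsv"), sep = "\t")
  hs <- hotspots(census)
  fwrite(hs, out("hotspot_genes.tsv"), sep = "\t")
  tb <- type_breakdown(census)
  fwrite(tb$per_sample, out("type_breakdown_per_sample.tsv"), sep = "\t")
  fwrite(tb$ranges, out("type_breakdown_ranges.tsv"), sep = "\t")
  mult <- gene_type_multiplicity(census)
  fwrite(mult, out("gene_type_multiplicity.tsv"), sep = "\t")
  dens <- stage_try("census_sets",
                    chromosome_density(census, gm, window_bp = window_bp))
  fwrite(dens$per_chrom, out("chromosome_totals.tsv"), sep = "\t")
  fwrite(dens$windows, out("chromosome_windows.tsv"), sep = "\t")

  blast_f <- file.path(input_dir, "blast_fwd.tsv")
  pairs <- NULL
  if (file.exists(blast_f)) {
    pairs <- stage_try("homology", rbh(
      read_blast(blast_f), read_blast(file.path(input_dir, "blast_rev.tsv"))))
    fwrite(pairs, out("homolog_pairs.tsv"), sep = "\t")
  }
  subg <- stage_try("census_sets", subgenome_compare(census, pairs = NULL))
  fwrite(subg$totals, out("subgenome_totals.tsv"), sep = "\t")
  fwrite(subg$per_sample, out("subgenome_per_sample.tsv"), sep = "\t")

  sets <- stage_try("census_sets", stage_sets(census))
  fwrite(sets$genes$upset, out("upset_genes.tsv"), sep = "\t")
  fwrite(sets$events$upset, out("upset_events.tsv"), sep = "\t")

  feats <- stage_try("seq_features", gene_features(gm, genome, retained))
  fwrite(feats, out("gene_features.tsv"), sep = "\t")
  grp <- stage_try("seq_features", compare_groups(feats))
  fwrite(grp$summary, out("gene_feature_summary.tsv"), sep = "\t")
  fwrite(grp$tests, out("gene_feature_tests.tsv"), sep = "\t")

  sites <- stage_try("seq_features", extract_junctions(retained, gm))
  jw <- stage_try("seq_features", junction_gc(sites, genome))
  fwrite(jw, out("junction_windows.tsv"), sep = "\t")
  jcmp <- stage_try("seq_features", compare_junction_gc(jw))
  fwrite(jcmp, out("junction_gc_tests.tsv"), sep = "\t")

  counts_f <- file.path(input_dir, "counts.tsv")
  expr <- NULL
  if (file.exists(counts_f)) {
    cdt <- fread(counts_f)
    cm <- as.matrix(cdt[, -1]); rownames(cm) <- cdt[[1]]
    tp <- stage_try("expression_enrichment", tpm_normalize(cm, gm))
    panel_genes <- readLines(file.path(input_dir, "sf_panel.txt"))
    panel <- stage_try("expression_enrichment", expression_panel(
      tp$tpm, panel_genes, design,
      group_a = design[tissue == "fiber" | dpa == 25, sample_id],
      group_b = design[tissue == "ovule" & dpa < 25, sample_id]))
    zdt <- data.table(gene_id = rownames(panel$z))
    for (s in colnames(panel$z)) zdt[[s]] <- panel$z[, s]
    fwrite(zdt, out("sf_panel_zscores.tsv"), sep = "\t")
    if (!is.null(panel$flags))
      fwrite(panel$flags, out("sf_panel_flags.tsv"), sep = "\t")
    tm <- fread(file.path(input_dir, "term_map.tsv"))
    enr <- stage_try("expression_enrichment", enrich(
      intersect(census$genes$gene_id, gm$gene_id), gm$gene_id, tm))
    fwrite(enr, out("enrichment.tsv"), sep = "\t")
    expr <- list(tpm = tp, panel = panel, enrichment = enr)
  }

  meth_f <- file.path(input_dir, "methylation.tsv")
  meth <- NULL
  if (file.exists(meth_f)) {
    records <- stage_try("methylation", read_methylation(meth_f))
    idx <- build_meth_index(records)
    groups <- list(SE = feats[group_SE == TRUE, gene_id],
                   RI = feats[group_RI == TRUE, gene_id],
                   normal = feats[as_group == "normal", gene_id])
    profs <- rbindlist(lapply(names(groups), function(g)
      stage_try("methylation", gene_body_profile(
        gm[gene_id %in% groups[[g]]], idx, profile, group = g))$profile))
    fwrite(profs, out("methylation_body_profiles.tsv"), sep = "\t")
    jprof <- stage_try("methylation", junction_profile(sites, idx, profile))
    fwrite(jprof, out("methylation_junction_profiles.tsv"), sep = "\t")
    body_regions <- rbindlist(lapply(names(groups), function(g)
      gm[gene_id %in% groups[[g]],
         .(chrom, start, end, id = gene_id, group = g)]))
    body_levels <- stage_try("methylation",
                             methylation_levels(body_regions, idx))
    body_cmp <- compare_methylation(body_levels)
    fwrite(body_cmp, out("methylation_body_tests.tsv"), sep = "\t")
    jsites <- copy(sites)
    jsites[, group := ifelse(source %in% c("SE_A", "SE_B"), "SE",
                       ifelse(source %in% c("RI_C", "RI_D"), "RI", "normal"))]
    jregions <- jsites[, .(chrom,
                           start = pmax(1L, position + 1L - 50L),
                           end = position + 1L + 50L,
                           id = paste0(gene_id, "_", .I), group)]
    jlevels <- stage_try("methylation", methylation_levels(jregions, idx))
    jcmp_m <- compare_methylation(jlevels)
    fwrite(jcmp_m, out("methylation_junction_tests.tsv"), sep = "\t")
    meth <- list(body_profiles = profs, junction_profiles = jprof,
                 body_tests = body_cmp, junction_tests = jcmp_m,
                 body_levels = body_levels, junction_levels = jlevels)
  }

  manifest <- list(
    package = "spliceCensus",
    parameters = list(
      psi_low = filter$psi_low, psi_high = filter$psi_high,
      min_sjc = filter$min_sjc, window_bp = window_bp,
      flank_len = profile$flank_len,
      junction_window = profile$junction_window,
      junction_step = profile$junction_step),
    rows = list(
      events_in = nrow(events), events_retained = nrow(retained),
      as_genes = census$totals$n_as_genes,
      as_events = census$totals$n_as_events,
      hotspots = nrow(hs),
      junction_sites = nrow(sites),
      junction_sites_excluded = attr(jw, "n_excluded") %||% 0L,
      homolog_pairs = if (is.null(pairs)) 0L else nrow(pairs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(design = design, retained = retained, census = census,
                 hotspots = hs, type_breakdown = tb, multiplicity = mult,
                 density = dens, pairs = pairs, subgenome = subg,
                 stage_sets = sets, features = feats, feature_tests = grp,
                 junction_sites = sites, junction_windows = jw,
                 junction_gc_tests = jcmp, expression = expr,
                 methylation = meth, manifest = manifest))
}
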