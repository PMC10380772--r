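mk_records <- function(pos, n_meth, n_total, context = "CpG",
                       chrom = "chr1", strand = "+") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_total = as.integer(n_total))
}

test_that("region level is the read-weighted mean", {
  expect_equal(region_level(mk_records(10, 5, 10), "chr1", 1, 100, "CpG"),
               0.5)
  # two sites 0/10 and 10/10 -> 0.5 weighted
  r <- mk_records(c(10, 20), c(0, 10), c(10, 10))
  expect_equal(region_level(r, "chr1", 1, 100, "CpG"), 0.5)
  # no covered cytosine -> missing
  expect_true(is.na(region_level(r, "chr1", 30, 100, "CpG")))
  expect_error(region_level(r, "chr1", 0, 10), "start")
})

test_that("region level equals a brute-force summation oracle", {
  set.seed(61)
  n <- 100L
  r <- mk_records(sample(1:5000, n),
                  n_meth = rbinom(n, 20, 0.3), n_total = 20,
                  context = sample(c("CpG", "CHG", "CHH"), n, TRUE))
  r[, n_total := pmax(n_meth, rpois(n, 20))]
  for (i in 1:20) {
    lo <- sample(1:4500, 1); hi <- lo + sample(50:500, 1)
    for (ctx in c("CpG", "CHG", "CHH", "m5C")) {
      sub <- r[pos >= lo & pos <= hi]
      if (ctx != "m5C") sub <- sub[context == ctx]
      want <- if (nrow(sub) == 0) NA_real_ else
        sum(sub$n_meth) / sum(sub$n_total)
      expect_equal(region_level(r, "chr1", lo, hi, ctx), want)
    }
  }
})

test_that("pooled m5C lies between the per-context extremes; doubling is a no-op", {
  set.seed(62)
  r <- mk_records(1:300, rbinom(300, 10, runif(300)), 10,
                  context = rep(c("CpG", "CHG", "CHH"), 100))
  lv <- sapply(c("CpG", "CHG", "CHH"),
               function(ctx) region_level(r, "chr1", 1, 300, ctx))
  m5 <- region_level(r, "chr1", 1, 300, "m5C")
  expect_gte(m5, min(lv))
  expect_lte(m5, max(lv))
  doubled <- copy(r)[, `:=`(n_meth = 2L * n_meth, n_total = 2L * n_total)]
  for (ctx in c("CpG", "CHG", "CHH", "m5C"))
    expect_equal(region_level(doubled, "chr1", 1, 300, ctx),
                 region_level(r, "chr1", 1, 300, ctx))
})

test_that("window counts follow the closed forms (99 body, 19 junction)", {
  for (L in c(50L, 73L, 150L, 999L, 1000L, 1001L, 20000L, 54321L))
    expect_equal(nrow(spliceCensus:::body_windows(L)), 99L)
  expect_equal(nrow(spliceCensus:::fixed_windows(101L, 10L, 5L)), 19L)
  expect_equal(nrow(spliceCensus:::fixed_windows(2000L, 40L, 20L)), 99L)
  # windows tile within bounds and are never empty
  for (L in c(50L, 137L, 2048L)) {
    w <- spliceCensus:::body_windows(L)
    expect_true(all(w$end_off > w$start_off))
    expect_true(all(w$end_off <= L))
    expect_equal(w$start_off[1], 0L)
  }
})

test_that("uniform methylome gives a flat profile at the planted level", {
  gm <- data.table(gene_id = "g1", chrom = "chr1", strand = "+",
                   start = 3001L, end = 4000L, gene_length = 1000L)
  r <- mk_records(seq(1, 8000, by = 7), 8, 10)
  prof <- gene_body_profile(gm, r, profile_config())
  lv <- prof$profile[context == "CpG", level]
  expect_equal(lv, rep(0.8, 297))
  expect_equal(prof$n_genes, 1L)
  # genes shorter than 50 bp are excluded with a count
  gm2 <- rbind(gm, data.table(gene_id = "tiny", chrom = "chr1",
                              strand = "+", start = 10L, end = 40L,
                              gene_length = 31L))
  expect_equal(gene_body_profile(gm2, r)$n_excluded, 1L)
  expect_error(gene_body_profile(gm[0], r), "empty")
})

test_that("profiles are strand-oriented (upstream = biological 5')", {
  # methylation high only left of the gene in genomic coordinates
  gm_plus <- data.table(gene_id = "g", chrom = "chr1", strand = "+",
                        start = 3001L, end = 4000L, gene_length = 1000L)
  gm_minus <- copy(gm_plus)[, strand := "-"]
  r <- rbind(mk_records(seq(1000, 3000, 5), 10, 10),     # left flank high
             mk_records(seq(3001, 7000, 5), 0, 10))      # rest zero
  up_plus <- gene_body_profile(gm_plus, r)$profile[
    context == "CpG" & segment == "upstream", level]
  up_minus <- gene_body_profile(gm_minus, r)$profile[
    context == "CpG" & segment == "upstream", level]
  expect_equal(mean(up_plus), 1)       # + gene: 5' flank is the left flank
  expect_equal(mean(up_minus), 0)      # - gene: 5' flank is the right flank
})

test_that("planted body CpG difference is recovered; CHH stays flat", {
  sm <- small_sim()
  meth <- make_methylome(sm$cfg, sm$sim)
  gm <- sm$sim$gene_models
  idx <- spliceCensus:::build_meth_index(meth$records)
  as_prof <- gene_body_profile(gm[group != "normal"], idx, group = "AS")
  no_prof <- gene_body_profile(gm[group == "normal"], idx, group = "normal")
  as_cpg <- mean(as_prof$profile[context == "CpG" & segment == "body", level])
  no_cpg <- mean(no_prof$profile[context == "CpG" & segment == "body", level])
  expect_equal(as_cpg, sm$cfg$meth_body_cpg_as, tolerance = 0.05)
  expect_equal(no_cpg, sm$cfg$meth_body_cpg_normal, tolerance = 0.05)
  as_chh <- mean(as_prof$profile[context == "CHH" & segment == "body", level])
  no_chh <- mean(no_prof$profile[context == "CHH" & segment == "body", level])
  expect_lt(abs(as_chh - no_chh), 0.02)
})

test_that("junction profile has 19 windows and skips uncovered sites", {
  site <- data.table(chrom = "chr1", strand = "+", position = 500L,
                     side = "donor", intron_side = "right",
                     source = "SE_A", gene_id = "g")
  r <- mk_records(seq(440, 560, 3), 5, 10)
  jp <- junction_profile(site, r)
  expect_equal(nrow(jp[context == "CpG"]), 19L)
  expect_equal(unique(jp[context == "CpG", level]), 0.5)
  # a site with no coverage anywhere contributes nothing
  far <- copy(site)[, position := 90000L]
  jp2 <- junction_profile(rbind(site, far), r)
  expect_equal(max(jp2[context == "CpG", n]), 1L)
})

test_that("group comparison flags planted differences and degenerate input", {
  set.seed(63)
  lv <- rbind(
    data.table(id = paste0("a", 1:50), group = "SE", context = "CpG",
               level = rnorm(50, 0.7, 0.05)),
    data.table(id = paste0("n", 1:50), group = "normal", context = "CpG",
               level = rnorm(50, 0.4, 0.05)))
  cmp <- compare_methylation(lv)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$mean_group, cmp$mean_ref)
  # identical groups -> p = 1
  same <- copy(lv)[, level := 0.5]
  expect_equal(compare_methylation(same)$p, 1)
  # one empty context skipped with warning
  lone <- lv[group == "SE"][1:2][, context := "CHH"]
  expect_warning(compare_methylation(rbind(lv, lone)), "skipped")
})
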