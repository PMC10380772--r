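# toy retained-event table: genes x types x samples assigned at random
random_retained <- function(seed, n_genes = 3L, n_events = 12L,
                            design = toy_design()) {
  set.seed(seed)
  gene_chrom <- setNames(sample(c("chrA01", "chrD01"), n_genes, TRUE),
                         paste0("g", seq_len(n_genes)))
  rbindlist(lapply(seq_len(n_events), function(i) {
    g <- sample(paste0("g", seq_len(n_genes)), 1)
    ty <- sample(c("SE", "RI", "A3SS", "A5SS", "MXE"), 1)
    chrom <- gene_chrom[[g]]
    samples <- sample(design$sample_id, sample(1:4, 1))
    rbindlist(lapply(samples, function(s)
      event_row(event_key = paste0(ty, "|", chrom, "|e", i),
                gene_id = g, event_type = ty, chrom = chrom, sample_id = s)))
  }))
}

test_that("census counts match a brute-force recount of the event list", {
  design <- toy_design()
  ret <- random_retained(21)
  cen <- build_census(ret, design)
  # brute force over the raw list
  expect_equal(cen$totals$n_as_genes, length(unique(ret$gene_id)))
  expect_equal(cen$totals$n_as_events, length(unique(ret$event_key)))
  for (s in unique(ret$sample_id)) {
    sub <- ret[sample_id == s]
    expect_equal(cen$per_sample_genes[sample_id == s, total_genes],
                 length(unique(sub$gene_id)))
    expect_equal(cen$per_sample_events[sample_id == s, total_events],
                 length(unique(sub$event_key)))
    for (ty in unique(sub$event_type))
      expect_equal(cen$per_sample_genes[sample_id == s][[ty]],
                   length(unique(sub[event_type == ty, gene_id])))
  }
  # one gene, one event in one sample
  cen1 <- build_census(event_row(), design)
  expect_equal(cen1$totals$n_as_genes, 1L)
  expect_equal(cen1$totals$n_as_events, 1L)
})

test_that("census is invariant to input row order", {
  design <- toy_design()
  ret <- random_retained(22)
  set.seed(1)
  shuffled <- ret[sample(.N)]
  a <- build_census(ret, design)
  b <- build_census(shuffled, design)
  expect_equal(a$totals, b$totals)
  expect_equal(a$genes[order(gene_id)], b$genes[order(gene_id)])
})

test_that("hotspots require strictly more than the threshold", {
  design <- toy_design()
  ret <- rbindlist(lapply(1:9, function(i)
    event_row(event_key = paste0("SE|chr1|e", i),
              gene_id = if (i <= 5) "g5" else "g4")))
  cen <- build_census(ret, design)
  h <- hotspots(cen)          # g5 has 5 events, g4 has 4
  expect_equal(h$gene_id, "g5")
  expect_warning(empty <- build_census(event_row()[0], design), "zero")
  expect_equal(nrow(hotspots(empty)), 0L)
})

test_that("census summary arithmetic behaves as stated", {
  expect_equal(events_per_gene(6, 3), 2)
  expect_true(is.na(events_per_gene(0, 0)))
  expect_equal(percent_of(1, 4), 25)
  expect_equal(range_ratio(30, 10), 3)
})

test_that("type breakdown equals per-sample proportions", {
  design <- toy_design()
  ret <- rbind(event_row(event_key = "SE|e1"),
               event_row(event_key = "SE|e2"),
               event_row(event_key = "RI|e3", event_type = "RI"),
               event_row(event_key = "RI|e4", event_type = "RI"))
  tb <- type_breakdown(build_census(ret, design))
  expect_equal(sort(tb$per_sample$pct), c(50, 50))
})

test_that("type proportions recover a planted 5-type mixture", {
  set.seed(33)
  design <- toy_design()
  w <- c(SE = 0.35, A3SS = 0.3, RI = 0.15, A5SS = 0.15, MXE = 0.05)
  n <- 2000L
  types <- sample(names(w), n, TRUE, prob = w)
  ret <- event_row()[rep(1L, n)]
  ret[, `:=`(event_key = paste0(types, "|e", seq_len(n)),
             event_type = types)]
  tb <- type_breakdown(build_census(ret, design))
  got <- tb$per_sample[order(event_type), pct] / 100
  exp_w <- w[order(names(w))]
  # within ~4 binomial sd at n = 2000
  expect_true(all(abs(got - exp_w) < 4 * sqrt(exp_w * (1 - exp_w) / n)))
})

test_that("gene type multiplicity equals a brute-force histogram", {
  design <- toy_design()
  ret <- random_retained(23, n_genes = 6L, n_events = 30L)
  mult <- gene_type_multiplicity(build_census(ret, design))
  brute <- table(sapply(split(ret$event_type, ret$gene_id),
                        function(x) length(unique(x))))
  for (k in names(brute))
    expect_equal(mult[n_types == as.integer(k), n_genes],
                 unname(as.integer(brute[k])))
  # a gene with SE and RI only has multiplicity 2
  two <- build_census(rbind(
    event_row(event_key = "SE|x"),
    event_row(event_key = "RI|y", event_type = "RI")), design)
  expect_equal(gene_type_multiplicity(two)$n_types, 2L)
})

test_that("chromosome density equals brute-force interval stabbing", {
  design <- toy_design()
  set.seed(5)
  gm <- data.table(gene_id = paste0("g", 1:40),
                   chrom = sample(c("chrA01", "chrD01"), 40, TRUE),
                   start = sample(1:9000, 40), strand = "+")
  gm[, end := start + sample(200:800, 40)]
  ret <- rbindlist(lapply(1:25, function(i)
    event_row(event_key = paste0("SE|e", i),
              gene_id = sample(gm$gene_id, 1))))
  ret <- merge(ret, gm[, .(gene_id, chrom)], by = "gene_id")[,
    chrom := chrom.y][, c("chrom.x", "chrom.y") := NULL]
  ret[, junc_start := NA_integer_]
  cen <- build_census(ret, design)
  dens <- chromosome_density(cen, gm, window_bp = 1000)
  as_pos <- merge(cen$genes[, .(gene_id)], gm, by = "gene_id")
  for (i in seq_len(nrow(dens$windows))) {
    w <- dens$windows[i]
    brute <- sum(as_pos$chrom == w$chrom &
                   (as_pos$start - 1) >= w$start & (as_pos$start - 1) < w$end)
    expect_equal(w$n_as_genes, brute)
  }
  # all AS genes on one chromosome -> argmax; window larger than chromosome
  one <- copy(ret)[, chrom := "chrA01"]
  gm1 <- copy(gm)[, chrom := "chrA01"]
  d1 <- chromosome_density(build_census(one, design), gm1, window_bp = 1e7)
  expect_equal(d1$argmax_chrom, "chrA01")
  expect_equal(nrow(d1$windows), 1L)
  expect_equal(d1$windows$n_genes, nrow(gm1))
})

test_that("subgenome comparison: identical counts give t = 0, p = 1", {
  design <- toy_design()
  ret <- rbindlist(lapply(design$sample_id, function(s) rbind(
    event_row(event_key = "SE|a", gene_id = "gA", chrom = "chrA01",
              sample_id = s),
    event_row(event_key = "SE|d", gene_id = "gD", chrom = "chrD01",
              sample_id = s))))
  sg <- subgenome_compare(build_census(ret, design))
  expect_equal(unname(sg$t_genes$statistic), 0)
  expect_equal(sg$t_genes$p.value, 1)
  expect_equal(sg$totals[subgenome == "At", n_as_genes],
               sg$totals[subgenome == "Dt", n_as_genes])
})

test_that("subgenome totals restrict to the homoeolog-pair universe", {
  design <- toy_design()
  ret <- rbind(
    event_row(event_key = "SE|a1", gene_id = "gA1", chrom = "chrA01"),
    event_row(event_key = "SE|a2", gene_id = "gA2", chrom = "chrA01"),
    event_row(event_key = "SE|d1", gene_id = "gD1", chrom = "chrD01"))
  pairs <- data.table(gene_a = "gA1", gene_b = "gD1")
  sg <- subgenome_compare(build_census(ret, design), pairs = pairs)
  expect_equal(sg$totals[subgenome == "At", n_as_genes], 1L)
  expect_equal(sg$totals[subgenome == "At", pct_of_universe], 100)
})

test_that("stage sets equal a brute-force power-set count", {
  design <- toy_design()       # groups: ovule_s1, ovule_s2, fiber_s2, fiber_s3
  ret <- rbind(
    # e1: in every group -> conservative
    rbindlist(lapply(design$sample_id, function(s)
      event_row(event_key = "SE|e1", gene_id = "g1", sample_id = s))),
    # e2: one group only -> specific
    event_row(event_key = "SE|e2", gene_id = "g2", sample_id = "s1"),
    # e3: two groups
    event_row(event_key = "SE|e3", gene_id = "g3", sample_id = "s2"),
    event_row(event_key = "SE|e3", gene_id = "g3", sample_id = "s3"))
  ss <- stage_sets(build_census(ret, design))
  expect_equal(ss$events$conservative, "SE|e1")
  expect_equal(ss$events$specific$item, "SE|e2")
  expect_equal(ss$events$n_union,
               sum(ss$events$upset$n))                 # cells sum to union
  got2 <- ss$events$upset[combo == "fiber_s2+ovule_s2", n]
  expect_equal(got2, 1L)
  # brute-force power-set recount
  mem <- split(ss$events$membership$group, ss$events$membership$item)
  brute <- table(vapply(mem, function(g) paste(sort(unique(g)),
                                               collapse = "+"), ""))
  for (cb in names(brute))
    expect_equal(ss$events$upset[combo == cb, n],
                 unname(as.integer(brute[cb])))
})
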