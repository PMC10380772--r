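mk_gene <- function(gene_id, chrom, strand, exons) {
  data.table(gene_id = gene_id, chrom = chrom, strand = strand,
             start = min(exons[, 1]), end = max(exons[, 2]),
             exon_count = nrow(exons),
             exons = list(cbind(start = exons[, 1], end = exons[, 2])),
             gene_length = max(exons[, 2]) - min(exons[, 1]) + 1L,
             intron_count = nrow(exons) - 1L)
}

test_that("gene GC and span match brute-force character counting", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCNNATGC"))
  gm <- mk_gene("g1", "chr1", "+", cbind(1L, 10L))
  ft <- gene_features(gm, genome)
  expect_equal(ft$gc_content, 0.5)     # N excluded from the denominator
  expect_equal(ft$gene_length, 10L)

  # 50 random genes vs the character-count oracle, both strands
  set.seed(31)
  seqs <- random_dna(20000, seed = 31)
  genome <- Biostrings::DNAStringSet(c(chrX = seqs))
  gms <- rbindlist(lapply(1:50, function(i) {
    s <- sample(1:19000, 1); e <- s + sample(50:900, 1)
    mk_gene(paste0("g", i), "chrX", sample(c("+", "-"), 1),
            cbind(s, e))
  }))
  ft <- gene_features(gms, genome)
  oracle <- sapply(1:50, function(i)
    gc_by_chars(substr(seqs, gms$start[i], gms$end[i])))
  expect_equal(ft$gc_content, oracle)
  # strand symmetry: span and GC ignore strand
  flipped <- copy(gms)[, strand := ifelse(strand == "+", "-", "+")]
  expect_equal(gene_features(flipped, genome)$gc_content, ft$gc_content)
})

test_that("missing chromosome raises an error naming genes", {
  gm <- mk_gene("gZ", "chrMissing", "+", cbind(1L, 10L))
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_error(gene_features(gm, genome), "chrMissing.*gZ")
})

test_that("AS-group labels come from retained events", {
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(2000)))
  gm <- rbind(mk_gene("gSE", "chr1", "+", cbind(c(1L, 301L), c(200L, 600L))),
              mk_gene("gBoth", "chr1", "+", cbind(701L, 900L)),
              mk_gene("gNone", "chr1", "+", cbind(1001L, 1200L)),
              mk_gene("gOther", "chr1", "+", cbind(1301L, 1500L)))
  ret <- rbind(event_row(gene_id = "gSE"),
               event_row(gene_id = "gBoth"),
               event_row(gene_id = "gBoth", event_type = "RI",
                         event_key = "RI|x"),
               event_row(gene_id = "gOther", event_type = "MXE",
                         event_key = "MXE|x"))
  ft <- gene_features(gm, genome, ret)
  expect_equal(ft[gene_id == "gSE", as_group], "SE")
  expect_equal(ft[gene_id == "gBoth", as_group], "SE+RI")
  expect_true(ft[gene_id == "gBoth", group_SE & group_RI])
  expect_equal(ft[gene_id == "gNone", as_group], "normal")
  expect_equal(ft[gene_id == "gOther", as_group], "other")
})

test_that("group comparison detects a planted GC shift and handles edge cases", {
  set.seed(32)
  n <- 200L
  ft <- data.table(
    gene_id = paste0("g", 1:(2 * n)),
    gene_length = c(rnorm(n, 4400, 500), rnorm(n, 1900, 400)),
    exon_count = c(rpois(n, 9), rpois(n, 3)),
    gc_content = c(rnorm(n, 0.36, 0.03), rnorm(n, 0.40, 0.03)),
    group_SE = rep(c(TRUE, FALSE), each = n),
    group_RI = FALSE,
    as_group = rep(c("SE", "normal"), each = n))
  suppressWarnings(cmp <- compare_groups(ft))
  gc_test <- cmp$tests[group == "SE" & feature == "gc_content"]
  expect_lt(gc_test$p, 0.001)
  expect_lt(gc_test$mean_group, gc_test$mean_normal)

  # identical groups -> p = 1, zero mean difference
  ft2 <- copy(ft)[, `:=`(gene_length = 100, exon_count = 3,
                         gc_content = 0.4)]
  suppressWarnings(cmp2 <- compare_groups(ft2))
  expect_true(all(cmp2$tests[group == "SE", p] == 1))
  expect_equal(cmp2$tests[group == "SE", mean_group - mean_normal],
               rep(0, 3))

  # single-member group skipped with a warning
  ft3 <- rbind(ft[as_group == "normal"], ft[as_group == "SE"][1])
  suppressWarnings(expect_warning(compare_groups(ft3), "degenerate"))
})

test_that("RI events give one donor and one acceptor; SE gives A and B", {
  gm <- mk_gene("gN", "chr1", "+", cbind(1L, 100L))
  ri <- event_row(gene_id = "gRI", event_type = "RI",
                  junc_start = 500L, junc_end = 600L, event_key = "RI|x")
  s <- extract_junctions(ri, gm)
  expect_equal(nrow(s[source != "normal"]), 2L)
  expect_setequal(s[source != "normal", side], c("donor", "acceptor"))
  expect_equal(s[source == "RI_C", position], 500L)   # first intron base
  expect_equal(s[source == "RI_D", position], 599L)   # last intron base

  se <- event_row(junc_start = 300L, junc_end = 400L)
  s2 <- extract_junctions(se, mk_gene("gN", "chr1", "+", cbind(1L, 100L)))
  expect_equal(s2[source == "SE_A", position], 299L)
  expect_equal(s2[source == "SE_B", position], 400L)
  expect_equal(s2[source == "SE_A", side], "acceptor")
  expect_equal(s2[source == "SE_B", side], "donor")
})

test_that("normal multi-exon genes contribute every internal boundary", {
  gm <- rbind(
    mk_gene("g3ex", "chr1", "+",
            cbind(c(101L, 301L, 501L), c(200L, 400L, 600L))),
    mk_gene("g1ex", "chr1", "+", cbind(701L, 800L)))
  s <- extract_junctions(event_row(gene_id = "gElse")[0], gm)
  expect_equal(nrow(s), 4L)                       # 2 introns x 2 boundaries
  expect_equal(sum(s$side == "donor"), 2L)
  expect_equal(sum(s$side == "acceptor"), 2L)
  expect_false("g1ex" %in% s$gene_id)             # single-exon genes excluded
})

test_that("strand flip swaps donor/acceptor labels consistently", {
  exons <- cbind(c(101L, 301L), c(200L, 400L))
  plus <- extract_junctions(event_row()[0], mk_gene("g", "chr1", "+", exons))
  minus <- extract_junctions(event_row()[0], mk_gene("g", "chr1", "-", exons))
  expect_equal(plus$position, minus$position)
  # the genomic-left boundary is a donor on +, an acceptor on -
  expect_equal(plus[intron_side == "right", side], "donor")
  expect_equal(minus[intron_side == "right", side], "acceptor")
})

test_that("junction windows: GC, boundaries and disjointness", {
  # site at 0-based position 25 on a 51 bp contig: full window = whole contig
  contig <- random_dna(51, seed = 40)
  genome <- Biostrings::DNAStringSet(c(c51 = contig))
  site <- data.table(chrom = "c51", strand = "+", position = 25L,
                     side = "donor", intron_side = "right",
                     source = "normal", gene_id = "g")
  w <- junction_gc(site, genome)
  expect_equal(w$gc_full, gc_by_chars(contig))
  # all-G contig -> every window GC = 1
  gg <- Biostrings::DNAStringSet(c(cG = strrep("G", 120)))
  wg <- junction_gc(copy(site)[, chrom := "cG"][, position := 60L], gg)
  expect_equal(unlist(wg[, .(gc_full, gc_exon, gc_intron)]),
               c(gc_full = 1, gc_exon = 1, gc_intron = 1))
  # too close to the contig end -> excluded and counted
  near <- copy(site)[, position := 10L]
  we <- junction_gc(near, genome)
  expect_equal(nrow(we), 0L)
  expect_equal(attr(we, "n_excluded"), 1L)
})

test_that("window GC equals brute-force string counting on random sites", {
  seqs <- random_dna(60000, seed = 41)
  genome <- Biostrings::DNAStringSet(c(chrX = seqs))
  set.seed(42)
  n <- 1000L
  sites <- data.table(chrom = "chrX", strand = sample(c("+", "-"), n, TRUE),
                      position = sample(30:59950, n),
                      side = "donor",
                      intron_side = sample(c("left", "right"), n, TRUE),
                      source = "normal", gene_id = "g")
  w <- junction_gc(sites, genome)
  for (i in sample(nrow(w), 50)) {
    P <- w$position[i] + 1L
    expect_equal(w$gc_full[i], gc_by_chars(substr(seqs, P - 25, P + 25)))
    if (w$intron_side[i] == "right") {
      expect_equal(w$gc_intron[i], gc_by_chars(substr(seqs, P, P + 19)))
      expect_equal(w$gc_exon[i], gc_by_chars(substr(seqs, P - 20, P - 1)))
    } else {
      expect_equal(w$gc_intron[i], gc_by_chars(substr(seqs, P - 19, P)))
      expect_equal(w$gc_exon[i], gc_by_chars(substr(seqs, P + 1, P + 20)))
    }
  }
})

test_that("GC values survive reverse-complementing the genome", {
  seqs <- random_dna(5000, seed = 43)
  genome <- Biostrings::DNAStringSet(c(chrX = seqs))
  rc <- Biostrings::reverseComplement(genome)
  L <- nchar(seqs)
  set.seed(44)
  sites <- data.table(chrom = "chrX", strand = "+",
                      position = sample(100:4900, 40), side = "donor",
                      intron_side = "right", source = "normal", gene_id = "g")
  # mirrored site: 0-based position maps to L - 1 - position; intron side flips
  mirrored <- copy(sites)[, `:=`(position = L - 1L - position,
                                 strand = "-", intron_side = "left")]
  w1 <- junction_gc(sites, genome)
  w2 <- junction_gc(mirrored, rc)
  expect_equal(w2[order(-position), gc_full], w1[order(position), gc_full])
  expect_equal(w2[order(-position), gc_intron],
               w1[order(position), gc_intron])
  expect_equal(w2[order(-position), gc_exon], w1[order(position), gc_exon])
})

test_that("planted intron-side GC elevation is detected (I' > I)", {
  set.seed(45)
  # AS intron windows drawn GC-rich, normal baseline
  base <- random_dna(200000, seed = 46)
  genome <- Biostrings::DNAStringSet(c(chrX = base))
  pos <- seq(1000, 190000, by = 600)
  n <- length(pos)
  grp <- rep(c("RI_C", "normal"), length.out = n)
  v <- strsplit(base, "")[[1]]
  for (i in which(grp == "RI_C")) {
    P <- pos[i] + 1L
    idx <- P:(P + 19L)       # intron-side window (intron right)
    v[idx] <- sample(c("G", "C", "A", "T"), 20, TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.2))
  }
  genome <- Biostrings::DNAStringSet(c(chrX = paste(v, collapse = "")))
  sites <- data.table(chrom = "chrX", strand = "+", position = pos,
                      side = "donor", intron_side = "right",
                      source = grp, gene_id = "g")
  cmp <- compare_junction_gc(junction_gc(sites, genome))
  ri_i <- cmp[source == "RI_C" & window == "intron"]
  expect_lt(ri_i$p, 0.01)
  expect_gt(ri_i$mean_as, ri_i$mean_normal)
})
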