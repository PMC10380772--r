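library(data.table)

# one long-format event row (defaults give a retained SE event)
event_row <- function(event_key = "SE|chr1|+|100:200:50:90:250:300",
                      gene_id = "g1", event_type = "SE", chrom = "chr1",
                      strand = "+", junc_start = 100L, junc_end = 200L,
                      sample_id = "s1", ijc = 20, sjc = 10,
                      inc_form_len = 2, skip_form_len = 1) {
  dt <- data.table(event_key = event_key, event_id = event_key,
                   gene_id = gene_id, event_type = event_type, chrom = chrom,
                   strand = strand, anchors = sub("^.*\\|", "", event_key),
                   junc_start = junc_start, junc_end = junc_end,
                   sample_id = sample_id, ijc = ijc, sjc = sjc,
                   inc_form_len = inc_form_len, skip_form_len = skip_form_len)
  dt[, psi := compute_psi(ijc, sjc, inc_form_len, skip_form_len)]
  dt
}

# write a minimal rMATS-style SE table; counts given as character
# (comma-separated replicates allowed)
write_se_table <- function(path, ijc = "5,5", sjc = "3,2", n = length(ijc),
                           gene = "gX", col_order = NULL) {
  dt <- data.table(
    ID = seq_len(n), GeneID = rep(gene, n), geneSymbol = rep(gene, n),
    chr = "chr1", strand = "+",
    exonStart_0base = 100L + seq_len(n), exonEnd = 200L + seq_len(n),
    upstreamES = 50L, upstreamEE = 90L, downstreamES = 250L,
    downstreamEE = 300L,
    IJC_SAMPLE_1 = ijc, SJC_SAMPLE_1 = sjc,
    IncFormLen = 2L, SkipFormLen = 1L)
  if (!is.null(col_order)) dt <- dt[, col_order, with = FALSE]
  fwrite(dt, path, sep = "\t", quote = FALSE)
  path
}

toy_design <- function() {
  read_design(data.table(
    sample_id = c("s1", "s2", "s3", "s4"),
    tissue = c("ovule", "ovule", "fiber", "fiber"),
    dpa = c(0L, 15L, 10L, 25L)))
}

# deterministic random DNA string
random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force GC by character counting (independent oracle)
gc_by_chars <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  v <- v[v %in% c("A", "C", "G", "T")]
  sum(v %in% c("C", "G")) / length(v)
}

# small synthetic dataset shared by cheaper tests (built once per run)
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(seed = 11, n_normal = 40L, n_se = 15L, n_ri = 15L)
    .sim_cache$small <- list(cfg = cfg, sim = make_genome_and_annotation(cfg))
  }
  .sim_cache$small
}

# the default-scale dataset used by planted-effect recovery (built once)
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    cfg <- sim_config(seed = 101)
    dir <- file.path(tempdir(), "spliceCensus_default_sim")
    obj <- simulate_dataset(cfg, dir)
    .sim_cache$default <- list(cfg = cfg, dir = dir, obj = obj)
  }
  .sim_cache$default
}
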