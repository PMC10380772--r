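# Readers and writers for every external format the pipeline touches.
# All downstream modules consume only the tables built here:
#   * events:      long table, one row per (event, sample) with junction counts
#   * gene models: one row per gene with a merged-exon list column
#   * design:      sample -> (tissue, dpa, stage)
#   * methylation: per-cytosine calls
#   * blast:       12-column tabular hits

# rMATS JC coordinate columns per event type. All *_0base columns are 0-based;
# the remaining coordinates are exclusive ends of half-open intervals, so the
# whole tuple is usable as-is in 0-based half-open convention.
RMATS_COORD_COLS <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart", "2ndExonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE")
)

# sum "5,3,0"-style replicate count fields; returns NA for malformed fields
sum_replicates <- function(x) {
  vapply(strsplit(as.character(x), ","), function(v) {
    n <- suppressWarnings(as.numeric(trimws(v)))
    if (anyNA(n)) return(NA_real_)
    sum(n)
  }, numeric(1))
}

#' Read one rMATS-style junction-count table
#'
#' Parses a tab-separated rMATS "JC" table for a single event type into the
#' long per-(event, sample) representation used by the whole pipeline.
#' Comma-separated replicate counts within a sample column are summed (junction
#' counts are additive); PSI is computed from the summed counts with the
#' form-length-normalized rMATS formula (see [compute_psi()]).
#'
#' @param path path to the tab-separated table (header required).
#' @param event_type one of `"SE"`, `"A5SS"`, `"A3SS"`, `"MXE"`, `"RI"`.
#' @param sample_ids names for the samples present in the table. Defaults to
#'   the `SAMPLE_1`/`SAMPLE_2` suffixes found in the header; give one name per
#'   IJC/SJC column pair present.
#' @return a `data.table` with one row per event and sample: `event_key`
#'   (identity across samples: type + chrom + strand + anchors), `event_id`,
#'   `gene_id`, `event_type`, `chrom`, `strand`, `anchors`, `junc_start`,
#'   `junc_end` (alternative segment for SE, retained intron for RI, `NA`
#'   otherwise; 0-based half-open), `sample_id`, `ijc`, `sjc`,
#'   `inc_form_len`, `skip_form_len`, `psi`.
#' @export
read_rmats_table <- function(path, event_type, sample_ids = NULL) {
  event_type <- match.arg(event_type, AS_EVENT_TYPES)
  # read everything as character: replicate count fields like "5,3" must not
  # be auto-parsed as decimals
  dt <- fread(path, sep = "\t", header = TRUE, check.names = FALSE,
              colClasses = "character")
  coord_cols <- RMATS_COORD_COLS[[event_type]]
  need <- c("ID", "GeneID", "chr", "strand", coord_cols,
            "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncFormLen", "SkipFormLen")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stopf("%s: missing mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) return(empty_events_table())

  samples_present <- c("SAMPLE_1",
                       if (all(c("IJC_SAMPLE_2", "SJC_SAMPLE_2") %in% names(dt)))
                         "SAMPLE_2")
  if (is.null(sample_ids)) sample_ids <- samples_present
  if (length(sample_ids) != length(samples_present))
    stopf("%s: %d sample column pair(s) present but %d sample_ids supplied",
          path, length(samples_present), length(sample_ids))

  anchors <- do.call(paste, c(lapply(coord_cols, function(cc) dt[[cc]]),
                              sep = ":"))
  per_sample <- lapply(seq_along(samples_present), function(i) {
    ijc <- sum_replicates(dt[[paste0("IJC_", samples_present[i])]])
    sjc <- sum_replicates(dt[[paste0("SJC_", samples_present[i])]])
    bad <- which(is.na(ijc) | is.na(sjc))
    if (length(bad))
      stopf("%s: malformed junction counts at data line(s) %s",
            path, paste(bad + 1L, collapse = ", "))
    neg <- which(ijc < 0 | sjc < 0)
    if (length(neg))
      stopf("%s: negative junction count at data line(s) %s",
            path, paste(neg + 1L, collapse = ", "))
    data.table(
      event_key = paste(event_type, dt$chr, dt$strand, anchors, sep = "|"),
      event_id = as.character(dt$ID),
      gene_id = dt$GeneID,
      event_type = event_type,
      chrom = dt$chr,
      strand = dt$strand,
      anchors = anchors,
      junc_start = switch(event_type,
                          SE = as.integer(dt[["exonStart_0base"]]),
                          RI = as.integer(dt[["upstreamEE"]]),
                          rep(NA_integer_, nrow(dt))),
      junc_end = switch(event_type,
                        SE = as.integer(dt[["exonEnd"]]),
                        RI = as.integer(dt[["downstreamES"]]),
                        rep(NA_integer_, nrow(dt))),
      sample_id = sample_ids[i],
      ijc = ijc,
      sjc = sjc,
      inc_form_len = as.numeric(dt$IncFormLen),
      skip_form_len = as.numeric(dt$SkipFormLen)
    )
  })
  ev <- rbindlist(per_sample)
  if (any(ev$inc_form_len <= 0) || any(ev$skip_form_len <= 0))
    stopf("%s: non-positive form length", path)
  ev[, psi := compute_psi(ijc, sjc, inc_form_len, skip_form_len)]
  ev[]
}

empty_events_table <- function() {
  data.table(event_key = character(), event_id = character(),
             gene_id = character(), event_type = character(),
             chrom = character(), strand = character(), anchors = character(),
             junc_start = integer(), junc_end = integer(),
             sample_id = character(), ijc = numeric(), sjc = numeric(),
             inc_form_len = numeric(), skip_form_len = numeric(),
             psi = numeric())
}

#' Read a directory of per-sample rMATS-style tables
#'
#' Expects files named `<sample_id>.<TYPE>.txt` (one event type per file),
#' each holding that sample's junction counts in `SAMPLE_1` columns.
#'
#' @param dir directory containing the tables.
#' @param design optional design table; when given, only files whose sample id
#'   appears in the design are read and an error is raised if a design sample
#'   has no tables at all.
#' @return combined long events `data.table` (see [read_rmats_table()]).
#' @export
read_events_dir <- function(dir, design = NULL) {
  files <- list.files(dir, pattern = "\\.(SE|A5SS|A3SS|MXE|RI)\\.txt$",
                      full.names = TRUE)
  if (!length(files)) stopf("no rMATS-style tables found under %s", dir)
  meta <- data.table(
    path = files,
    base = basename(files)
  )
  meta[, event_type := sub("^.*\\.(SE|A5SS|A3SS|MXE|RI)\\.txt$", "\\1", base)]
  meta[, sample_id := sub("\\.(SE|A5SS|A3SS|MXE|RI)\\.txt$", "", base)]
  if (!is.null(design)) {
    meta <- meta[sample_id %in% design$sample_id]
    absent <- setdiff(design$sample_id, meta$sample_id)
    if (length(absent))
      stopf("design sample(s) with no event tables: %s",
            paste(absent, collapse = ", "))
  }
  rbindlist(lapply(seq_len(nrow(meta)), function(i)
    read_rmats_table(meta$path[i], meta$event_type[i], meta$sample_id[i])))
}

#' Read gene models from a GTF file
#'
#' Builds one gene model per `gene_id` from the exon features of a GTF
#' (1-based inclusive coordinates at the file boundary). Exons are merged
#' (overlapping/duplicate exons collapse) and sorted; gene length is the
#' genomic span.
#'
#' @param path GTF file.
#' @return `data.table` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive span), `gene_length`, `exon_count`,
#'   `intron_count`, and list column `exons` (each a two-column integer matrix
#'   of merged 1-based inclusive exon intervals).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == "exon"]
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  no_gene <- is.na(gid) | gid == ""
  if (any(no_gene)) {
    warnf("skipping %d exon feature(s) without gene_id", sum(no_gene))
    gr <- gr[!no_gene]
    gid <- gid[!no_gene]
  }
  if (!length(gr)) return(empty_gene_models())
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, gid))
  glist <- as.list(grl)
  gene_ids <- names(glist)
  rows <- lapply(seq_along(glist), function(i) {
    g <- glist[[i]]
    data.table(
      gene_id = gene_ids[i],
      chrom = as.character(GenomicRanges::seqnames(g))[1],
      strand = as.character(GenomicRanges::strand(g))[1],
      start = min(GenomicRanges::start(g)),
      end = max(GenomicRanges::end(g)),
      exon_count = length(g),
      exons = list(cbind(start = GenomicRanges::start(g),
                         end = GenomicRanges::end(g)))
    )
  })
  gm <- rbindlist(rows)
  gm[, gene_length := end - start + 1L]
  gm[, intron_count := exon_count - 1L]
  setkey(gm, gene_id)
  gm[]
}

empty_gene_models <- function() {
  data.table(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), exon_count = integer(),
             exons = list(), gene_length = integer(), intron_count = integer())
}

#' Map days post-anthesis to a developmental stage
#'
#' Stage 1 (fiber initiation and primary elongation): -3 to 5 DPA; stage 2
#' (fiber elongation): 10 to 15 DPA; stage 3 (secondary wall thickening):
#' 20 to 25 DPA.
#'
#' @param dpa integer vector of days post-anthesis.
#' @return integer stage in 1..3; error for DPA outside the sampled design.
#' @export
stage_from_dpa <- function(dpa) {
  stage <- rep(NA_integer_, length(dpa))
  stage[dpa >= -3 & dpa <= 5] <- 1L
  stage[dpa >= 10 & dpa <= 15] <- 2L
  stage[dpa >= 20 & dpa <= 25] <- 3L
  if (anyNA(stage))
    stopf("DPA value(s) outside the sampled range: %s",
          paste(unique(dpa[is.na(stage)]), collapse = ", "))
  stage
}

VALID_DPA <- c(-3L, 0L, 1L, 3L, 5L, 10L, 15L, 20L, 25L)

#' Read (and validate) a sample design table
#'
#' Tab-separated with columns `sample_id`, `tissue` (`ovule`/`fiber`), `dpa`.
#' The stage is derived from DPA. Fibers exist only from 10 DPA on, so fiber
#' rows with earlier DPA are rejected, as is any DPA not in the sampled grid
#' (-3, 0, 1, 3, 5, 10, 15, 20, 25).
#'
#' @param path TSV file, or a `data.frame` already in memory.
#' @return `data.table` with `sample_id`, `tissue`, `dpa`, `stage`, `group`
#'   (tissue + stage label, e.g. `"ovule_s1"`).
#' @export
read_design <- function(path) {
  d <- if (is.data.frame(path)) as.data.table(path) else fread(path, sep = "\t")
  need <- c("sample_id", "tissue", "dpa")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stopf("design: missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (!all(d$tissue %in% c("ovule", "fiber")))
    stopf("design: tissue must be 'ovule' or 'fiber'")
  bad_dpa <- setdiff(d$dpa, VALID_DPA)
  if (length(bad_dpa))
    stopf("design: DPA value(s) outside the sampled grid: %s",
          paste(bad_dpa, collapse = ", "))
  if (any(d$tissue == "fiber" & d$dpa < 10))
    stopf("design: fiber samples exist only from 10 DPA on")
  if (anyDuplicated(d$sample_id))
    stopf("design: duplicated sample_id")
  d <- d[, .(sample_id = as.character(sample_id), tissue, dpa = as.integer(dpa))]
  d[, stage := stage_from_dpa(dpa)]
  d[, group := paste0(tissue, "_s", stage)]
  d[]
}

#' Read per-cytosine methylation calls (native 6-column TSV)
#'
#' Columns: `chrom`, `pos` (1-based), `strand`, `context`
#' (`CpG`/`CHG`/`CHH`), `n_meth`, `n_total`.
#'
#' @param path TSV file with header.
#' @return validated `data.table` keyed by (chrom, pos).
#' @export
read_methylation <- function(path) {
  m <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stopf("methylation: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!all(m$context %in% METH_CONTEXTS))
    stopf("methylation: context must be one of %s",
          paste(METH_CONTEXTS, collapse = "/"))
  bad <- which(m$n_meth < 0 | m$n_total < m$n_meth)
  if (length(bad))
    stopf("methylation: 0 <= n_meth <= n_total violated at data line(s) %s",
          paste(bad + 1L, collapse = ", "))
  setkey(m, chrom, pos)
  m[]
}

#' Read CGmap-style methylation calls (adapter)
#'
#' Thin adapter for the CGmap dialect emitted by common bisulfite callers
#' (columns: chrom, nucleotide, pos, context, dinucleotide, level, n_meth,
#' n_total). Converted to the native 6-column representation; context `CG`
#' maps to `CpG`, the watson/crick strand is inferred from the nucleotide
#' column (C = +, G = -).
#'
#' @param path CGmap file (no header).
#' @return `data.table` as from [read_methylation()].
#' @export
read_cgmap <- function(path) {
  cg <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "nucleotide", "pos", "context",
                            "dinucleotide", "level", "n_meth", "n_total"))
  m <- cg[, .(chrom, pos = as.integer(pos),
              strand = ifelse(nucleotide == "C", "+", "-"),
              context = ifelse(context == "CG", "CpG", context),
              n_meth = as.integer(n_meth), n_total = as.integer(n_total))]
  if (!all(m$context %in% METH_CONTEXTS))
    stopf("CGmap: unrecognized context value(s)")
  setkey(m, chrom, pos)
  m[]
}

BLAST6_COLS <- c("query_id", "subject_id", "identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' @param path 12-column tab-separated BLAST output, no header.
#' @return `data.table` with the standard outfmt-6 columns named
#'   `query_id`, `subject_id`, `identity`, ..., `evalue`, `bitscore`.
#' @export
read_blast <- function(path) {
  b <- fread(path, sep = "\t", header = FALSE)
  if (ncol(b) != 12L)
    stopf("BLAST table must have 12 columns (outfmt 6), found %d", ncol(b))
  setnames(b, BLAST6_COLS)
  if (any(b$bitscore < 0) || any(b$evalue < 0))
    stopf("BLAST table: negative bitscore or e-value")
  b[]
}

#' Write pipeline tables as TSV
#'
#' Plain writers so that every parsed table round-trips: `write_events_tsv()`
#' pairs with `fread`-based reread via [read_events_tsv()], and the design,
#' methylation and BLAST writers pair with their readers.
#'
#' @param x table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("event_id", "gene_id",
                                              "sample_id")))
  ev[]
}

#' @rdname write_events_tsv
#' @export
write_methylation_tsv <- function(x, path) {
  fwrite(x[, .(chrom, pos, strand, context, n_meth, n_total)], path,
         sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_blast_tsv <- function(x, path) {
  fwrite(x[, BLAST6_COLS, with = FALSE], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_design_tsv <- function(x, path) {
  fwrite(x[, .(sample_id, tissue, dpa)], path, sep = "\t", quote = FALSE)
  invisible(path)
}
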