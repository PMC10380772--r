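# TPM normalization, the splicing-factor expression panel, and
# hypergeometric over-representation enrichment.

#' TPM normalization of a counts matrix
#'
#' \deqn{TPM_g = 10^6 \frac{c_g / l_g}{\sum_h c_h / l_h}}
#' with effective length \eqn{l_g} = the sum of the gene's merged exon
#' lengths (standard TPM semantics; not the genomic span). Genes with
#' non-positive or missing length are excluded with a warning. Every TPM
#' column sums to 1e6 unless the column has zero counts everywhere.
#'
#' @param counts gene x sample numeric matrix of raw counts (rownames =
#'   gene ids).
#' @param effective_lengths named numeric vector of effective lengths, or a
#'   gene-models table from [read_gtf()] (merged exon lengths are derived).
#' @return list with `tpm` (matrix, same shape minus excluded genes),
#'   `counts`, `effective_length` (named vector), `excluded` (gene ids).
#' @export
tpm_normalize <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  if (is.data.frame(effective_lengths) || is.list(effective_lengths) &&
      !is.null(effective_lengths$exons)) {
    gm <- as.data.table(effective_lengths)
    effective_lengths <- stats::setNames(
      vapply(gm$exons, function(ex) sum(ex[, "end"] - ex[, "start"] + 1),
             numeric(1)),
      gm$gene_id)
  }
  len <- effective_lengths[rownames(counts)]
  bad <- is.na(len) | len <= 0
  if (any(bad)) {
    warnf("excluding %d gene(s) with missing or non-positive effective length",
          sum(bad))
    counts <- counts[!bad, , drop = FALSE]
    len <- len[!bad]
  }
  rate <- counts / len
  denom <- colSums(rate)
  zero_cols <- denom == 0
  if (any(zero_cols)) warnf("%d all-zero sample column(s); TPM left at 0",
                            sum(zero_cols))
  denom[zero_cols] <- 1
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  list(tpm = tpm, counts = counts, effective_length = len,
       excluded = names(bad)[bad] %||% character())
}

#' Expression panel for a gene set (heatmap matrix + fold-change flags)
#'
#' Extracts the given genes from a TPM matrix, row-z-scores them over the
#' samples ordered by the design (tissue, then DPA), and flags descriptive
#' fold changes between two sample groups at |log2FC| >= `lfc_cutoff`,
#' computed on group-mean TPM with a pseudocount of 1. This is a descriptive
#' summary, not a differential-expression test.
#'
#' @param tpm gene x sample TPM matrix.
#' @param genes character vector of panel genes.
#' @param design design table ([read_design()]); columns order the panel.
#' @param group_a,group_b character vectors of sample ids to contrast
#'   (optional; no flags when absent).
#' @param lfc_cutoff |log2 fold change| threshold (default 1).
#' @param pseudocount added to group-mean TPM before the ratio (default 1).
#' @return list with `z` (row-z-scored matrix; constant rows give 0),
#'   `tpm` (panel TPM), `missing` (requested genes absent from the matrix),
#'   and `flags` (gene, mean_a, mean_b, log2fc, flagged, direction) when the
#'   two groups are given.
#' @export
expression_panel <- function(tpm, genes, design = NULL,
                             group_a = NULL, group_b = NULL,
                             lfc_cutoff = 1, pseudocount = 1) {
  genes <- unique(as.character(genes))
  missing_genes <- setdiff(genes, rownames(tpm))
  present <- intersect(genes, rownames(tpm))
  sub <- tpm[present, , drop = FALSE]
  if (!is.null(design)) {
    d <- as.data.table(design)
    setorder(d, tissue, dpa)
    ord <- intersect(d$sample_id, colnames(sub))
    sub <- sub[, ord, drop = FALSE]
  }
  z <- t(apply(sub, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(sub)
  flags <- NULL
  if (!is.null(group_a) && !is.null(group_b)) {
    ma <- rowMeans(sub[, intersect(group_a, colnames(sub)), drop = FALSE])
    mb <- rowMeans(sub[, intersect(group_b, colnames(sub)), drop = FALSE])
    lfc <- log2((ma + pseudocount) / (mb + pseudocount))
    flags <- data.table(gene_id = rownames(sub), mean_a = ma, mean_b = mb,
                        log2fc = lfc, flagged = abs(lfc) >= lfc_cutoff,
                        direction = ifelse(lfc >= 0, "up", "down"))
  }
  list(z = z, tpm = sub, missing = missing_genes, flags = flags)
}

#' Hypergeometric over-representation enrichment
#'
#' Upper-tail hypergeometric test per term: with `N` background genes, `K`
#' of them in the term, `n` selected genes and `k` selected genes in the
#' term, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Benjamini-
#' Hochberg adjustment across the tested terms. Terms with no background
#' gene are skipped.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   `background`).
#' @param background character vector of universe genes.
#' @param term_map two-column table (`term`, `gene`) or a named list of gene
#'   vectors.
#' @return `data.table`: `term`, `k`, `K`, `n`, `N`, `p`, `q`, ordered by
#'   increasing `p`.
#' @export
enrich <- function(selected, background, term_map) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  if (length(setdiff(selected, background)))
    stopf("selected genes must be a subset of the background")
  if (is.list(term_map) && !is.data.frame(term_map)) {
    term_map <- rbindlist(lapply(names(term_map), function(t)
      data.table(term = t, gene = term_map[[t]])))
  }
  tm <- unique(as.data.table(term_map)[, .(term, gene)])
  tm <- tm[gene %in% background]
  if (nrow(tm) == 0L) return(data.table(term = character(), k = integer(),
                                        K = integer(), n = integer(),
                                        N = integer(), p = numeric(),
                                        q = numeric()))
  N <- length(background)
  n <- length(selected)
  res <- tm[, .(K = .N, k = sum(gene %in% selected)), by = term]
  res[, `:=`(n = n, N = N)]
  res[, p := stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)]
  res[, q := stats::p.adjust(p, method = "BH")]
  setorder(res, p, term)
  res[, .(term, k, K, n, N, p, q)]
}
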