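# Gene-level sequence features of SE/RI/normal gene groups and the GC
# microenvironment of splice junctions.
#
# Junction coordinate convention: a site is stored as the 0-based coordinate
# of the intronic base adjacent to the exon/intron boundary, together with
# the genomic side the intron lies on. The 51 bp window is the site +/- 25 bp;
# the exon-side and intron-side 20 bp windows are the bases immediately
# adjacent to the boundary (adjacency to the junction is the mechanistically
# relevant placement; both widths are configurable).

# GC fraction of a DNAStringSet, case-insensitive, N excluded from denominator
gc_fraction <- function(seqs) {
  fr <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(fr)
  out <- (fr[, "C"] + fr[, "G"]) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Gene-level sequence features with AS-group labels
#'
#' Computes, per gene model, the genomic span length, merged exon count and
#' GC content of the genomic span (introns included; N bases excluded from
#' the denominator), and labels each gene by the AS events it hosts: `SE`
#' and/or `RI` membership from the retained events, `normal` when the gene
#' has no retained event of any type in any sample, `other` when it has
#' events but neither SE nor RI.
#'
#' @param gene_models gene models from [read_gtf()].
#' @param genome a `DNAStringSet` (or path to a FASTA file) with every gene's
#'   chromosome present.
#' @param retained retained events table ([filter_events()]); `NULL` labels
#'   every gene `normal`.
#' @return `data.table`: `gene_id`, `chrom`, `strand`, `gene_length`,
#'   `exon_count`, `intron_count`, `gc_content`, logical `group_SE`,
#'   `group_RI`, and `as_group` in `{SE, RI, SE+RI, other, normal}`.
#' @export
gene_features <- function(gene_models, genome, retained = NULL) {
  gm <- as.data.table(gene_models)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  absent <- setdiff(unique(gm$chrom), names(genome))
  if (length(absent))
    stopf("chromosome(s) absent from FASTA: %s (genes: %s)",
          paste(absent, collapse = ", "),
          paste(head(gm[chrom %in% absent, gene_id], 5), collapse = ", "))
  gc <- rep(NA_real_, nrow(gm))
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    at <- IRanges::IRanges(start = gm$start[idx], end = gm$end[idx])
    gc[idx] <- gc_fraction(Biostrings::extractAt(genome[[ch]], at))
  }
  feats <- gm[, .(gene_id, chrom, strand, gene_length, exon_count,
                  intron_count)]
  feats[, gc_content := gc]
  if (is.null(retained) || nrow(retained) == 0L) {
    feats[, `:=`(group_SE = FALSE, group_RI = FALSE, as_group = "normal")]
    return(feats[])
  }
  ev <- as.data.table(retained)
  se_genes <- unique(ev[event_type == "SE", gene_id])
  ri_genes <- unique(ev[event_type == "RI", gene_id])
  any_genes <- unique(ev$gene_id)
  feats[, group_SE := gene_id %in% se_genes]
  feats[, group_RI := gene_id %in% ri_genes]
  feats[, as_group := ifelse(!(gene_id %in% any_genes), "normal",
                       ifelse(group_SE & group_RI, "SE+RI",
                        ifelse(group_SE, "SE",
                         ifelse(group_RI, "RI", "other"))))]
  feats[]
}

#' Compare gene features between AS groups and the normal group
#'
#' Group means/sd/n for gene length, exon count and GC content of the SE, RI
#' and normal groups (a gene hosting both SE and RI events contributes to
#' both AS groups), with two-sided t-tests of each AS group against normal.
#'
#' @param features table from [gene_features()].
#' @param welch use Welch's t-test instead of the pooled-variance Student's
#'   t-test (default pooled).
#' @return list with `summary` (group x feature mean/sd/n) and `tests`
#'   (group, feature, mean_group, mean_normal, t, p). Degenerate groups
#'   (fewer than 2 members) are skipped with a warning.
#' @export
compare_groups <- function(features, welch = FALSE) {
  ft <- as.data.table(features)
  groups <- list(SE = ft[group_SE == TRUE],
                 RI = ft[group_RI == TRUE],
                 normal = ft[as_group == "normal"])
  feats <- c("gene_length", "exon_count", "gc_content")
  summary <- rbindlist(lapply(names(groups), function(g)
    data.table(group = g, feature = feats,
               mean = vapply(feats, function(f)
                 mean(groups[[g]][[f]], na.rm = TRUE), numeric(1)),
               sd = vapply(feats, function(f)
                 stats::sd(groups[[g]][[f]], na.rm = TRUE), numeric(1)),
               n = nrow(groups[[g]]))))
  tests <- rbindlist(lapply(c("SE", "RI"), function(g) {
    rbindlist(lapply(feats, function(f) {
      x <- groups[[g]][[f]]; y <- groups$normal[[f]]
      if (length(x) < 2L || length(y) < 2L) {
        warnf("group %s vs normal on %s skipped (degenerate group size)", g, f)
        return(data.table(group = g, feature = f,
                          mean_group = mean(x), mean_normal = mean(y),
                          t = NA_real_, p = NA_real_))
      }
      if (isTRUE(all.equal(stats::var(c(x, y)), 0))) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- stats::t.test(x, y, var.equal = !welch)
      }
      data.table(group = g, feature = f, mean_group = mean(x),
                 mean_normal = mean(y), t = unname(tt$statistic),
                 p = tt$p.value)
    }))
  }))
  list(summary = summary[], tests = tests[])
}

#' Extract splice-junction sites from events and normal genes
#'
#' SE events contribute their two boundaries: site A, the acceptor at the
#' skipped exon's transcript-upstream edge, and site B, the donor at its
#' transcript-downstream edge. RI events contribute site C, the donor at the
#' retained intron's 5' end, and site D, the acceptor at its 3' end. Normal
#' genes (multi-exon genes with no retained event) contribute every internal
#' exon/intron boundary as the comparison population; single-exon genes
#' contribute nothing. Donor/acceptor labels are strand-aware.
#'
#' @param events retained events table (only distinct SE/RI events are used).
#' @param gene_models gene models from [read_gtf()]; needed for the normal
#'   population.
#' @return `data.table` of sites: `chrom`, `strand`, `position` (0-based
#'   coordinate of the intronic base adjacent to the boundary), `side`
#'   (`donor`/`acceptor`), `intron_side` (`left`/`right`, genomic),
#'   `source` (`SE_A`, `SE_B`, `RI_C`, `RI_D`, `normal`), `gene_id`.
#' @export
extract_junctions <- function(events, gene_models) {
  ev <- unique(as.data.table(events)[event_type %in% c("SE", "RI"),
                                     .(event_key, event_type, chrom, strand,
                                       junc_start, junc_end, gene_id)])
  site_row <- function(chrom, strand, pos, intron_side, source, gene_id) {
    # transcript role of the boundary: donor = exon then intron in transcript
    side <- if (intron_side == "right") {
      if (strand == "+") "donor" else "acceptor"
    } else {
      if (strand == "+") "acceptor" else "donor"
    }
    data.table(chrom = chrom, strand = strand, position = pos, side = side,
               intron_side = intron_side, source = source, gene_id = gene_id)
  }
  out <- list()
  if (nrow(ev)) {
    se <- ev[event_type == "SE"]
    if (nrow(se)) {
      # skipped exon [junc_start, junc_end) 0-based half-open;
      # genomic-left boundary has its intron on the left, right boundary on the right
      left <- se[, site_row(chrom, strand, junc_start - 1L, "left",
                   ifelse(strand == "+", "SE_A", "SE_B"), gene_id),
                 by = event_key]
      right <- se[, site_row(chrom, strand, junc_end, "right",
                    ifelse(strand == "+", "SE_B", "SE_A"), gene_id),
                  by = event_key]
      out <- c(out, list(left, right))
    }
    ri <- ev[event_type == "RI"]
    if (nrow(ri)) {
      # retained intron [junc_start, junc_end) 0-based half-open
      left <- ri[, site_row(chrom, strand, junc_start, "right",
                   ifelse(strand == "+", "RI_C", "RI_D"), gene_id),
                 by = event_key]
      right <- ri[, site_row(chrom, strand, junc_end - 1L, "left",
                    ifelse(strand == "+", "RI_D", "RI_C"), gene_id),
                  by = event_key]
      out <- c(out, list(left, right))
    }
    out <- lapply(out, function(d) d[, event_key := NULL])
  }
  gm <- as.data.table(gene_models)
  as_gene_ids <- unique(as.data.table(events)$gene_id)
  normal <- gm[!(gene_id %in% as_gene_ids) & exon_count >= 2L]
  if (nrow(normal)) {
    nsites <- rbindlist(lapply(seq_len(nrow(normal)), function(i) {
      ex <- normal$exons[[i]]      # merged, sorted, 1-based inclusive
      n <- nrow(ex)
      rbindlist(list(
        # first intron base after each internal exon end (0-based = 1-based end)
        site_row(normal$chrom[i], normal$strand[i], ex[-n, "end"],
                 "right", "normal", normal$gene_id[i]),
        # last intron base before each internal exon start
        site_row(normal$chrom[i], normal$strand[i], ex[-1L, "start"] - 2L,
                 "left", "normal", normal$gene_id[i])
      ))
    }))
    out <- c(out, list(nsites))
  }
  if (!length(out)) return(
    data.table(chrom = character(), strand = character(), position = integer(),
               side = character(), intron_side = character(),
               source = character(), gene_id = character()))
  rbindlist(out)[]
}

#' GC content of splice-junction windows
#'
#' For every junction site, extracts the 51 bp window centred on the site
#' (25 bp each side of the intronic base at the boundary), plus the 20 bp
#' exon-side and 20 bp intron-side windows immediately adjacent to the
#' boundary, and computes each window's GC fraction. Sites closer than 25 bp
#' to a contig end are excluded and counted.
#'
#' @param sites table from [extract_junctions()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param flank half-width of the full window (default 25 bp).
#' @param side_width width of the exon-side/intron-side windows (default 20).
#' @return `data.table` of the retained sites with `gc_full`, `gc_exon`,
#'   `gc_intron` columns; attribute `n_excluded` counts edge exclusions.
#' @export
junction_gc <- function(sites, genome, flank = 25L, side_width = 20L) {
  st <- as.data.table(sites)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  P <- st$position + 1L                       # 1-based boundary base
  ok <- P - flank >= 1L & P + flank <= lens[st$chrom]
  n_excluded <- sum(!ok)
  st <- st[ok]
  P <- P[ok]
  right <- st$intron_side == "right"
  win <- data.table(
    full_s = P - flank, full_e = P + flank,
    i_s = ifelse(right, P, P - side_width + 1L),
    i_e = ifelse(right, P + side_width - 1L, P),
    e_s = ifelse(right, P - side_width, P + 1L),
    e_e = ifelse(right, P - 1L, P + side_width)
  )
  for (nm in c("full", "i", "e"))
    st[, paste0("gc_", nm) := rep(NA_real_, .N)]
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    subj <- genome[[ch]]
    st$gc_full[idx] <- gc_fraction(Biostrings::extractAt(
      subj, IRanges::IRanges(win$full_s[idx], win$full_e[idx])))
    st$gc_i[idx] <- gc_fraction(Biostrings::extractAt(
      subj, IRanges::IRanges(win$i_s[idx], win$i_e[idx])))
    st$gc_e[idx] <- gc_fraction(Biostrings::extractAt(
      subj, IRanges::IRanges(win$e_s[idx], win$e_e[idx])))
  }
  setnames(st, c("gc_i", "gc_e"), c("gc_intron", "gc_exon"))
  setattr(st, "n_excluded", n_excluded)
  st[]
}

#' Compare junction-window GC between AS and normal sites
#'
#' Two-sided t-tests of exon-side and intron-side window GC, each AS site
#' class (`SE_A`, `SE_B`, `RI_C`, `RI_D`) against the normal sites of the
#' matching transcript side (donors against donors, acceptors against
#' acceptors).
#'
#' @param windows table from [junction_gc()].
#' @param welch Welch's test instead of pooled Student's (default pooled).
#' @return `data.table`: `source`, `side`, `window` (`exon`/`intron`),
#'   `n_as`, `n_normal`, `mean_as`, `mean_normal`, `t`, `p`.
#' @export
compare_junction_gc <- function(windows, welch = FALSE) {
  w <- as.data.table(windows)
  normal <- w[source == "normal"]
  rows <- list()
  for (src in intersect(c("SE_A", "SE_B", "RI_C", "RI_D"), unique(w$source))) {
    as_sites <- w[source == src]
    side_ <- as_sites$side[1]
    ref <- normal[side == side_]
    for (wc in c("exon", "intron")) {
      x <- as_sites[[paste0("gc_", wc)]]
      y <- ref[[paste0("gc_", wc)]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) {
        warnf("junction GC comparison %s/%s skipped (too few sites)", src, wc)
        next
      }
      tt <- stats::t.test(x, y, var.equal = !welch)
      rows[[paste(src, wc)]] <- data.table(
        source = src, side = side_, window = wc,
        n_as = length(x), n_normal = length(y),
        mean_as = mean(x), mean_normal = mean(y),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  rbindlist(rows)[]
}
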