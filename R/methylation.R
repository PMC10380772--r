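# Context-resolved methylation levels and sliding-window metagene profiles
# over gene bodies, 2 kb flanks and splice-junction neighborhoods.
#
# Levels are weighted (read-count) levels: sum(n_meth) / sum(n_total) over
# the covered cytosines of a context inside a region, robust to coverage
# variation. "m5C" is the pooled level over all three contexts.

#' Sliding-window profile configuration
#'
#' Gene bodies and 2 kb flanks use fractional windows: width 0.02 and step
#' 0.01 of the segment length, giving exactly 99 windows per segment for any
#' segment of at least 50 bp (fractional boundaries are rounded half-up to
#' integers per window). Junction neighborhoods use fixed 10 bp windows with
#' 5 bp steps over the 101 bp region centred on the site (19 windows).
#'
#' @param body_window_frac,body_step_frac fractional window/step for bodies
#'   and flanks.
#' @param flank_len flank length in bp (default 2000).
#' @param junction_flank half-width of the junction region (default 50 bp).
#' @param junction_window,junction_step junction window/step in bp.
#' @param min_sites minimum covered cytosines for a window level (default 1).
#' @param pool_genes pool counts across genes instead of averaging per-gene
#'   levels (default: per-gene averaging).
#' @return a `profile_config` list.
#' @export
profile_config <- function(body_window_frac = 0.02, body_step_frac = 0.01,
                           flank_len = 2000L, junction_flank = 50L,
                           junction_window = 10L, junction_step = 5L,
                           min_sites = 1L, pool_genes = FALSE) {
  stopifnot(body_step_frac > 0, body_step_frac <= body_window_frac,
            flank_len > 0, junction_step > 0,
            junction_step <= junction_window, min_sites >= 1)
  structure(list(body_window_frac = body_window_frac,
                 body_step_frac = body_step_frac,
                 flank_len = as.integer(flank_len),
                 junction_flank = as.integer(junction_flank),
                 junction_window = as.integer(junction_window),
                 junction_step = as.integer(junction_step),
                 min_sites = as.integer(min_sites),
                 pool_genes = pool_genes),
            class = "profile_config")
}

# per-(chrom, context incl. pooled "m5C") position-sorted cumulative sums
build_meth_index <- function(records) {
  m <- as.data.table(records)
  idx <- list()
  for (ch in unique(m$chrom)) {
    sub <- m[chrom == ch]
    setorder(sub, pos)
    by_ctx <- list()
    for (ctx in c(METH_CONTEXTS, "m5C")) {
      s <- if (ctx == "m5C") sub else sub[context == ctx]
      if (ctx == "m5C") {
        # pooled: collapse duplicate positions across contexts is unnecessary,
        # cumulative sums over all rows in position order are correct
        s <- sub
      }
      by_ctx[[ctx]] <- list(pos = s$pos,
                            cmeth = cumsum(as.numeric(s$n_meth)),
                            ctot = cumsum(as.numeric(s$n_total)))
    }
    idx[[ch]] <- by_ctx
  }
  structure(idx, class = "meth_index")
}

# vectorized interval query; lo/hi 1-based inclusive
index_query <- function(idx, chrom, lo, hi, context, min_sites = 1L) {
  ci <- idx[[chrom]][[context]]
  if (is.null(ci) || length(ci$pos) == 0L) return(rep(NA_real_, length(lo)))
  ihi <- findInterval(hi, ci$pos)
  ilo <- findInterval(lo - 1L, ci$pos)
  nsite <- ihi - ilo
  meth <- ifelse(ihi > 0, ci$cmeth[pmax(ihi, 1L)], 0) -
          ifelse(ilo > 0, ci$cmeth[pmax(ilo, 1L)], 0)
  tot <- ifelse(ihi > 0, ci$ctot[pmax(ihi, 1L)], 0) -
         ifelse(ilo > 0, ci$ctot[pmax(ilo, 1L)], 0)
  out <- meth / tot
  out[nsite < min_sites | tot == 0] <- NA_real_
  out
}

#' Weighted methylation level of a region
#'
#' Level = sum(n_meth) / sum(n_total) over the covered cytosines of the given
#' context inside the 1-based inclusive region; `"m5C"` pools all three
#' contexts. `NA` when the region holds no covered cytosine.
#'
#' @param records methylation calls ([read_methylation()]) or a prebuilt
#'   index.
#' @param chrom,start,end region (1-based inclusive).
#' @param context `"CpG"`, `"CHG"`, `"CHH"` or `"m5C"`.
#' @return numeric level in `[0, 1]` or `NA`.
#' @export
region_level <- function(records, chrom, start, end, context = "m5C") {
  stopifnot(start >= 1, end >= start)
  context <- match.arg(context, c(METH_CONTEXTS, "m5C"))
  idx <- if (inherits(records, "meth_index")) records else
    build_meth_index(records)
  index_query(idx, chrom, start, end, context)
}

# 99 fractional windows over a segment of length L, as 0-based half-open
# local offsets; boundaries rounded half-up
body_windows <- function(L, window_frac = 0.02, step_frac = 0.01) {
  n <- as.integer(floor((1 - window_frac) / step_frac)) + 1L
  i <- seq_len(n) - 1L
  s <- round_half_up(i * step_frac * L)
  e <- round_half_up((i * step_frac + window_frac) * L)
  e <- pmax(e, s + 1L)    # a window is never empty once L >= 1/window_frac
  data.table(start_off = as.integer(s), end_off = as.integer(e))
}

# fixed-size sliding windows over a segment of length L (0-based half-open)
fixed_windows <- function(L, window, step) {
  n <- as.integer(floor((L - window) / step)) + 1L
  s <- (seq_len(n) - 1L) * step
  data.table(start_off = as.integer(s), end_off = as.integer(s + window))
}

# map local 5'->3' offsets [s,e) on a segment to genomic 1-based intervals.
# seg_start/seg_end: genomic 1-based inclusive bounds of the segment;
# strand "+" reads left->right, "-" right->left.
orient_windows <- function(win, seg_start, seg_end, strand) {
  if (strand == "-") {
    data.table(lo = seg_end - win$end_off + 1L, hi = seg_end - win$start_off)
  } else {
    data.table(lo = seg_start + win$start_off, hi = seg_start + win$end_off - 1L)
  }
}

#' Metagene methylation profile over gene bodies and flanks
#'
#' For each gene, the upstream 2 kb flank, gene body and downstream 2 kb
#' flank are each cut into 99 sliding windows (width 0.02, step 0.01 of the
#' segment length) oriented 5' to 3' along the gene strand, and the weighted
#' methylation level of every window is computed per context. The group
#' profile is the unweighted mean across genes per window index (missing
#' windows ignored), or a pooled-count profile with
#' `config$pool_genes = TRUE`. Genes shorter than 50 bp are excluded (their
#' body window width would fall below 1 bp) and counted.
#'
#' @param genes gene models (rows of [read_gtf()] output) forming one group.
#' @param records methylation calls or a prebuilt index.
#' @param config a [profile_config()].
#' @param contexts contexts to profile (default all three plus pooled m5C).
#' @param group label stamped on the output rows.
#' @return list with `profile` (long `data.table`: `group`, `context`,
#'   `segment` in upstream/body/downstream, `window` 1..99, `level`, `n`
#'   contributing genes), `n_genes`, `n_excluded`.
#' @export
gene_body_profile <- function(genes, records, config = profile_config(),
                              contexts = c(METH_CONTEXTS, "m5C"),
                              group = "all") {
  stopifnot(inherits(config, "profile_config"))
  gm <- as.data.table(genes)
  if (nrow(gm) == 0L) stopf("empty gene group")
  min_len <- ceiling(1 / config$body_window_frac)
  excluded <- gm$gene_length < min_len
  gm <- gm[!excluded]
  if (nrow(gm) == 0L) stopf("no gene of length >= %d bp in group", min_len)
  idx <- if (inherits(records, "meth_index")) records else
    build_meth_index(records)

  fw <- body_windows(config$flank_len, config$body_window_frac,
                     config$body_step_frac)
  n_win <- nrow(fw)
  segs <- c("upstream", "body", "downstream")
  acc_num <- acc_den <- array(
    0, dim = c(length(contexts), 3L, n_win),
    dimnames = list(contexts, segs, NULL))

  for (gi in seq_len(nrow(gm))) {
    st <- gm$start[gi]; en <- gm$end[gi]; strand <- gm$strand[gi]
    bw <- body_windows(gm$gene_length[gi], config$body_window_frac,
                       config$body_step_frac)
    five_prime_flank <- if (strand == "-")
      c(en + 1L, en + config$flank_len) else c(st - config$flank_len, st - 1L)
    three_prime_flank <- if (strand == "-")
      c(st - config$flank_len, st - 1L) else c(en + 1L, en + config$flank_len)
    wins <- list(
      upstream = orient_windows(fw, five_prime_flank[1], five_prime_flank[2],
                                strand),
      body = orient_windows(bw, st, en, strand),
      downstream = orient_windows(fw, three_prime_flank[1],
                                  three_prime_flank[2], strand))
    for (ctx in contexts) {
      for (sg in segs) {
        w <- wins[[sg]]
        ok <- w$lo >= 1L
        lv <- rep(NA_real_, n_win)
        if (any(ok))
          lv[ok] <- index_query(idx, gm$chrom[gi], w$lo[ok], w$hi[ok], ctx,
                                config$min_sites)
        has <- !is.na(lv)
        if (config$pool_genes) {
          # pooled variant: accumulate counts via level*1 weighting is wrong;
          # re-query raw sums instead
          ci <- idx[[gm$chrom[gi]]][[ctx]]
          if (!is.null(ci) && length(ci$pos)) {
            ihi <- findInterval(w$hi, ci$pos)
            ilo <- findInterval(w$lo - 1L, ci$pos)
            meth <- ifelse(ihi > 0, ci$cmeth[pmax(ihi, 1L)], 0) -
                    ifelse(ilo > 0, ci$cmeth[pmax(ilo, 1L)], 0)
            tot <- ifelse(ihi > 0, ci$ctot[pmax(ihi, 1L)], 0) -
                   ifelse(ilo > 0, ci$ctot[pmax(ilo, 1L)], 0)
            meth[!ok] <- 0; tot[!ok] <- 0
            acc_num[ctx, sg, ] <- acc_num[ctx, sg, ] + meth
            acc_den[ctx, sg, ] <- acc_den[ctx, sg, ] + tot
          }
        } else {
          acc_num[ctx, sg, has] <- acc_num[ctx, sg, has] + lv[has]
          acc_den[ctx, sg, has] <- acc_den[ctx, sg, has] + 1
        }
      }
    }
  }
  prof <- rbindlist(lapply(contexts, function(ctx)
    rbindlist(lapply(segs, function(sg)
      data.table(group = group, context = ctx, segment = sg,
                 window = seq_len(n_win),
                 level = ifelse(acc_den[ctx, sg, ] > 0,
                                acc_num[ctx, sg, ] / acc_den[ctx, sg, ],
                                NA_real_),
                 n = if (config$pool_genes) NA_integer_ else
                   as.integer(acc_den[ctx, sg, ]))))))
  prof[, segment := factor(segment, levels = segs)]
  list(profile = prof[], n_genes = nrow(gm), n_excluded = sum(excluded))
}

#' Sliding-window methylation profile around splice junctions
#'
#' Profiles the 101 bp region centred on each junction site (50 bp each side
#' of the boundary base) with 10 bp windows stepping 5 bp (19 windows),
#' oriented so window 1 is the biological 5' end. Sites are grouped by
#' their source (`SE`, `RI`, `normal`); sites with no covered cytosine in
#' any window contribute nothing.
#'
#' @param sites junction sites from [extract_junctions()].
#' @param records methylation calls or a prebuilt index.
#' @param config a [profile_config()].
#' @param contexts contexts to profile.
#' @return long `data.table`: `group`, `context`, `window` (1..19), `level`
#'   (mean over sites), `n` contributing sites.
#' @export
junction_profile <- function(sites, records, config = profile_config(),
                             contexts = c(METH_CONTEXTS, "m5C")) {
  stopifnot(inherits(config, "profile_config"))
  st <- as.data.table(sites)
  st[, group := ifelse(source %in% c("SE_A", "SE_B"), "SE",
                 ifelse(source %in% c("RI_C", "RI_D"), "RI", "normal"))]
  idx <- if (inherits(records, "meth_index")) records else
    build_meth_index(records)
  L <- 2L * config$junction_flank + 1L
  fw <- fixed_windows(L, config$junction_window, config$junction_step)
  n_win <- nrow(fw)
  out <- list()
  for (g in unique(st$group)) {
    sub <- st[group == g]
    acc_num <- acc_den <- matrix(0, nrow = length(contexts), ncol = n_win,
                                 dimnames = list(contexts, NULL))
    for (si in seq_len(nrow(sub))) {
      P <- sub$position[si] + 1L          # 1-based boundary base
      seg <- c(P - config$junction_flank, P + config$junction_flank)
      w <- orient_windows(fw, seg[1], seg[2], sub$strand[si])
      ok <- w$lo >= 1L
      for (ctx in contexts) {
        lv <- rep(NA_real_, n_win)
        if (any(ok))
          lv[ok] <- index_query(idx, sub$chrom[si], w$lo[ok], w$hi[ok], ctx,
                                config$min_sites)
        has <- !is.na(lv)
        acc_num[ctx, has] <- acc_num[ctx, has] + lv[has]
        acc_den[ctx, has] <- acc_den[ctx, has] + 1
      }
    }
    out[[g]] <- rbindlist(lapply(contexts, function(ctx)
      data.table(group = g, context = ctx, window = seq_len(n_win),
                 level = ifelse(acc_den[ctx, ] > 0,
                                acc_num[ctx, ] / acc_den[ctx, ], NA_real_),
                 n = as.integer(acc_den[ctx, ]))))
  }
  rbindlist(out)[]
}

#' Per-region methylation levels for a set of labelled regions
#'
#' Convenience over [region_level()]: computes the weighted level of every
#' region per context, carrying the region's group label, so groups can be
#' compared with [compare_methylation()].
#'
#' @param regions `data.table` with `chrom`, `start`, `end` (1-based
#'   inclusive), `id`, `group`.
#' @param records methylation calls or a prebuilt index.
#' @param contexts contexts to evaluate.
#' @return long `data.table`: `id`, `group`, `context`, `level`.
#' @export
methylation_levels <- function(regions, records,
                               contexts = c(METH_CONTEXTS, "m5C")) {
  rg <- as.data.table(regions)
  idx <- if (inherits(records, "meth_index")) records else
    build_meth_index(records)
  rbindlist(lapply(contexts, function(ctx) {
    lv <- rep(NA_real_, nrow(rg))
    for (ch in unique(rg$chrom)) {
      ii <- which(rg$chrom == ch)
      lv[ii] <- index_query(idx, ch, rg$start[ii], rg$end[ii], ctx)
    }
    data.table(id = rg$id, group = rg$group, context = ctx, level = lv)
  }))
}

#' Compare region-level methylation between groups
#'
#' Two-sided t-tests of each AS group against the normal group, per context,
#' on per-region levels (gene bodies or junction neighborhoods). Contexts
#' with no data in a group are skipped with a warning; identical groups give
#' p = 1.
#'
#' @param levels long table from [methylation_levels()].
#' @param reference reference group name (default `"normal"`).
#' @param welch Welch's t-test instead of pooled Student's.
#' @return `data.table`: `group`, `context`, `n_group`, `n_ref`,
#'   `mean_group`, `mean_ref`, `t`, `p`.
#' @export
compare_methylation <- function(levels, reference = "normal", welch = FALSE) {
  lv <- as.data.table(levels)[!is.na(level)]
  rows <- list()
  for (g in setdiff(unique(lv$group), reference)) {
    for (ctx in unique(lv$context)) {
      x <- lv[group == g & context == ctx, level]
      y <- lv[group == reference & context == ctx, level]
      if (length(x) < 2L || length(y) < 2L) {
        warnf("methylation comparison %s/%s skipped (empty or degenerate)",
              g, ctx)
        next
      }
      if (isTRUE(all.equal(stats::var(c(x, y)), 0))) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- stats::t.test(x, y, var.equal = !welch)
      }
      rows[[paste(g, ctx)]] <- data.table(
        group = g, context = ctx, n_group = length(x), n_ref = length(y),
        mean_group = mean(x), mean_ref = mean(y),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  if (!length(rows)) return(data.table(group = character(),
                                       context = character(),
                                       n_group = integer(), n_ref = integer(),
                                       mean_group = numeric(),
                                       mean_ref = numeric(), t = numeric(),
                                       p = numeric()))
  rbindlist(rows)[]
}
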