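# Reciprocal-best-hit pairing from BLAST tabular hits.
# Used twice: strict 1:1 pairing of At/Dt homoeologs, and one-to-many
# expansion of a cross-species splicing-factor query list.

# order hits best-first: bitscore desc, e-value asc, subject id asc
rank_hits <- function(hits) {
  h <- as.data.table(hits)
  setorder(h, query_id, -bitscore, evalue, subject_id)
  h
}

best_hit_per_query <- function(hits) {
  rank_hits(hits)[, .SD[1L], by = query_id]
}

#' Reciprocal-best-hit homolog pairing
#'
#' Pairs `(a, b)` such that `b` is `a`'s top hit in the forward (A to B)
#' search and `a` is `b`'s top hit in the reverse (B to A) search. Hits are
#' ranked by bitscore (length-corrected), breaking ties by smaller e-value
#' and then lexicographic subject id, so the output is deterministic.
#'
#' With `mode = "one_to_many"`, the reciprocity requirement is relaxed on the
#' query side: a pair is emitted whenever `a` is `b`'s top reverse hit and
#' `b` appears anywhere among `a`'s forward hits, so one query may collect
#' several targets (the homolog-family expansion case).
#'
#' @param forward,reverse BLAST outfmt-6 tables from [read_blast()]
#'   (forward: A queries vs B; reverse: B queries vs A).
#' @param mode `"one_to_one"` (strict RBH, default) or `"one_to_many"`.
#' @return `data.table` with `gene_a`, `gene_b`, `bitscore_fwd`,
#'   `bitscore_rev`, sorted by `gene_a`. Under strict RBH no gene occurs in
#'   more than one pair.
#' @export
rbh <- function(forward, reverse, mode = c("one_to_one", "one_to_many")) {
  mode <- match.arg(mode)
  forward <- as.data.table(forward)
  reverse <- as.data.table(reverse)
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    warnf("empty BLAST hit list; no pairs")
    return(data.table(gene_a = character(), gene_b = character(),
                      bitscore_fwd = numeric(), bitscore_rev = numeric()))
  }
  best_rev <- best_hit_per_query(reverse)[, .(gene_b = query_id,
                                              gene_a = subject_id,
                                              bitscore_rev = bitscore)]
  if (mode == "one_to_one") {
    best_fwd <- best_hit_per_query(forward)[, .(gene_a = query_id,
                                                gene_b = subject_id,
                                                bitscore_fwd = bitscore)]
    pairs <- merge(best_fwd, best_rev, by = c("gene_a", "gene_b"))
  } else {
    any_fwd <- unique(forward[, .(gene_a = query_id, gene_b = subject_id,
                                  bitscore_fwd = bitscore)],
                      by = c("gene_a", "gene_b"))
    pairs <- merge(any_fwd, best_rev, by = c("gene_a", "gene_b"))
  }
  setorder(pairs, gene_a, gene_b)
  pairs[, .(gene_a, gene_b, bitscore_fwd, bitscore_rev)]
}

#' Expand a query gene set through homolog pairs
#'
#' Maps a set of query genes (side A) to their paired genes in the target
#' genome (side B), reporting queries with no match.
#'
#' @param queries character vector of side-A gene ids.
#' @param pairs pair table from [rbh()].
#' @return list with `targets` (character vector of matched side-B genes,
#'   unique, sorted), `map` (query, target long table) and `unmatched`
#'   (queries with no pair).
#' @export
homolog_expansion <- function(queries, pairs) {
  queries <- unique(as.character(queries))
  map <- as.data.table(pairs)[gene_a %in% queries,
                              .(query = gene_a, target = gene_b)]
  setorder(map, query, target)
  list(targets = sort(unique(map$target)),
       map = map[],
       unmatched = setdiff(queries, map$query))
}
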