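#' One-tailed hypergeometric enrichment
#'
#' Fold enrichment and upper-tail P for observing `observed` category
#' members in a group of `group_size` genes drawn from a universe of
#' `universe_size` genes containing `category_size` category members.
#' This is the one-tailed Fisher exact test on the 2x2 table with fixed
#' margins, computed as the hypergeometric tail `P(X >= observed)`.
#'
#' @param observed category members in the group
#' @param group_size group size
#' @param category_size category size in the universe
#' @param universe_size universe size
#' @return list with `fold` (observed / expected), `expected`, and `p`
#' @examples
#' hypergeomEnrichment(175, 1500, 1500, 17533)  # 1.4-fold
#' @export
hypergeomEnrichment <- function(observed, group_size, category_size,
                                universe_size) {
  if (observed > min(group_size, category_size))
    stop("observed exceeds group or category size")
  if (category_size > universe_size || group_size > universe_size)
    stop("category/group larger than universe")
  expected <- group_size * category_size / universe_size
  if (expected == 0)
    stop("undefined fold: expected count is 0")
  p <- stats::phyper(observed - 1, category_size,
    universe_size - category_size, group_size, lower.tail = FALSE)
  list(fold = observed / expected, expected = expected, p = p)
}

#' Sliding-window enrichment over a gene ranking
#'
#' Genes are ranked (e.g. by H3K27me3 width) and scored in overlapping
#' windows: each window holds `window` genes and neighboring windows
#' share `shared` genes, so windows start at ranks 0, window-shared,
#' 2(window-shared), ...  A trailing window shorter than `window` is
#' dropped.  Each window is tested against the full universe with
#' [hypergeomEnrichment()].  Ranked genes missing from the universe are
#' dropped with a warning.
#'
#' @param ranked_gene_ids character vector, best rank first
#' @param category gene set list (see [readGeneSet()]) or character ids
#' @param universe gene set list or character ids
#' @param window window size (default 1500)
#' @param shared overlap between neighboring windows (default 500)
#' @return data.frame with one row per window: window_index, rank_start,
#'   rank_end, observed, expected, fold, p_value
#' @export
slidingWindowEnrichment <- function(ranked_gene_ids, category, universe,
                                    window = 1500L, shared = 500L) {
  cat_ids <- if (is.list(category)) category$gene_ids else category
  uni_ids <- if (is.list(universe)) universe$gene_ids else universe
  stopifnot(window > shared, shared >= 0)
  drop <- !(ranked_gene_ids %in% uni_ids)
  if (any(drop)) {
    warning(sum(drop), " ranked gene(s) not in the universe; dropped")
    ranked_gene_ids <- ranked_gene_ids[!drop]
  }
  n <- length(ranked_gene_ids)
  if (window > n)
    stop("window larger than the ranking (", n,
      " genes); no full window fits")
  cat_ids <- intersect(cat_ids, uni_ids)
  step <- window - shared
  starts <- seq(0L, n - window, by = step)
  rows <- lapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1):(starts[i] + window)
    obs <- sum(ranked_gene_ids[idx] %in% cat_ids)
    e <- hypergeomEnrichment(obs, window, length(cat_ids), length(uni_ids))
    data.frame(window_index = i, rank_start = starts[i],
      rank_end = starts[i] + window, observed = obs,
      expected = e$expected, fold = e$fold, p_value = e$p)
  })
  do.call(rbind, rows)
}

#' Mutual overlap between two domain sets
#'
#' Counts how many domains of set A overlap (>= 1 bp) at least one
#' domain of set B, and symmetrically.
#'
#' @param domains_a,domains_b GRanges, or data.frames with columns
#'   chrom, start, end (0-based half-open)
#' @return list with `n_a_hit` and `n_b_hit`
#' @export
domainSetOverlap <- function(domains_a, domains_b) {
  asGr <- function(d) {
    if (is(d, "GRanges")) return(d)
    GRanges(d$chrom, IRanges(d$start + 1L, d$end))
  }
  a <- asGr(domains_a)
  b <- asGr(domains_b)
  list(n_a_hit = sum(IRanges::overlapsAny(a, b, ignore.strand = TRUE)),
    n_b_hit = sum(IRanges::overlapsAny(b, a, ignore.strand = TRUE)))
}
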