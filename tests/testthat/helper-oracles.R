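suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Exhaustive O(genes x peaks) interval-overlap oracle for per-gene peak
# aggregation, independent of findOverlaps.
oracleGenePeakStats <- function(genes, peaks, clip = FALSE) {
  gs <- start(genes) - 1L; ge <- end(genes)
  ps <- start(peaks) - 1L; pe <- end(peaks)
  gchr <- as.character(seqnames(genes))
  pchr <- as.character(seqnames(peaks))
  ws <- numeric(length(genes)); hm <- numeric(length(genes))
  for (i in seq_along(genes)) {
    for (j in seq_along(peaks)) {
      if (gchr[i] != pchr[j]) next
      ov <- min(ge[i], pe[j]) - max(gs[i], ps[j])
      if (ov <= 0) next
      ws[i] <- ws[i] + if (clip) ov else (pe[j] - ps[j])
      hm[i] <- max(hm[i], peaks$height[j])
    }
  }
  data.frame(gene_id = genes$gene_id, width_sum = ws, height_max = hm,
    coverage = ws / (ge - gs))
}

# Brute-force knee: explicit distance scan over the scaled curve.
oracleKnee <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf; best_i <- NA
  for (i in seq_len(n)) {
    xs <- i - 1
    ys <- (v[i] - v[1]) / (v[n] - v[1]) * (n - 1)
    d <- sqrt((n - 1 - xs)^2 + ys^2)
    if (d <= best) { best <- d; best_i <- i }  # ties -> larger rank
  }
  list(rank_index = best_i - 1L, width = v[best_i])
}

# Hypergeometric upper tail from first principles (log choose), no
# phyper.
oracleHyperP <- function(obs, group, categ, uni) {
  lch <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  ks <- obs:min(group, categ)
  sum(exp(lch(categ, ks) + lch(uni - categ, group - ks) - lch(uni, group)))
}

# Full enumeration of all C(n, draws) equally likely draws (tiny n).
oracleHyperEnum <- function(obs, group, categ, uni) {
  pop <- c(rep(1, categ), rep(0, uni - categ))
  draws <- utils::combn(uni, group)
  hits <- apply(draws, 2, function(ix) sum(pop[ix]))
  mean(hits >= obs)
}

# Per-bp window sum on an expanded track.
oracleWindowSum <- function(values, step, from, to) {
  perbp <- rep(values, each = step)
  from <- max(from, 0); to <- min(to, length(perbp))
  if (to <= from) return(0)
  sum(perbp[(from + 1):to])
}

# Targeted quantile normalization by explicit sort-and-average.
oracleQuantNorm <- function(v, ref) {
  rs <- sort(ref)
  out <- numeric(length(v))
  for (val in unique(v)) {
    ranks <- which(sort(v) == val)
    out[v == val] <- mean(rs[ranks])
  }
  out
}
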