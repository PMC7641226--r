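# Strand-oriented window arithmetic uses 0-based half-open bp throughout:
# s0 = first base of the gene, e0 = one past the last.  For a + gene the
# TSS is s0 and "downstream" increases coordinates; for a - gene the TSS
# is e0 and downstream decreases coordinates.

#' TSS-anchored signal profile
#'
#' Average signal in fixed bins around the TSS of each gene.  Rows of
#' minus-strand genes are orientation-flipped so that positive offsets
#' always point into the gene body.  Positions beyond chromosome bounds
#' contribute 0 signal.
#'
#' @param track a [SignalTrack-class]
#' @param genes gene-model GRanges
#' @param flank distance covered on each side of the TSS (bp)
#' @param bin bin width (bp, >= track step)
#' @return a [ProfileMatrix-class]; positions are bin-center offsets
#' @export
tssProfile <- function(track, genes, flank = 10000L, bin = 100L) {
  stopifnot(flank > 0, bin >= trackStep(track))
  nb <- as.integer(flank %/% bin)
  offsets <- seq(-nb, nb - 1L)  # bin k covers [k*bin, (k+1)*bin)
  vals <- matrix(0, nrow = length(genes), ncol = length(offsets),
    dimnames = list(genes$gene_id, NULL))
  chrs <- as.character(seqnames(genes))
  minus <- as.character(strand(genes)) == "-"
  s0 <- start(genes) - 1L
  e0 <- end(genes)
  for (i in seq_along(genes)) {
    tss <- if (minus[i]) e0[i] else s0[i]
    for (k in seq_along(offsets)) {
      o <- offsets[k]
      win <- if (minus[i]) c(tss - (o + 1L) * bin, tss - o * bin)
             else c(tss + o * bin, tss + (o + 1L) * bin)
      vals[i, k] <- trackWindowSum(track, chrs[i], win[1], win[2]) / bin
    }
  }
  new("ProfileMatrix", values = vals,
    positions = (offsets + 0.5) * bin, mode = "tss")
}

#' Scaled gene-body profile
#'
#' Gene bodies of different lengths are rescaled to `n_body_bins` equal
#' fractions (per-bp mean within each fraction); flanks are covered in
#' ten fixed bp bins of `flank / 10` each side.  Genes shorter than
#' `n_body_bins` times the track step are skipped with a warning.
#'
#' @param track a [SignalTrack-class]
#' @param genes gene-model GRanges
#' @param n_body_bins number of body fractions (default 40)
#' @param flank flank size in bp each side (default 5000; 0 for none)
#' @return a [ProfileMatrix-class]; body bins have positions 1..n,
#'   upstream flank bins negative, downstream past n
#' @export
scaledBodyProfile <- function(track, genes, n_body_bins = 40L,
                              flank = 5000L) {
  n_flank_bins <- if (flank > 0) 10L else 0L
  fb <- if (n_flank_bins) flank / n_flank_bins else 0
  keep <- width(genes) >= n_body_bins * trackStep(track)
  if (!all(keep))
    warning(sum(!keep), " gene(s) shorter than n_body_bins x step skipped")
  genes <- genes[keep]
  ncol_tot <- n_body_bins + 2L * n_flank_bins
  vals <- matrix(0, nrow = length(genes), ncol = ncol_tot,
    dimnames = list(genes$gene_id, NULL))
  chrs <- as.character(seqnames(genes))
  minus <- as.character(strand(genes)) == "-"
  s0 <- start(genes) - 1L
  e0 <- end(genes)
  for (i in seq_along(genes)) {
    L <- e0[i] - s0[i]
    # strand-oriented coordinate u in [ -flank, L + flank )
    u2g <- if (minus[i]) function(u) e0[i] - u else function(u) s0[i] + u
    col <- 0L
    edges_up <- seq(-flank, 0, by = fb)
    if (n_flank_bins) for (k in seq_len(n_flank_bins)) {
      col <- col + 1L
      a <- sort(c(u2g(edges_up[k]), u2g(edges_up[k + 1])))
      vals[i, col] <- trackWindowSum(track, chrs[i], a[1], a[2]) / fb
    }
    bd <- floor(seq(0, L, length.out = n_body_bins + 1L))
    for (k in seq_len(n_body_bins)) {
      col <- col + 1L
      a <- sort(c(u2g(bd[k]), u2g(bd[k + 1])))
      wbp <- bd[k + 1] - bd[k]
      vals[i, col] <- if (wbp > 0)
        trackWindowSum(track, chrs[i], a[1], a[2]) / wbp else 0
    }
    if (n_flank_bins) for (k in seq_len(n_flank_bins)) {
      col <- col + 1L
      a <- sort(c(u2g(L + (k - 1) * fb), u2g(L + k * fb)))
      vals[i, col] <- trackWindowSum(track, chrs[i], a[1], a[2]) / fb
    }
  }
  pos <- c(if (n_flank_bins) seq(-n_flank_bins, -1L),
    seq_len(n_body_bins), if (n_flank_bins) n_body_bins + seq_len(n_flank_bins))
  new("ProfileMatrix", values = vals, positions = as.numeric(pos),
    mode = "body")
}

#' Pol II pausing index
#'
#' Ratio of the Pol II signal sum over the promoter window (TSS - 30 bp
#' to TSS + 300 bp, strand-oriented) to the sum over the gene body
#' (TSS + 300 bp to the TTS).  Sums are per-bp read density sums.
#' Returns NA when the body sum is 0 (flagged undefined).
#'
#' @param pol2 Pol II [SignalTrack-class]
#' @param gene single gene (length-1 GRanges)
#' @return numeric pausing index, or NA if undefined
#' @export
pausingIndex <- function(pol2, gene) {
  r <- promoterBodySums(pol2, gene, up = 30L, down = 300L)
  if (r$body_sum == 0) return(NA_real_)
  r$promoter_sum / r$body_sum
}

#' H3K27me3 promoter-to-body (PTB) ratio
#'
#' As [pausingIndex()] but with the promoter defined as TSS - 3 kb to
#' TSS + 3 kb and the body as TSS + 3 kb to the TTS.
#'
#' @param k27 H3K27me3 [SignalTrack-class]
#' @param gene single gene (length-1 GRanges)
#' @return numeric ratio, or NA if undefined
#' @export
ptbRatio <- function(k27, gene) {
  r <- promoterBodySums(k27, gene, up = 3000L, down = 3000L)
  if (r$body_sum == 0) return(NA_real_)
  r$promoter_sum / r$body_sum
}

# Strand-oriented promoter [TSS-up, TSS+down) and body [TSS+down, TTS)
# sums and means.
promoterBodySums <- function(track, gene, up, down) {
  stopifnot(length(gene) == 1L)
  if (width(gene) <= down)
    stop("gene ", gene$gene_id, " shorter than the promoter window")
  chr <- as.character(seqnames(gene))
  s0 <- start(gene) - 1L
  e0 <- end(gene)
  if (as.character(strand(gene)) == "-") {
    prom <- c(e0 - down, e0 + up)
    body <- c(s0, e0 - down)
  } else {
    prom <- c(s0 - up, s0 + down)
    body <- c(s0 + down, e0)
  }
  ps <- trackWindowSum(track, chr, prom[1], prom[2])
  bs <- trackWindowSum(track, chr, body[1], body[2])
  list(promoter_sum = ps, body_sum = bs,
    promoter_mean = ps / (up + down), body_mean = bs / (body[2] - body[1]))
}

#' Pausing and PTB statistics for a gene set
#'
#' Computes the Pol II pausing index and the H3K27me3 PTB ratio per
#' gene, together with the Pol II promoter and body mean densities used
#' by [eligibilityFilter()].  Genes too short for the windows are
#' skipped.
#'
#' @param pol2 Pol II [SignalTrack-class]
#' @param k27 H3K27me3 [SignalTrack-class]
#' @param genes gene-model GRanges
#' @param density_floor eligibility floor on Pol II mean densities
#' @return data.frame: gene_id, pol2_pausing_index, k27_ptb_ratio,
#'   pol2_promoter_mean, pol2_body_mean, eligible
#' @export
pausingStats <- function(pol2, k27, genes, density_floor = 0.01) {
  keep <- width(genes) > 3000L
  genes <- genes[keep]
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    r2 <- promoterBodySums(pol2, g, 30L, 300L)
    r7 <- promoterBodySums(k27, g, 3000L, 3000L)
    data.frame(gene_id = g$gene_id,
      pol2_pausing_index = if (r2$body_sum == 0) NA_real_ else
        r2$promoter_sum / r2$body_sum,
      k27_ptb_ratio = if (r7$body_sum == 0) NA_real_ else
        r7$promoter_sum / r7$body_sum,
      pol2_promoter_mean = r2$promoter_mean,
      pol2_body_mean = r2$body_mean)
  })
  out <- do.call(rbind, rows)
  out$eligible <- out$pol2_promoter_mean > density_floor &
    out$pol2_body_mean > density_floor & !is.na(out$pol2_pausing_index)
  out
}

#' Keep genes with detectable Pol II at promoter and body
#'
#' Strict inequality at the floor: a mean density exactly equal to the
#' floor is dropped.
#'
#' @param stats data.frame from [pausingStats()]
#' @param density_floor minimum mean density (default 0.01)
#' @return the filtered data.frame
#' @export
eligibilityFilter <- function(stats, density_floor = 0.01) {
  stats[stats$pol2_promoter_mean > density_floor &
        stats$pol2_body_mean > density_floor, , drop = FALSE]
}

#' Binary motif occupancy track
#'
#' Each base pair covered by at least one motif occurrence gets value 1,
#' all others 0 (no double counting of overlapping occurrences).
#'
#' @param occurrences GRanges or data.frame (chrom, start, end; 0-based
#'   half-open) of motif matches
#' @param chrom_lengths optional named chromosome lengths (bp)
#' @return a per-bp (step 1) binary [SignalTrack-class]
#' @export
motifTrack <- function(occurrences, chrom_lengths = NULL) {
  gr <- if (is(occurrences, "GRanges")) occurrences
    else if (NROW(occurrences) == 0L) GRanges()
    else GRanges(occurrences$chrom,
      IRanges(occurrences$start + 1L, occurrences$end))
  chrs <- unique(as.character(seqnames(gr)))
  if (!is.null(chrom_lengths)) chrs <- union(chrs, names(chrom_lengths))
  vals <- lapply(chrs, function(chr) {
    g <- gr[seqnames(gr) == chr]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else if (length(g)) max(end(g)) else 0L
    if (len == 0L) return(numeric(0))
    as.numeric(as.integer(
      IRanges::coverage(ranges(g), width = len) > 0))
  })
  names(vals) <- chrs
  SignalTrack(vals, 1L)
}

#' Motif fold enrichment in BGRD gene bodies
#'
#' Mean scaled-body motif density over BGRD genes divided by the same
#' over control genes; gene bodies are length-scaled so long and short
#' genes weigh equally.
#'
#' @param motif binary [SignalTrack-class] from [motifTrack()]
#' @param bgrd_genes,control_genes gene-model GRanges
#' @param n_body_bins body fractions (default 40)
#' @param flank flank bp each side, excluded from the fold (default 0)
#' @return numeric fold
#' @export
motifFoldEnrichment <- function(motif, bgrd_genes, control_genes,
                                n_body_bins = 40L, flank = 0L) {
  stopifnot(length(bgrd_genes) > 0, length(control_genes) > 0)
  bodyMean <- function(genes) {
    pm <- scaledBodyProfile(motif, genes, n_body_bins, flank)
    body_cols <- which(profilePositions(pm) >= 1 &
                       profilePositions(pm) <= n_body_bins)
    mean(profileValues(pm)[, body_cols, drop = FALSE])
  }
  num <- bodyMean(bgrd_genes)
  den <- bodyMean(control_genes)
  if (den == 0) stop("undefined fold: control density is 0")
  num / den
}

#' Top / median / bottom slices of a ranking
#'
#' Generic ranking utility used to compare genes with high, intermediate
#' and low values of a statistic (e.g. PTB ratio) in fixed-size slices.
#'
#' @param values named numeric vector
#' @param slice slice size
#' @return list with `top`, `median`, `bottom` character id vectors
#' @export
rankSlices <- function(values, slice = 1000L) {
  stopifnot(slice <= length(values))
  ord <- names(sort(values, decreasing = TRUE))
  n <- length(ord)
  mid0 <- floor((n - slice) / 2)
  list(top = ord[seq_len(slice)],
    median = ord[(mid0 + 1):(mid0 + slice)],
    bottom = ord[(n - slice + 1):n])
}
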