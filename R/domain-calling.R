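#' Per-gene H3K27me3 peak statistics
#'
#' Retrieves every peak overlapping each gene (>= 1 bp, strand-blind)
#' and aggregates: `width_sum` is the sum of full peak widths (or of the
#' overlapping portions when `clip = TRUE`), `height_max` the largest
#' peak height, `coverage` the width sum divided by gene length.  A peak
#' overlapping several genes contributes to each of them.  Genes without
#' peaks get zeros.
#'
#' @param genes gene-model GRanges ([geneModels()])
#' @param peaks peak GRanges ([peakRanges()])
#' @param clip if TRUE, only the portion of each peak inside the gene
#'   counts towards the width sum; default FALSE (full peak widths, so
#'   coverage can exceed 1 when domains extend past gene ends)
#' @return data.frame with columns gene_id, length, width_sum,
#'   height_max, coverage, domain_class, group
#' @examples
#' g <- geneModels("g1", "chr1", 0, 100, "+")
#' p <- peakRanges(c("chr1", "chr1"), c(10, 50), c(20, 90), c(2, 5))
#' genePeakStats(g, p)
#' @export
genePeakStats <- function(genes, peaks, clip = FALSE) {
  validateGeneModels(genes)
  n <- length(genes)
  width_sum <- numeric(n)
  height_max <- numeric(n)
  if (length(peaks)) {
    hits <- findOverlaps(genes, peaks, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      w <- if (clip) {
        pmin(end(genes)[qh], end(peaks)[sh]) -
          pmax(start(genes)[qh], start(peaks)[sh]) + 1L
      } else {
        width(peaks)[sh]
      }
      ws <- tapply(w, factor(qh, levels = seq_len(n)), sum)
      width_sum <- as.numeric(ifelse(is.na(ws), 0, ws))
      hm <- tapply(peaks$height[sh], factor(qh, levels = seq_len(n)), max)
      height_max <- as.numeric(ifelse(is.na(hm), 0, hm))
    }
  }
  len <- width(genes)
  data.frame(gene_id = genes$gene_id, length = len,
    width_sum = width_sum, height_max = height_max,
    coverage = width_sum / len,
    domain_class = "none", group = "unassigned",
    stringsAsFactors = FALSE)
}

#' Find the turning point (knee) of a ranked width curve
#'
#' Values are sorted ascending; with rank `x = 0..n-1` and value `y`,
#' both axes are affinely rescaled to `[0, n-1]` and the turning point is
#' the curve point closest (Euclidean) to the bottom-right corner
#' `(n-1, 0)`.  Ties break towards the larger rank (broader width).  The
#' derived cutoff is `multiplier` times the width at the turn.
#'
#' @param values numeric widths (bp), n >= 3
#' @param multiplier cutoff multiplier (default 2)
#' @return a [TurningPoint-class]
#' @examples
#' findTurningPoint(c(rep(0, 99), 1e6))
#' @export
findTurningPoint <- function(values, multiplier = 2.0) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  v <- sort(values)
  if (v[1] == v[n])
    stop("degenerate curve: all values equal, no L shape")
  x <- seq_len(n) - 1
  ys <- (v - v[1]) / (v[n] - v[1]) * (n - 1)
  d2 <- (n - 1 - x)^2 + ys^2
  idx <- max(which(d2 == min(d2)))  # ties -> larger rank
  TurningPoint(idx - 1L, v[idx], multiplier)
}

#' Classify genes into BGRD / FGRD and draw a random control set
#'
#' BGRD genes are the `n_top` with the largest total H3K27me3 width that
#' also satisfy the turning-point cutoff (fewer than `n_top` are
#' returned when the cutoff bites).  FGRD genes are the `n_top` with the
#' highest peaks, excluding genes already labeled BGRD.  A random
#' control set of `n_top` genes is drawn without replacement from the
#' remainder.  Ranking ties break by lexicographic gene id.
#'
#' @param stats data.frame from [genePeakStats()]
#' @param turning a [TurningPoint-class] for the width cutoff
#' @param n_top number of genes per class (default 500)
#' @param seed RNG seed for the control draw (default 1)
#' @return list with elements `stats` (domain_class filled in),
#'   `bgrd`, `fgrd`, `control` (character id vectors)
#' @export
classifyDomains <- function(stats, turning, n_top = 500L, seed = 1L) {
  if (nrow(stats) == 0L) stop("empty stats")
  if (n_top > nrow(stats))
    stop("n_top exceeds number of genes")
  ord_w <- order(-stats$width_sum, stats$gene_id)
  bgrd_idx <- ord_w[seq_len(n_top)]
  bgrd_idx <- bgrd_idx[stats$width_sum[bgrd_idx] >= widthCutoff(turning)]
  ord_h <- order(-stats$height_max, stats$gene_id)
  ord_h <- setdiff(ord_h, bgrd_idx)
  fgrd_idx <- ord_h[seq_len(min(n_top, length(ord_h)))]
  rest <- setdiff(seq_len(nrow(stats)), c(bgrd_idx, fgrd_idx))
  control <- withSeed(seed,
    sample(stats$gene_id[rest], min(n_top, length(rest))))
  stats$domain_class <- "none"
  stats$domain_class[bgrd_idx] <- "BGRD"
  stats$domain_class[fgrd_idx] <- "FGRD"
  list(stats = stats, bgrd = stats$gene_id[bgrd_idx],
    fgrd = stats$gene_id[fgrd_idx], control = control)
}

#' Boundary between the two modes of the coverage distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule) over positive
#' coverage values and returns the location of the density minimum
#' between the two highest local maxima.
#'
#' @param coverages per-gene coverage values; only values > 0 are used
#' @return boundary coverage value (numeric scalar)
#' @export
coverageBoundary <- function(coverages) {
  v <- coverages[coverages > 0]
  if (length(unique(v)) < 2L)
    stop("need at least 2 distinct positive coverage values")
  d <- stats::density(v, bw = "nrd0")
  y <- d$y
  # interior local maxima
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) loc <- c(1L, loc)
  if (y[length(y)] > y[length(y) - 1]) loc <- c(loc, length(y))
  if (length(loc) < 2L)
    stop(sprintf("no boundary: coverage density is unimodal (mode at %.3g)",
      d$x[which.max(y)]))
  top2 <- sort(loc[order(-y[loc])][1:2])
  # negligible side bumps do not count as modes
  if (min(y[top2]) < 0.05 * max(y[loc]))
    stop(sprintf("no boundary: coverage density is unimodal (mode at %.3g)",
      d$x[which.max(y)]))
  seg <- seq(top2[1], top2[2])
  valley <- min(y[seg])
  # kernel wiggles do not count as modes: demand a genuine dip
  if (valley > 0.95 * min(y[top2]))
    stop(sprintf("no boundary: coverage density is unimodal (mode at %.3g)",
      d$x[which.max(y)]))
  d$x[seg[which.min(y[seg])]]
}

#' Assign gene groups a1/a2/b/c
#'
#' Group a1 is the BGRD genes themselves; the minimal BGRD gene length
#' `L*` splits the rest: a2 = long (>= L*) and high-coverage, b = long
#' and low-coverage, c = shorter than L*.  The four groups partition the
#' gene universe.
#'
#' @param stats data.frame from [genePeakStats()]
#' @param bgrd_ids character vector of BGRD gene ids (subset of stats)
#' @param boundary coverage boundary (e.g. from [coverageBoundary()])
#' @return stats with the `group` column filled in
#' @export
assignGeneGroups <- function(stats, bgrd_ids, boundary) {
  if (length(bgrd_ids) == 0L) stop("empty bgrd_ids")
  if (!all(bgrd_ids %in% stats$gene_id))
    stop("bgrd_ids not all present in stats")
  lstar <- min(stats$length[stats$gene_id %in% bgrd_ids])
  is_a1 <- stats$gene_id %in% bgrd_ids
  long <- stats$length >= lstar
  high <- stats$coverage >= boundary
  stats$group <- ifelse(is_a1, "a1",
    ifelse(long & high, "a2", ifelse(long, "b", "c")))
  attr(stats, "min_bgrd_length") <- lstar
  stats
}

#' Intron fraction of a gene
#'
#' One minus the total exon length over the gene length.
#'
#' @param gene a single gene from a gene-model GRanges
#' @return fraction in \[0, 1\]
#' @export
intronFraction <- function(gene) {
  stopifnot(length(gene) == 1L)
  e <- gene$exons[[1]]
  if (length(e) == 0L)
    stop("undefined: gene ", gene$gene_id, " has no exons")
  1 - sum(IRanges::width(e)) / width(gene)
}

#' Threshold peak caller for synthetic signal tracks
#'
#' Finds maximal runs of signal >= threshold, merges runs separated by
#' less than `merge_gap`, drops merged runs shorter than `min_width`.
#' Peak height is the maximum signal in the run.  This is plumbing for
#' simulated tracks, not a statistical peak caller.
#'
#' @param track a [SignalTrack-class]
#' @param threshold signal threshold (> 0)
#' @param min_width minimum peak width in bp (default 0)
#' @param merge_gap merge runs closer than this many bp (default 0)
#' @return a peak GRanges
#' @export
callPeaksFromSignal <- function(track, threshold, min_width = 0L,
                                merge_gap = 0L) {
  stopifnot(threshold > 0)
  step <- trackStep(track)
  out <- lapply(trackChroms(track), function(chr) {
    v <- trackValues(track)[[chr]]
    if (!length(v)) return(NULL)
    r <- rle(v >= threshold)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    ks <- starts[r$values] * step
    ke <- ends[r$values] * step
    if (!length(ks)) return(NULL)
    # merge runs closer than merge_gap
    if (length(ks) > 1L && merge_gap > 0L) {
      keep_s <- ks[1]; ms <- integer(0); me <- integer(0)
      cur_s <- ks[1]; cur_e <- ke[1]
      for (i in seq_along(ks)[-1]) {
        if (ks[i] - cur_e < merge_gap) {
          cur_e <- ke[i]
        } else {
          ms <- c(ms, cur_s); me <- c(me, cur_e)
          cur_s <- ks[i]; cur_e <- ke[i]
        }
      }
      ms <- c(ms, cur_s); me <- c(me, cur_e)
      ks <- ms; ke <- me
    }
    wide <- (ke - ks) >= min_width
    ks <- ks[wide]; ke <- ke[wide]
    if (!length(ks)) return(NULL)
    h <- vapply(seq_along(ks), function(i)
      max(v[(ks[i] / step + 1):(ke[i] / step)]), numeric(1))
    data.frame(chrom = chr, start = ks, end = ke, height = h)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(peakRanges(character(0), integer(0), integer(0), numeric(0)))
  peakRanges(out$chrom, out$start, out$end, out$height)
}
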