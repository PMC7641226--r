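#' Construct a gene model GRanges
#'
#' Genes are represented as a [GenomicRanges::GRanges] with metadata
#' columns `gene_id` (unique), `biotype` (`coding` or `lncRNA`) and
#' `exons` (an [IRanges::IRangesList], possibly empty per gene).  All
#' coordinates are 0-based half-open (BED convention): `start` is the
#' first base of the gene, `end` is one past the last.  Internally the
#' GRanges uses 1-based closed coordinates, so conversion happens here
#' and only here.
#'
#' @param gene_id character vector of unique gene identifiers
#' @param chrom chromosome names
#' @param start,end 0-based half-open coordinates (bp)
#' @param strand "+" or "-"
#' @param biotype "coding" or "lncRNA" (recycled)
#' @param exons optional list of 2-column matrices (start,end; 0-based
#'   half-open) or an IRangesList (1-based closed, used as-is)
#' @return a GRanges with the metadata columns described above
#' @examples
#' geneModels("geneA", "chr1", 100, 200, "+")
#' @export
geneModels <- function(gene_id, chrom, start, end, strand = "+",
                       biotype = "coding", exons = NULL) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_ids: ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(end <= start))
    stop("gene end must exceed start (0-based half-open); offending: ",
      paste(gene_id[end <= start], collapse = ", "))
  if (length(gene_id) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(0),
      biotype = character(0), exons = IRangesList())
    return(gr)
  }
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  if (is.null(exons)) {
    ex <- IRangesList(lapply(seq_along(gene_id), function(i) IRanges()))
  } else if (is(exons, "IRangesList") || is(exons, "CompressedIRangesList")) {
    ex <- exons
  } else {
    ex <- IRangesList(lapply(exons, function(m) {
      if (is.null(m) || NROW(m) == 0L) return(IRanges())
      IRanges(m[, 1] + 1L, m[, 2])
    }))
  }
  mcols(gr) <- DataFrame(gene_id = gene_id,
    biotype = rep_len(biotype, length(gene_id)), exons = ex)
  names(gr) <- gene_id
  validateGeneModels(gr)
  gr
}

#' Validate a gene-model GRanges
#'
#' Checks the invariants the pipeline relies on: unique ids, positive
#' lengths, exons within the gene, sorted and non-overlapping.
#'
#' @param genes a GRanges as built by [geneModels()]
#' @return the input, invisibly; stops on violation
#' @export
validateGeneModels <- function(genes) {
  stopifnot(is(genes, "GRanges"))
  need <- c("gene_id", "biotype", "exons")
  miss <- setdiff(need, colnames(mcols(genes)))
  if (length(miss))
    stop("gene models missing metadata column(s): ",
      paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_ids")
  ex <- genes$exons
  for (i in seq_along(genes)) {
    e <- ex[[i]]
    if (length(e) == 0L) next
    if (any(IRanges::start(e) < start(genes)[i]) ||
        any(IRanges::end(e) > end(genes)[i]))
      stop("exons outside gene bounds for ", genes$gene_id[i])
    if (is.unsorted(IRanges::start(e)))
      stop("exons not sorted for ", genes$gene_id[i])
    if (length(e) > 1L &&
        any(IRanges::start(e)[-1] <= IRanges::end(e)[-length(e)]))
      stop("overlapping exons for ", genes$gene_id[i])
  }
  invisible(genes)
}

#' Construct a peak GRanges
#'
#' Peaks carry a `height` metadata column (maximal read density within
#' the peak).  Coordinates are supplied 0-based half-open; width is
#' always `end - start`.
#'
#' @param chrom chromosome names
#' @param start,end 0-based half-open coordinates
#' @param height non-negative peak heights
#' @return a GRanges with a `height` metadata column
#' @examples
#' peakRanges("chr1", 1000, 5000, 3.2)
#' @export
peakRanges <- function(chrom, start, end, height) {
  if (length(chrom) == 0L)
    return(GRanges(height = numeric(0)))
  if (any(end <= start)) stop("peak end must exceed start")
  if (any(height < 0)) stop("peak height must be >= 0")
  gr <- GRanges(chrom, IRanges(start + 1L, end))
  mcols(gr)$height <- as.numeric(height)
  gr
}

# 0-based starts for reporting / BED output
bedStart <- function(gr) start(gr) - 1L
bedEnd <- function(gr) end(gr)
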