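#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame SimpleList
#' @importFrom GenomicRanges GRanges seqnames start end strand width ranges
#' @importFrom IRanges IRanges IRangesList findOverlaps
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SignalTrack: fixed-step per-chromosome signal
#'
#' Holds ChIP-Seq read density (or any non-negative signal) as one numeric
#' vector per chromosome, sampled at a fixed step in base pairs.  Value
#' `i` of a chromosome covers base pairs `[(i-1)*step, i*step)` (0-based,
#' half-open, BED convention).
#'
#' @slot values named list of numeric vectors, one per chromosome
#' @slot step integer step size in bp
#' @export
setClass("SignalTrack",
  representation(values = "list", step = "integer"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@step) != 1L || is.na(object@step) || object@step < 1L)
    msg <- c(msg, "step must be a single positive integer")
  if (is.null(names(object@values)) && length(object@values) > 0L)
    msg <- c(msg, "values must be named by chromosome")
  bad <- vapply(object@values,
    function(v) !is.numeric(v) || anyNA(v) || any(v < 0), logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("negative or NA signal on: %s",
      paste(names(object@values)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param values named list of non-negative numeric vectors (one per
#'   chromosome)
#' @param step bin size in bp
#' @return a [SignalTrack-class] object
#' @examples
#' SignalTrack(list(chr1 = rep(1, 100)), step = 10)
#' @export
SignalTrack <- function(values, step = 1L) {
  new("SignalTrack", values = values, step = as.integer(step))
}

#' @describeIn SignalTrack-class step size accessor
#' @param x a SignalTrack
#' @export
trackStep <- function(x) x@step

#' @describeIn SignalTrack-class per-chromosome value list accessor
#' @export
trackValues <- function(x) x@values

#' @describeIn SignalTrack-class chromosome names
#' @export
trackChroms <- function(x) names(x@values)

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %d chromosome(s), step %d bp\n",
    length(object@values), object@step))
  for (chr in utils::head(names(object@values), 5))
    cat(sprintf("  %s: %d bins (%.0f bp)\n", chr,
      length(object@values[[chr]]),
      length(object@values[[chr]]) * as.numeric(object@step)))
})

#' TurningPoint: knee of a ranked-width curve
#'
#' The knee ("turning point") of the sorted cumulative width curve after
#' both axes are rescaled to a common range; the derived width cutoff is
#' `multiplier` times the width at the knee.
#'
#' @slot rank_index 0-based rank of the knee in the sorted curve
#' @slot width_at_turn width value at the knee (bp)
#' @slot cutoff derived cutoff (bp)
#' @slot multiplier multiplier applied to the knee width
#' @export
setClass("TurningPoint",
  representation(rank_index = "integer", width_at_turn = "numeric",
    cutoff = "numeric", multiplier = "numeric"))

setValidity("TurningPoint", function(object) {
  msg <- character()
  if (object@rank_index < 0L) msg <- c(msg, "rank_index must be >= 0")
  if (object@multiplier >= 1 && object@cutoff < object@width_at_turn)
    msg <- c(msg, "cutoff must be >= width_at_turn when multiplier >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TurningPoint
#' @param rank_index 0-based rank position of the knee
#' @param width_at_turn width at the knee (bp)
#' @param multiplier cutoff multiplier (default 2)
#' @return a [TurningPoint-class]
#' @export
TurningPoint <- function(rank_index, width_at_turn, multiplier = 2.0) {
  new("TurningPoint", rank_index = as.integer(rank_index),
    width_at_turn = as.numeric(width_at_turn),
    cutoff = as.numeric(multiplier) * as.numeric(width_at_turn),
    multiplier = as.numeric(multiplier))
}

#' @describeIn TurningPoint-class derived width cutoff (bp)
#' @param x a TurningPoint
#' @export
widthCutoff <- function(x) x@cutoff

#' @describeIn TurningPoint-class width at the knee (bp)
#' @export
widthAtTurn <- function(x) x@width_at_turn

setMethod("show", "TurningPoint", function(object) {
  cat(sprintf(
    "TurningPoint: rank %d, width %.1f bp, cutoff %.1f bp (x%.1f)\n",
    object@rank_index, object@width_at_turn, object@cutoff,
    object@multiplier))
})

#' ProfileMatrix: per-gene signal profiles
#'
#' Rows are genes, columns are positions (bp offsets relative to the TSS
#' for TSS-anchored profiles, or bin indices for scaled-body profiles).
#' Minus-strand genes are oriented so that increasing position always
#' points into the gene body.
#'
#' @slot values genes x positions numeric matrix (rownames = gene ids)
#' @slot positions numeric vector of position labels (bin centers)
#' @slot mode "tss" or "body"
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", positions = "numeric",
    mode = "character"))

setValidity("ProfileMatrix", function(object) {
  if (ncol(object@values) != length(object@positions))
    return("positions length must equal number of columns")
  TRUE
})

#' @describeIn ProfileMatrix-class per-position mean over genes
#' @param x a ProfileMatrix
#' @export
meanProfile <- function(x) colMeans(x@values)

#' @describeIn ProfileMatrix-class the genes x positions matrix
#' @export
profileValues <- function(x) x@values

#' @describeIn ProfileMatrix-class position labels
#' @export
profilePositions <- function(x) x@positions

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix (%s): %d genes x %d positions\n",
    object@mode, nrow(object@values), ncol(object@values)))
})

#' WidthMatrix: genes x samples BGRD width matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `widths`
#' (bp of summed H3K27me3 peak width per gene and sample) and `bgrd_mask`
#' (logical, per-sample BGRD membership).  `colData$label` holds the
#' sample condition (`normal`/`cancer`, or NA); `rowData` carries the
#' per-gene `conservation` (row mean of the mask) and `max_width`
#' (row max of widths).
#'
#' @export
setClass("WidthMatrix", contains = "SummarizedExperiment")

setValidity("WidthMatrix", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("widths", "bgrd_mask") %in% a))
    return("assays 'widths' and 'bgrd_mask' are required")
  w <- SummarizedExperiment::assay(object, "widths")
  if (any(w < 0)) msg <- c(msg, "widths must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("conservation", "max_width") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry conservation and max_width")
  else {
    cons <- rd$conservation
    if (any(cons < 0 | cons > 1)) msg <- c(msg, "conservation outside [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn WidthMatrix-class the widths assay
#' @param x a WidthMatrix
#' @export
widthValues <- function(x) SummarizedExperiment::assay(x, "widths")

#' @describeIn WidthMatrix-class the per-sample BGRD membership mask
#' @export
bgrdMask <- function(x) SummarizedExperiment::assay(x, "bgrd_mask")

#' @describeIn WidthMatrix-class per-gene conservation (fraction of
#'   samples with a BGRD)
#' @export
conservation <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$conservation, rownames(x))
}

#' @describeIn WidthMatrix-class per-gene maximum width across samples
#' @export
maxWidth <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$max_width, rownames(x))
}

#' @describeIn WidthMatrix-class sample condition labels
#' @export
sampleLabels <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$label),
    colnames(x))
}

setMethod("show", "WidthMatrix", function(object) {
  lab <- SummarizedExperiment::colData(object)$label
  cat(sprintf("WidthMatrix: %d genes x %d samples (%s)\n",
    nrow(object), ncol(object),
    paste(sprintf("%s=%d", names(table(lab)), table(lab)), collapse = ", ")))
  cons <- SummarizedExperiment::rowData(object)$conservation
  cat(sprintf("  conservation: median %.2f, %d gene(s) fully conserved\n",
    stats::median(cons), sum(cons == 1)))
})

#' PanelSelection: forward-selected optimal reference panel
#'
#' @slot ranked_sample_ids samples sorted by ascending single-sample
#'   enrichment P
#' @slot p_single per-sample enrichment P (same order)
#' @slot p_curve enrichment P of the cumulative union at each panel size k
#' @slot chosen_k selected panel size
#' @slot rule "argmin" or "threshold"
#' @export
setClass("PanelSelection",
  representation(ranked_sample_ids = "character", p_single = "numeric",
    p_curve = "numeric", chosen_k = "integer", rule = "character"))

setValidity("PanelSelection", function(object) {
  msg <- character()
  k <- object@chosen_k
  if (k < 1L || k > length(object@p_curve))
    msg <- c(msg, "chosen_k out of range")
  if (length(object@p_curve) != length(object@ranked_sample_ids))
    msg <- c(msg, "p_curve and ranked_sample_ids lengths differ")
  if (length(msg)) msg else TRUE
})

#' @describeIn PanelSelection-class the selected sample ids
#' @param x a PanelSelection
#' @export
chosenPanel <- function(x) x@ranked_sample_ids[seq_len(x@chosen_k)]

#' @describeIn PanelSelection-class selected panel size
#' @export
chosenK <- function(x) x@chosen_k

#' @describeIn PanelSelection-class P value curve over panel sizes
#' @export
pCurve <- function(x) x@p_curve

setMethod("show", "PanelSelection", function(object) {
  cat(sprintf(
    "PanelSelection: %d samples ranked, chosen k = %d (%s), p = %.3g\n",
    length(object@ranked_sample_ids), object@chosen_k, object@rule,
    object@p_curve[object@chosen_k]))
})

#' MockNull: label-shuffle null for cohort differential calls
#'
#' @slot n_reps number of label shuffles
#' @slot seed RNG seed used
#' @slot mean_shortened mean shortened-call count over shuffles
#' @slot sd_shortened sd of shortened-call counts
#' @slot mean_lengthened mean lengthened-call count
#' @slot sd_lengthened sd of lengthened-call counts
#' @slot counts n_reps x 2 matrix of raw per-rep counts
#' @export
setClass("MockNull",
  representation(n_reps = "integer", seed = "integer",
    mean_shortened = "numeric", sd_shortened = "numeric",
    mean_lengthened = "numeric", sd_lengthened = "numeric",
    counts = "matrix"))

setValidity("MockNull", function(object) {
  msg <- character()
  if (object@n_reps < 1L) msg <- c(msg, "n_reps must be >= 1")
  if (object@mean_shortened < 0 || object@mean_lengthened < 0)
    msg <- c(msg, "mean counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MockNull", function(object) {
  cat(sprintf(
    "MockNull (%d shuffles, seed %d): shortened %.2f +/- %.2f, lengthened %.2f +/- %.2f\n",
    object@n_reps, object@seed, object@mean_shortened, object@sd_shortened,
    object@mean_lengthened, object@sd_lengthened))
})
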