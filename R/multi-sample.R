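# Per-sample BGRD membership from a width vector under a rule.
# top_n: the n broadest genes with nonzero width; cutoff: width >= bp.
applyBgrdRule <- function(widths, gene_ids, bgrd_rule) {
  if (!is.null(bgrd_rule$top_n)) {
    n <- min(bgrd_rule$top_n, length(widths))
    ord <- order(-widths, gene_ids)
    mask <- logical(length(widths))
    mask[ord[seq_len(n)]] <- TRUE
    mask & widths > 0
  } else if (!is.null(bgrd_rule$cutoff)) {
    widths >= bgrd_rule$cutoff
  } else {
    stop("bgrd_rule must be list(top_n = n) or list(cutoff = bp)")
  }
}

# Assemble a WidthMatrix from a widths matrix + labels + rule.
newWidthMatrix <- function(widths, labels, bgrd_rule) {
  mask <- vapply(seq_len(ncol(widths)), function(j)
    applyBgrdRule(widths[, j], rownames(widths), bgrd_rule),
    logical(nrow(widths)))
  dimnames(mask) <- dimnames(widths)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(widths = widths, bgrd_mask = mask),
    rowData = DataFrame(conservation = rowMeans(mask),
      max_width = apply(widths, 1, max)),
    colData = DataFrame(label = unname(labels[colnames(widths)]),
      row.names = colnames(widths)))
  out <- new("WidthMatrix", se)
  metadata(out)$bgrd_rule <- bgrd_rule
  out
}

#' Build the genes x samples BGRD width matrix
#'
#' Collects per-sample gene statistics into a dense width matrix and
#' derives per-sample BGRD membership, per-gene conservation (fraction
#' of samples with a BGRD) and maximum width.  Genes absent from a
#' sample's statistics would break alignment: all samples must share the
#' gene universe.
#'
#' @param per_sample_stats named list of data.frames from
#'   [genePeakStats()], one per sample
#' @param bgrd_rule `list(top_n = 500)` (the n broadest genes with
#'   nonzero width per sample) or `list(cutoff = bp)` (absolute width
#'   cutoff)
#' @param labels optional named character of sample conditions
#'   (`normal` / `cancer`)
#' @return a [WidthMatrix-class]
#' @export
buildWidthMatrix <- function(per_sample_stats,
                             bgrd_rule = list(top_n = 500L),
                             labels = NULL) {
  stopifnot(length(per_sample_stats) >= 1, !is.null(names(per_sample_stats)))
  ids <- per_sample_stats[[1]]$gene_id
  for (s in names(per_sample_stats)) {
    sid <- per_sample_stats[[s]]$gene_id
    if (!setequal(sid, ids)) {
      miss <- c(setdiff(ids, sid), setdiff(sid, ids))
      stop("alignment error: sample ", s, " gene universe differs; e.g. ",
        paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  widths <- vapply(per_sample_stats, function(st)
    st$width_sum[match(ids, st$gene_id)], numeric(length(ids)))
  rownames(widths) <- ids
  if (is.null(labels))
    labels <- stats::setNames(rep(NA_character_,
      length(per_sample_stats)), names(per_sample_stats))
  newWidthMatrix(widths, labels, bgrd_rule)
}

#' Quantile-normalize widths to a reference sample
#'
#' Each non-reference sample's value at within-sample rank r is replaced
#' by the reference sample's order statistic at rank r; tied values
#' receive the mean of the reference order statistics their ranks span.
#' The reference column is unchanged, within-sample ranking is
#' preserved, and the operation is idempotent.
#'
#' By default the BGRD mask is kept as derived from the observed
#' (pre-normalization) widths: normalization forces the reference's
#' width distribution onto every sample, so re-deriving membership
#' under an absolute cutoff afterwards would hallucinate domains in a
#' sample that truly has fewer broad domains than the reference.  Set
#' `remask = TRUE` to re-derive the mask from the normalized widths
#' under the stored rule.
#'
#' @param x a [WidthMatrix-class]
#' @param reference_sample sample id of the reference column
#' @param remask re-derive the BGRD mask from normalized widths
#'   (default FALSE)
#' @return a [WidthMatrix-class] with normalized widths
#' @export
quantileNormalizeToReference <- function(x, reference_sample,
                                         remask = FALSE) {
  w <- widthValues(x)
  if (!reference_sample %in% colnames(w))
    stop("reference sample not found: ", reference_sample)
  ref <- w[, reference_sample]
  if (all(ref == 0)) stop("degenerate reference: all widths are zero")
  rs <- sort(ref)
  for (j in setdiff(colnames(w), reference_sample)) {
    v <- w[, j]
    ord <- order(v)
    out <- numeric(length(v))
    # walk tied groups in sorted order; group spanning ranks i..k gets
    # the mean of the reference order statistics rs[i..k]
    i <- 1L
    while (i <= length(v)) {
      k <- i
      while (k < length(v) && v[ord[k + 1L]] == v[ord[i]]) k <- k + 1L
      out[ord[i:k]] <- mean(rs[i:k])
      i <- k + 1L
    }
    w[, j] <- out
  }
  if (remask)
    return(newWidthMatrix(w, sampleLabels(x), metadata(x)$bgrd_rule))
  mask <- bgrdMask(x)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(widths = w, bgrd_mask = mask),
    rowData = DataFrame(conservation = rowMeans(mask),
      max_width = apply(w, 1, max)),
    colData = SummarizedExperiment::colData(x))
  out <- new("WidthMatrix", se)
  metadata(out)$bgrd_rule <- metadata(x)$bgrd_rule
  out
}

#' Conservation level versus maximum BGRD width
#'
#' Pairs each gene's conservation (fraction of samples with a BGRD) with
#' its maximum width across samples and reports their Spearman rank
#' correlation.  With constant vectors the correlation is undefined and
#' returned as NA.
#'
#' @param x a [WidthMatrix-class] with >= 2 samples
#' @return list with `conservation`, `max_width` (named vectors) and
#'   `rho`
#' @export
conservationVsWidth <- function(x) {
  stopifnot(ncol(x) >= 2)
  cons <- conservation(x)
  mw <- maxWidth(x)
  rho <- if (stats::sd(cons) == 0 || stats::sd(mw) == 0) NA_real_
    else stats::cor(cons, mw, method = "spearman")
  list(conservation = cons, max_width = mw, rho = rho)
}

#' Forward selection of an optimal reference panel
#'
#' Samples are ranked by the enrichment P value of their BGRD gene set
#' in the category (ascending, ties by sample id).  For each panel size
#' k the union of the top-k BGRD sets is scored again; the panel size
#' minimizing this P curve is chosen (`rule = "argmin"`, ties toward
#' smaller k).  With `rule = "threshold"` the panel instead grows until
#' the union P first exceeds the single best sample's P.
#'
#' @param per_sample_bgrd_sets named list of character id vectors
#' @param category gene set list or character ids
#' @param universe gene set list or character ids
#' @param rule "argmin" (default) or "threshold"
#' @return a [PanelSelection-class]
#' @export
forwardDatasetSelection <- function(per_sample_bgrd_sets, category,
                                    universe,
                                    rule = c("argmin", "threshold")) {
  rule <- match.arg(rule)
  cat_ids <- if (is.list(category)) category$gene_ids else category
  uni_ids <- if (is.list(universe)) universe$gene_ids else universe
  cat_ids <- intersect(cat_ids, uni_ids)
  if (!length(cat_ids)) stop("empty category")
  stopifnot(length(per_sample_bgrd_sets) >= 1)
  scoreSet <- function(ids) {
    ids <- intersect(ids, uni_ids)
    hypergeomEnrichment(length(intersect(ids, cat_ids)), length(ids),
      length(cat_ids), length(uni_ids))$p
  }
  p1 <- vapply(per_sample_bgrd_sets, scoreSet, numeric(1))
  ord <- order(p1, names(per_sample_bgrd_sets))
  ranked <- names(per_sample_bgrd_sets)[ord]
  acc <- character(0)
  p_curve <- numeric(length(ranked))
  for (k in seq_along(ranked)) {
    acc <- union(acc, per_sample_bgrd_sets[[ranked[k]]])
    p_curve[k] <- scoreSet(acc)
  }
  chosen <- if (rule == "argmin") {
    which(p_curve == min(p_curve))[1]
  } else {
    worse <- which(p_curve > p_curve[1])
    if (length(worse)) max(1L, worse[1] - 1L) else length(p_curve)
  }
  new("PanelSelection", ranked_sample_ids = ranked,
    p_single = p1[ord], p_curve = p_curve,
    chosen_k = as.integer(chosen), rule = rule)
}
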