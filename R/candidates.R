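# Shared filter-cascade engine for candidate nomination.  Flags:
#   recurrent_bgrd: BGRD in >= min_panel_count panel samples
#   not_mut_driver: mutation Q absent or >= q_cutoff (NULL table: all TRUE)
#   expressed:      expression strictly above the median of the table
#   shortened:      width change vs the panel mean per `direction`
candidateCascade <- function(panel, sample_widths, expression,
                             mutation_q = NULL, min_panel_count = 2L,
                             shrink_frac = 0.5, min_shrink_bp = 0,
                             direction = c("shortened", "lengthened"),
                             biotype = NULL, genes = NULL) {
  direction <- match.arg(direction)
  if (is.null(expression) || !length(expression))
    stop("empty expression table")
  ids <- rownames(widthValues(panel))
  if (!is.null(biotype)) {
    if (is.null(genes))
      stop("gene models required to filter by biotype")
    keep <- genes$gene_id[genes$biotype == biotype]
    ids <- intersect(ids, keep)
  }
  panel_count <- rowSums(bgrdMask(panel))[ids]
  panel_mean <- rowMeans(widthValues(panel))[ids]  # zeros included
  sw <- sample_widths[ids]
  sw[is.na(sw)] <- 0
  expr_median <- stats::median(expression)
  expr <- expression[ids]
  recurrent <- panel_count >= min_panel_count
  # genes missing from the Q table have no driver evidence -> TRUE
  not_driver <- if (is.null(mutation_q)) rep(TRUE, length(ids)) else {
    q <- mutation_q[ids]
    is.na(q) | q >= attr(mutation_q, "q_cutoff")
  }
  expressed <- !is.na(expr) & expr > expr_median
  changed <- if (direction == "shortened") {
    sw <= (1 - shrink_frac) * panel_mean &
      (panel_mean - sw) >= min_shrink_bp
  } else {
    sw >= (1 + shrink_frac) * panel_mean & panel_mean > 0
  }
  out <- data.frame(gene_id = ids,
    panel_bgrd_count = unname(panel_count),
    panel_mean_width = unname(panel_mean),
    sample_width = unname(sw),
    expression = unname(expr),
    recurrent_bgrd = unname(recurrent),
    not_mut_driver = unname(not_driver),
    expressed = unname(expressed),
    shortened = unname(changed),
    stringsAsFactors = FALSE)
  if (!is.null(mutation_q)) out$mutation_q <- unname(mutation_q[ids])
  out$is_candidate <- out$recurrent_bgrd & out$not_mut_driver &
    out$expressed & out$shortened
  out
}

#' Nominate candidate tumor-promoting genes
#'
#' A gene is a candidate when it (1) carries a BGRD in at least
#' `min_panel_count` reference-panel samples, (2) has no known driver
#' mutation signal (mutation Q value absent or at least `q_cutoff`),
#' (3) is expressed above the median of all genes in the expression
#' table, and (4) has its H3K27me3 width in the cancer sample at most
#' `1 - shrink_frac` of the panel mean width (mean over all panel
#' samples, zeros included).  All boundary comparisons for "at least"
#' are inclusive; "higher than median" is strict.
#'
#' @param panel a [WidthMatrix-class] of reference samples
#' @param sample_widths named numeric, gene -> width (bp) in the cancer
#'   sample
#' @param expression named numeric, gene -> expression
#' @param mutation_q named numeric, gene -> driver Q value (genes
#'   absent from the table count as non-drivers); NULL to skip the
#'   filter
#' @param min_panel_count minimum panel samples with a BGRD (default 2)
#' @param q_cutoff minimum Q value to count as non-driver (default 0.5)
#' @param shrink_frac required fractional width loss (default 0.5)
#' @return data.frame with the evidence columns, one flag per filter,
#'   and `is_candidate` (the conjunction)
#' @export
candidateGenes <- function(panel, sample_widths, expression,
                           mutation_q = NULL, min_panel_count = 2L,
                           q_cutoff = 0.5, shrink_frac = 0.5) {
  if (!is.null(mutation_q)) attr(mutation_q, "q_cutoff") <- q_cutoff
  candidateCascade(panel, sample_widths, expression, mutation_q,
    min_panel_count, shrink_frac, min_shrink_bp = 0,
    direction = "shortened")
}

#' Nominate candidate tumor-promoting lncRNAs
#'
#' As [candidateGenes()] restricted to lncRNA biotype and without the
#' mutation filter, but the width loss must satisfy BOTH the fractional
#' rule (sample width at most `1 - shrink_frac` of the panel mean) and
#' an absolute rule (panel mean minus sample width at least
#' `min_shrink_bp`); both boundaries inclusive.
#'
#' @param panel a [WidthMatrix-class]
#' @param sample_widths named numeric, gene -> width (bp)
#' @param expression named numeric, gene -> expression
#' @param genes gene-model GRanges carrying biotypes
#' @param min_panel_count minimum panel samples with a BGRD (default 2)
#' @param shrink_frac required fractional width loss (default 0.5)
#' @param min_shrink_bp required absolute width loss (default 20000)
#' @return data.frame as [candidateGenes()]
#' @export
candidateLncRNAs <- function(panel, sample_widths, expression, genes,
                             min_panel_count = 2L, shrink_frac = 0.5,
                             min_shrink_bp = 20000) {
  candidateCascade(panel, sample_widths, expression, mutation_q = NULL,
    min_panel_count, shrink_frac, min_shrink_bp,
    direction = "shortened", biotype = "lncRNA", genes = genes)
}

#' Lengthened-BGRD control gene set
#'
#' Mirror of [candidateGenes()]: the width in the cancer sample must be
#' at least `1 + grow_frac` times the panel mean width (inclusive); all
#' other filters are identical.  Disjoint from the shortened candidates
#' for any input.
#'
#' @param panel a [WidthMatrix-class]
#' @param sample_widths named numeric, gene -> width (bp)
#' @param expression named numeric, gene -> expression
#' @param mutation_q named numeric or NULL
#' @param min_panel_count minimum panel samples with a BGRD (default 2)
#' @param q_cutoff minimum Q value to count as non-driver (default 0.5)
#' @param grow_frac required fractional width gain (default 0.5)
#' @return data.frame as [candidateGenes()]
#' @export
lengthenedControls <- function(panel, sample_widths, expression,
                               mutation_q = NULL, min_panel_count = 2L,
                               q_cutoff = 0.5, grow_frac = 0.5) {
  if (!is.null(mutation_q)) attr(mutation_q, "q_cutoff") <- q_cutoff
  candidateCascade(panel, sample_widths, expression, mutation_q,
    min_panel_count, shrink_frac = grow_frac, min_shrink_bp = 0,
    direction = "lengthened")
}
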