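#' Pairwise shortened / lengthened BGRD calls
#'
#' Per-gene width change `delta = test - ref` (widths should be
#' quantile-normalized beforehand).  The magnitudes of decreases and of
#' increases each form an L-shaped cumulative curve; each tail gets its
#' own turning point and a gene is called shortened when its decrease
#' reaches `multiplier` times the shortened-tail turn value (lengthened
#' analogously).  With `cap = TRUE` only the `n_top` most extreme calls
#' per class are kept.  A degenerate tail (no decreases at all) yields
#' zero calls of that class.
#'
#' @param widths_ref,widths_test named numeric vectors (gene -> bp) on
#'   the same gene universe
#' @param multiplier cutoff multiplier on the turn value (default 2)
#' @param n_top per-class cap (default 350)
#' @param cap apply the cap (default TRUE)
#' @return data.frame: gene_id, delta_width, class (shortened /
#'   lengthened / unchanged); attributes `turn_shortened`,
#'   `turn_lengthened` carry the tail turn values
#' @export
pairwiseDifferential <- function(widths_ref, widths_test,
                                 multiplier = 2.0, n_top = 350L,
                                 cap = TRUE) {
  if (!setequal(names(widths_ref), names(widths_test)))
    stop("gene universes differ between ref and test")
  widths_test <- widths_test[names(widths_ref)]
  delta <- widths_test - widths_ref
  tailCalls <- function(mag) {
    # mag: per-gene magnitude of change in one direction (>= 0)
    turn <- tryCatch(widthAtTurn(findTurningPoint(mag, multiplier)),
      error = function(e) NA_real_)
    if (is.na(turn)) return(list(called = logical(length(mag)), turn = NA))
    # a zero turn value (perfect right angle) must not call unchanged genes
    list(called = mag >= multiplier * turn & mag > 0, turn = turn)
  }
  sh <- tailCalls(pmax(-delta, 0))
  ln <- tailCalls(pmax(delta, 0))
  cls <- rep("unchanged", length(delta))
  cls[sh$called] <- "shortened"
  cls[ln$called & cls == "unchanged"] <- "lengthened"
  out <- data.frame(gene_id = names(delta), delta_width = unname(delta),
    class = cls, stringsAsFactors = FALSE)
  if (cap) {
    for (cl in c("shortened", "lengthened")) {
      idx <- which(out$class == cl)
      if (length(idx) > n_top) {
        keep <- idx[order(-abs(out$delta_width[idx]))[seq_len(n_top)]]
        out$class[setdiff(idx, keep)] <- "unchanged"
      }
    }
  }
  attr(out, "turn_shortened") <- sh$turn
  attr(out, "turn_lengthened") <- ln$turn
  out
}

#' Cohort-level shortened / lengthened BGRD calls
#'
#' Per gene, the difference in mean width (cancer minus normal) and the
#' difference in BGRD conservation level between the two label classes.
#' Shortened requires both the width drop to exceed `min_delta_width`
#' and the conservation drop to exceed `min_delta_conservation`
#' (strictly); lengthened is symmetric.
#'
#' @param x a [WidthMatrix-class] with both `normal` and `cancer` labels
#' @param min_delta_width minimum |mean width difference| in bp
#'   (default 5000)
#' @param min_delta_conservation minimum |conservation difference|
#'   (default 0.3)
#' @return data.frame: gene_id, delta_width, delta_conservation, class
#' @export
cohortDifferential <- function(x, min_delta_width = 5000,
                               min_delta_conservation = 0.3) {
  lab <- sampleLabels(x)
  norm <- which(lab == "normal")
  canc <- which(lab == "cancer")
  if (!length(norm) || !length(canc))
    stop("need both normal and cancer samples")
  cohortDeltas(widthValues(x), bgrdMask(x), norm, canc,
    min_delta_width, min_delta_conservation)
}

# Vectorized core shared by cohortDifferential and mockShuffle.
cohortDeltas <- function(w, m, norm, canc, min_dw, min_dc) {
  dw <- rowMeans(w[, canc, drop = FALSE]) -
    rowMeans(w[, norm, drop = FALSE])
  dc <- rowMeans(m[, canc, drop = FALSE]) -
    rowMeans(m[, norm, drop = FALSE])
  cls <- rep("unchanged", nrow(w))
  cls[dw < -min_dw & dc < -min_dc] <- "shortened"
  cls[dw > min_dw & dc > min_dc] <- "lengthened"
  data.frame(gene_id = rownames(w), delta_width = unname(dw),
    delta_conservation = unname(dc), class = cls,
    stringsAsFactors = FALSE)
}

#' Label-shuffle null for cohort differential calls
#'
#' Sample labels are permuted (class sizes preserved), the cohort
#' comparison is rerun, and the per-class call counts are summarized as
#' mean and SD over replicates.
#'
#' @param x a [WidthMatrix-class] with normal/cancer labels
#' @param n_reps number of shuffles (default 1000)
#' @param seed RNG seed
#' @param ... passed to [cohortDifferential()]
#' @return a [MockNull-class]
#' @export
mockShuffle <- function(x, n_reps = 1000L, seed = 1L, ...) {
  lab <- sampleLabels(x)
  if (!all(c("normal", "cancer") %in% lab))
    stop("need both normal and cancer samples")
  w <- widthValues(x)
  m <- bgrdMask(x)
  args <- list(...)
  min_dw <- args$min_delta_width %||% 5000
  min_dc <- args$min_delta_conservation %||% 0.3
  counts <- withSeed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      perm <- sample(lab)
      calls <- cohortDeltas(w, m, which(perm == "normal"),
        which(perm == "cancer"), min_dw, min_dc)
      c(shortened = sum(calls$class == "shortened"),
        lengthened = sum(calls$class == "lengthened"))
    }, numeric(2)))
  })
  new("MockNull", n_reps = as.integer(n_reps), seed = as.integer(seed),
    mean_shortened = mean(counts[, "shortened"]),
    sd_shortened = stats::sd(counts[, "shortened"]),
    mean_lengthened = mean(counts[, "lengthened"]),
    sd_lengthened = stats::sd(counts[, "lengthened"]),
    counts = counts)
}

#' Enrichment of a gene category in differential calls
#'
#' Scores the shortened and the lengthened call sets separately with
#' [hypergeomEnrichment()], and reports the shortened-to-lengthened
#' count ratio.
#'
#' @param calls data.frame from [cohortDifferential()] or
#'   [pairwiseDifferential()]
#' @param category gene set list or character ids
#' @param universe gene set list or character ids
#' @return list with per-class elements (`n`, `observed`, `fold`, `p`;
#'   NULL for an empty class) and `shortened_to_lengthened_ratio`
#' @export
differentialEnrichment <- function(calls, category, universe) {
  cat_ids <- if (is.list(category)) category$gene_ids else category
  uni_ids <- if (is.list(universe)) universe$gene_ids else universe
  cat_ids <- intersect(cat_ids, uni_ids)
  scoreClass <- function(cl) {
    ids <- intersect(calls$gene_id[calls$class == cl], uni_ids)
    if (!length(ids)) {
      message("class ", cl, " is empty; skipped")
      return(NULL)
    }
    obs <- length(intersect(ids, cat_ids))
    e <- hypergeomEnrichment(obs, length(ids), length(cat_ids),
      length(uni_ids))
    list(n = length(ids), observed = obs, fold = e$fold, p = e$p)
  }
  n_s <- sum(calls$class == "shortened")
  n_l <- sum(calls$class == "lengthened")
  list(shortened = scoreClass("shortened"),
    lengthened = scoreClass("lengthened"),
    shortened_to_lengthened_ratio = if (n_l > 0) n_s / n_l else NA_real_)
}
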