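# Hand-built fixture: a 4-sample reference panel over 20 genes, with
# each filter boundary exercised by a dedicated gene.  Panel mean width
# is over all 4 samples, zeros included.
candidateFixture <- function() {
  ids <- sprintf("g%02d", 1:20)
  base <- c(
    2e5,  # g01: the intended candidate (all filters pass)
    2e5,  # g02: BGRD in one sample only
    2e5,  # g03: driver mutation (q 0.4)
    2e5,  # g04: q exactly at the 0.5 cutoff (kept: inclusive)
    2e5,  # g05: expression below median
    2e5,  # g06: expression exactly at the median (strict >, rejected)
    2e5,  # g07: width exactly 50% of panel mean (kept: inclusive)
    2e5,  # g08: width just above 50% of panel mean (rejected)
    2e5,  # g09: lengthened, exactly 1.5x mean (kept in controls)
    2e5,  # g10: lengthened, just below 1.5x mean (rejected)
    rep(0, 10))  # g11-g20: no panel BGRD at all
  w <- matrix(rep(base, 4), ncol = 4,
    dimnames = list(ids, sprintf("p%d", 1:4)))
  w["g02", 2:4] <- 0  # BGRD in a single sample
  st <- lapply(seq_len(ncol(w)), function(j)
    data.frame(gene_id = ids, width_sum = w[, j]))
  names(st) <- colnames(w)
  panel <- buildWidthMatrix(st, bgrd_rule = list(cutoff = 1e4))
  pm <- rowMeans(w)  # g01 2e5 ... g02 5e4
  sample_widths <- stats::setNames(rep(1e4, 20), ids)
  sample_widths["g01"] <- 0.4 * pm["g01"]   # clearly shortened
  sample_widths["g02"] <- 0.4 * pm["g02"]
  sample_widths["g03"] <- 0.4 * pm["g03"]
  sample_widths["g04"] <- 0.4 * pm["g04"]
  sample_widths["g05"] <- 0.4 * pm["g05"]
  sample_widths["g06"] <- 0.4 * pm["g06"]
  sample_widths["g07"] <- 0.5 * pm["g07"]   # inclusive boundary
  sample_widths["g08"] <- 0.5 * pm["g08"] + 1
  sample_widths["g09"] <- 1.5 * pm["g09"]   # inclusive boundary
  sample_widths["g10"] <- 1.5 * pm["g10"] - 1
  expression <- stats::setNames(rep(1, 20), ids)  # median is 1
  expression[c("g01", "g02", "g03", "g04", "g07", "g08", "g09",
    "g10")] <- 5
  expression["g06"] <- 1  # exactly the median
  mutation_q <- c(g03 = 0.4, g04 = 0.5, g01 = 0.9)
  list(panel = panel, sample_widths = sample_widths,
    expression = expression, mutation_q = mutation_q)
}
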