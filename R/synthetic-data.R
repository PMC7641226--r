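#' Synthetic study specification
#'
#' Bundles every parameter of the synthetic genome / panel / cohort
#' generators.  Identical spec and seed produce identical outputs; all
#' generator functions draw their randomness from `seed` plus a fixed
#' per-stage offset, so the individual stages are independently
#' reproducible.
#'
#' The defaults describe the study conditions the generators emulate: a
#' minority of long genes carrying broad promoter-plus-body repression
#' domains of 60-90% gene coverage, a minority of genes with tall
#' narrow promoter peaks, short background noise peaks, a multi-sample
#' panel sharing a conserved core of broad domains, and cancer samples
#' that are modified copies of normals in which a planted subset of
#' core domains collapses to a few percent of its width.
#'
#' @param seed master RNG seed
#' @param n_genes number of genes
#' @param chrom chromosome name
#' @param chrom_length chromosome length (bp)
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (bp).  The spread is kept moderate so the ranked-width
#'   curve keeps a single well-defined corner; see the methods vignette.
#' @param frac_bgrd fraction of genes planted with broad domains
#' @param frac_fgrd fraction planted with focal tall promoter peaks
#' @param frac_lncrna fraction of genes labeled lncRNA
#' @param bgrd_cov_range (low, high) fraction of the gene covered by the
#'   planted broad domain
#' @param fgrd_width focal peak width (bp)
#' @param fgrd_height_boost focal peak height multiplier over broad-peak
#'   heights
#' @param noise_peak_rate background peaks per Mb
#' @param expression_baseline,expression_coupling,expression_noise_sd
#'   log-expression model: baseline - coupling x coverage + noise
#' @param track_step signal track bin size (bp)
#' @param n_samples panel size
#' @param conserved_core_frac fraction of planted broad domains shared
#'   by every panel sample
#' @param noncore_presence_prob per-sample presence probability of
#'   non-core planted domains
#' @param n_normal,n_cancer cohort sizes
#' @param shorten_frac fraction of core domains shortened in cancer
#' @param shorten_factor width multiplier for shortened domains (< 1)
#' @param lengthen_frac fraction (of core size) of non-planted genes
#'   gaining a broad domain in cancer
#' @return a list of class `synthetic_spec`
#' @export
syntheticSpec <- function(seed = 1L, n_genes = 2000L, chrom = "chrS",
    chrom_length = 3e8, gene_length_meanlog = log(3e4),
    gene_length_sdlog = 0.3, frac_bgrd = 0.2, frac_fgrd = 0.1,
    frac_lncrna = 0.15, bgrd_cov_range = c(0.6, 0.9), fgrd_width = 2000L,
    fgrd_height_boost = 5, noise_peak_rate = 2,
    expression_baseline = 2, expression_coupling = 2,
    expression_noise_sd = 0.5, track_step = 100L, n_samples = 10L,
    conserved_core_frac = 0.6, noncore_presence_prob = 0.95,
    n_normal = 10L, n_cancer = 8L, shorten_frac = 0.1,
    shorten_factor = 0.05, lengthen_frac = 0.05) {
  spec <- as.list(environment())
  fr <- c("frac_bgrd", "frac_fgrd", "frac_lncrna", "conserved_core_frac",
    "noncore_presence_prob", "shorten_frac", "lengthen_frac")
  for (f in fr) if (spec[[f]] < 0 || spec[[f]] > 1)
    stop(f, " must be in [0, 1]")
  if (shorten_factor >= 1) stop("shorten_factor must be < 1")
  stopifnot(bgrd_cov_range[1] > 0, bgrd_cov_range[2] <= 1,
    bgrd_cov_range[1] <= bgrd_cov_range[2])
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic genome
#'
#' Places `n_genes` non-overlapping genes of log-normal length uniformly
#' on one chromosome with random strands.  Exon count grows with gene
#' length while exon sizes stay in the 100-400 bp range, so the intron
#' fraction of a gene increases with its length.
#'
#' @param spec a [syntheticSpec()]
#' @return a gene-model GRanges
#' @export
makeGenome <- function(spec) {
  withSeed(spec$seed, {
    n <- spec$n_genes
    if (n == 0L)
      return(geneModels(character(0), character(0), integer(0), integer(0)))
    len <- round(stats::rlnorm(n, spec$gene_length_meanlog,
      spec$gene_length_sdlog))
    len <- pmax(len, 1000L)
    if (sum(len) > spec$chrom_length / 2)
      stop("capacity error: genes cannot be packed into half the chromosome")
    slack <- spec$chrom_length - sum(len)
    gaps <- stats::runif(n + 1L)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(c(gaps[1], len[-n] + gaps[2:n]))
    ends <- starts + len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    biotype <- ifelse(stats::runif(n) < spec$frac_lncrna, "lncRNA",
      "coding")
    exons <- lapply(seq_len(n), function(i) {
      L <- len[i]
      n_ex <- 1L + stats::rpois(1, log10(L))
      seg <- L / n_ex
      es <- integer(0); ee <- integer(0)
      for (k in seq_len(n_ex)) {
        sz <- min(floor(stats::runif(1, 100, 400)), floor(seg))
        off <- floor(stats::runif(1, 0, seg - sz))
        es <- c(es, starts[i] + floor((k - 1) * seg) + off)
        ee <- c(ee, starts[i] + floor((k - 1) * seg) + off + sz)
      }
      cbind(es, ee)
    })
    geneModels(sprintf("g%04d", seq_len(n)), spec$chrom, starts, ends,
      strand, biotype, exons)
  })
}

#' Choose the planted BGRD and FGRD gene sets
#'
#' Broad domains go to the longest `frac_bgrd` fraction of genes
#' (broad repression domains sit on long genes); focal peaks go to a
#' random `frac_fgrd` fraction of the remainder.
#'
#' @param genes gene-model GRanges from [makeGenome()]
#' @param spec a [syntheticSpec()]
#' @return list with `bgrd` and `fgrd` character id vectors
#' @export
choosePlantedDomains <- function(genes, spec) {
  np <- round(spec$frac_bgrd * length(genes))
  nf <- round(spec$frac_fgrd * length(genes))
  ord <- order(-width(genes), genes$gene_id)
  bgrd <- genes$gene_id[ord[seq_len(np)]]
  rest <- setdiff(genes$gene_id, bgrd)
  fgrd <- withSeed(spec$seed + 1L, sample(rest, nf))
  list(bgrd = bgrd, fgrd = fgrd)
}

# Build the peak set for one planted broad domain: a 2 kb promoter peak
# at the (strand-aware) TSS plus ~8 kb body tiles spaced to reach the
# target total width = coverage x gene length (scaled by cov_scale).
broadDomainPeaks <- function(gene, cov, height) {
  chr <- as.character(seqnames(gene))
  s0 <- start(gene) - 1L
  e0 <- end(gene)
  L <- e0 - s0
  minus <- as.character(strand(gene)) == "-"
  total <- round(cov * L)
  if (total <= 0)
    return(NULL)
  prom_w <- min(2000L, total)
  if (minus) {
    prom <- c(e0 - prom_w + 1000L, e0 + 1000L)
  } else {
    prom <- c(s0 - 1000L, s0 - 1000L + prom_w)
  }
  rows <- data.frame(chrom = chr, start = prom[1], end = prom[2],
    height = height * 1.5)
  rem <- total - prom_w
  if (rem > 0) {
    n_t <- ceiling(rem / 8000)
    tw <- floor(rem / n_t)
    # spread tiles evenly over the body (after the promoter region)
    body_lo <- if (minus) s0 else s0 + 1000L
    body_hi <- if (minus) e0 - 1000L else e0
    span <- body_hi - body_lo
    gap <- max(0, floor((span - n_t * tw) / max(1L, n_t)))
    pos <- body_lo + (seq_len(n_t) - 1L) * (tw + gap)
    rows <- rbind(rows, data.frame(chrom = chr, start = pos,
      end = pmin(pos + tw, body_hi), height = height))
    rows <- rows[rows$end > rows$start, ]
  }
  rows
}

#' Generate one synthetic ChIP-Seq sample
#'
#' Planted broad-domain genes receive a promoter peak plus body tiles
#' totalling a coverage drawn from `bgrd_cov_range`; planted focal genes
#' receive one narrow tall promoter peak; background noise peaks are
#' Poisson-placed.  The optional signal track is the peak superposition
#' plus a small non-negative noise floor.
#'
#' @param genes gene-model GRanges
#' @param spec a [syntheticSpec()]
#' @param planted_bgrd,planted_fgrd character id vectors
#' @param seed RNG seed for this sample (default `spec$seed + 2`)
#' @param with_track also build the [SignalTrack-class] (default TRUE)
#' @param cov_scale named numeric of per-gene coverage multipliers
#'   (used by the cancer-cohort generator to shorten domains)
#' @return list with `peaks` (GRanges) and `track` (SignalTrack or NULL)
#' @export
makeSample <- function(genes, spec, planted_bgrd, planted_fgrd,
                       seed = spec$seed + 2L, with_track = TRUE,
                       cov_scale = numeric(0)) {
  withSeed(seed, {
    rows <- list()
    for (g in planted_bgrd) {
      gene <- genes[match(g, genes$gene_id)]
      cov <- stats::runif(1, spec$bgrd_cov_range[1], spec$bgrd_cov_range[2])
      if (g %in% names(cov_scale)) cov <- cov * cov_scale[[g]]
      hb <- stats::runif(1, 2, 4)
      rows[[length(rows) + 1L]] <- broadDomainPeaks(gene, cov, hb)
    }
    for (g in planted_fgrd) {
      gene <- genes[match(g, genes$gene_id)]
      minus <- as.character(strand(gene)) == "-"
      tss <- if (minus) end(gene) else start(gene) - 1L
      h <- stats::runif(1, 2, 4) * spec$fgrd_height_boost
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(seqnames(gene)),
        start = tss - spec$fgrd_width %/% 2L,
        end = tss + spec$fgrd_width - spec$fgrd_width %/% 2L,
        height = h)
    }
    n_noise <- stats::rpois(1, spec$noise_peak_rate *
      spec$chrom_length / 1e6)
    if (n_noise > 0) {
      nw <- floor(stats::runif(n_noise, 200, 2000))
      ns <- floor(stats::runif(n_noise, 0, spec$chrom_length - nw))
      rows[[length(rows) + 1L]] <- data.frame(chrom = spec$chrom,
        start = ns, end = ns + nw,
        height = stats::runif(n_noise, 0.5, 1.5))
    }
    pk <- do.call(rbind, rows)
    pk <- pk[order(pk$start), ]
    peaks <- peakRanges(pk$chrom, pk$start, pk$end, pk$height)
    track <- NULL
    if (with_track) {
      step <- spec$track_step
      nbin <- ceiling(spec$chrom_length / step)
      v <- stats::runif(nbin, 0, 0.2)  # non-negative noise floor
      b0 <- pmax(pk$start, 0) %/% step
      b1 <- (pmin(pk$end, spec$chrom_length) - 1L) %/% step
      for (i in seq_len(nrow(pk))) {
        idx <- (b0[i] + 1L):(b1[i] + 1L)
        v[idx] <- v[idx] + pk$height[i]
      }
      track <- SignalTrack(stats::setNames(list(v), spec$chrom), step)
    }
    list(peaks = peaks, track = track)
  })
}

#' Generate a multi-sample panel with a conserved core
#'
#' A conserved core (`conserved_core_frac` of the planted broad
#' domains) appears in every sample; the remaining planted domains
#' appear in each sample independently with probability
#' `noncore_presence_prob`.  Focal peaks are planted identically in all
#' samples.
#'
#' @param genes gene-model GRanges
#' @param spec a [syntheticSpec()]
#' @param n_samples panel size (default `spec$n_samples`)
#' @param with_tracks build signal tracks too (default FALSE)
#' @return list with `samples` (named list of [makeSample()] outputs)
#'   and `truth` (planted sets, core, per-sample presence matrix and
#'   true conservation)
#' @export
makePanel <- function(genes, spec, n_samples = spec$n_samples,
                      with_tracks = FALSE) {
  planted <- choosePlantedDomains(genes, spec)
  n_core <- round(spec$conserved_core_frac * length(planted$bgrd))
  core <- withSeed(spec$seed + 3L, sample(planted$bgrd, n_core))
  noncore <- setdiff(planted$bgrd, core)
  presence <- withSeed(spec$seed + 4L, {
    m <- matrix(FALSE, length(planted$bgrd), n_samples,
      dimnames = list(planted$bgrd, sprintf("s%02d", seq_len(n_samples))))
    m[core, ] <- TRUE
    for (j in seq_len(n_samples))
      m[noncore, j] <- stats::runif(length(noncore)) <
        spec$noncore_presence_prob
    m
  })
  samples <- lapply(seq_len(n_samples), function(j) {
    makeSample(genes, spec,
      planted_bgrd = rownames(presence)[presence[, j]],
      planted_fgrd = planted$fgrd,
      seed = spec$seed + 100L + j, with_track = with_tracks)
  })
  names(samples) <- colnames(presence)
  list(samples = samples,
    truth = list(planted_bgrd = planted$bgrd, core = core,
      planted_fgrd = planted$fgrd, presence = presence,
      conservation = rowMeans(presence)))
}

#' Generate a cancer/normal cohort with planted width changes
#'
#' Normal samples come from [makePanel()].  Each cancer sample is a
#' modified copy of one normal sample: it keeps that sample's planted
#' domain presence, but a `shorten_frac` subset of the conserved core
#' collapses to `shorten_factor` of its width in every cancer sample,
#' and a smaller set of previously unmarked genes gains a full broad
#' domain (the lengthened truth set).
#'
#' @param genes gene-model GRanges
#' @param spec a [syntheticSpec()]
#' @param with_tracks build signal tracks too (default FALSE)
#' @return list with `samples` (named list, normals then cancers),
#'   `labels` (named character), and `truth` (panel truth plus
#'   `shortened` and `lengthened` id vectors)
#' @export
makeCancerCohort <- function(genes, spec, with_tracks = FALSE) {
  stopifnot(spec$n_cancer <= spec$n_normal)
  panel <- makePanel(genes, spec, n_samples = spec$n_normal,
    with_tracks = with_tracks)
  truth <- panel$truth
  n_short <- round(spec$shorten_frac * length(truth$core))
  shortened <- withSeed(spec$seed + 5L, sample(truth$core, n_short))
  pool <- setdiff(genes$gene_id, c(truth$planted_bgrd, truth$planted_fgrd))
  pool <- intersect(pool,
    genes$gene_id[width(genes) >= exp(spec$gene_length_meanlog)])
  n_len <- round(spec$lengthen_frac * length(truth$core))
  lengthened <- withSeed(spec$seed + 6L, sample(pool, n_len))
  cov_scale <- stats::setNames(rep(spec$shorten_factor,
    length(shortened)), shortened)
  cancers <- lapply(seq_len(spec$n_cancer), function(j) {
    present <- rownames(truth$presence)[truth$presence[, j]]
    makeSample(genes, spec,
      planted_bgrd = c(present, lengthened),
      planted_fgrd = truth$planted_fgrd,
      seed = spec$seed + 200L + j, with_track = with_tracks,
      cov_scale = cov_scale)
  })
  names(cancers) <- sprintf("c%02d", seq_len(spec$n_cancer))
  samples <- c(panel$samples, cancers)
  labels <- stats::setNames(
    c(rep("normal", spec$n_normal), rep("cancer", spec$n_cancer)),
    names(samples))
  truth$shortened <- shortened
  truth$lengthened <- lengthened
  list(samples = samples, labels = labels, truth = truth)
}

#' Generate expression values coupled to repression coverage
#'
#' Log-expression is `baseline - coupling x coverage` plus Gaussian
#' noise; reported expression is the exponential, so all values are
#' finite and non-negative.  With positive coupling, genes under broad
#' repression domains express below the gene-wide median.
#'
#' @param genes gene-model GRanges
#' @param domain_stats data.frame from [genePeakStats()]
#' @param spec a [syntheticSpec()]
#' @param seed RNG seed (default `spec$seed + 7`)
#' @return named numeric vector of expression values
#' @export
makeExpression <- function(genes, domain_stats, spec,
                           seed = spec$seed + 7L) {
  cov <- stats::setNames(domain_stats$coverage, domain_stats$gene_id)
  cov <- cov[genes$gene_id]
  withSeed(seed, {
    le <- spec$expression_baseline - spec$expression_coupling * cov +
      stats::rnorm(length(cov), 0, spec$expression_noise_sd)
    stats::setNames(exp(le), genes$gene_id)
  })
}
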