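# bgrd: broad genic repression domain analysis for H3K27me3 ChIP-Seq

H3K27me3, the repressive histone mark written by Polycomb, marks genes
in two geometries: tall, narrow peaks confined near the TSS (**focal
genic repression domains, FGRDs**) and intermediate-height peaks that
blanket the promoter and gene body over up to hundreds of kilobases
(**broad genic repression domains, BGRDs**). BGRDs sit preferentially
on long genes and are enriched in oncogenes, and their shortening in
cancer marks candidate tumor-promoting genes that mutation analysis
misses. This package is for computational epigenomics groups who want
that analysis as a reusable, tested pipeline rather than a chain of
one-off scripts.

## The method

Per gene *g* with length *L<sub>g</sub>*, every overlapping enrichment
peak contributes its width to the width sum *W<sub>g</sub>* and its
height to the height max *H<sub>g</sub>*; coverage is
*W<sub>g</sub>/L<sub>g</sub>*. Sorting *W<sub>g</sub>* gives an
L-shaped curve; after rescaling both axes to [0, n−1] the **turning
point** is the point nearest the corner (n−1, 0), and the BGRD cutoff
is twice the width at the turn. BGRD genes are the top-500 widest
passing the cutoff; FGRD genes the top-500 tallest among the rest.
Enrichment of gene categories (oncogenes, tumor suppressors,
housekeeping genes) is scored as the one-tailed hypergeometric tail
P(X ≥ k) with fold = observed/expected, in sliding 1500-gene rank
windows sharing 500 genes. Across samples, widths are quantile
normalized onto a reference sample, per-gene **conservation** is the
fraction of samples carrying a BGRD, and an optimal reference panel is
chosen by forward selection on enrichment P values. Differential
calls between cancer and normal require both a mean width change
(> 5 kb) and a conservation change (> 0.3), with a label-shuffle mock
null; a four-flag filter cascade (recurrent BGRD, no mutation-driver
evidence, expressed above median, width at least halved) nominates
candidate genes and lncRNAs. A synthetic-data generator with planted
domains, conserved cores and cancer cohorts makes every stage testable
offline; see `vignettes/bgrd-methods.Rmd` for the full model and its
assumptions.

## A worked example

```r
library(bgrd)
spec   <- syntheticSpec(seed = 1)        # 2000 genes, 400 planted BGRDs
genes  <- makeGenome(spec)
pl     <- choosePlantedDomains(genes, spec)
smp    <- makeSample(genes, spec, pl$bgrd, pl$fgrd, with_track = FALSE)
st     <- genePeakStats(genes, smp$peaks)
tp     <- findTurningPoint(st$width_sum)
tp
#> TurningPoint: rank 1589, width 2569.0 bp, cutoff 5138.0 bp (x2.0)
cl <- classifyDomains(st, tp, n_top = 400, seed = 1)
length(intersect(cl$bgrd, pl$bgrd)) / length(pl$bgrd)   # recall
#> [1] 1
```

The turning point lands at the corner between background peak widths
(a few kb) and the planted broad domains (tens to hundreds of kb), so
the twofold cutoff (5.1 kb here) separates them cleanly and all 400
planted genes are recovered. On a planted cancer cohort the
differential caller recovers every planted shortening:

```r
coh  <- makeCancerCohort(genes, spec)    # 10 normals, 8 paired cancers
sts  <- lapply(coh$samples, function(s) genePeakStats(genes, s$peaks))
x    <- buildWidthMatrix(sts,
          bgrd_rule = list(cutoff = widthCutoff(tp)),
          labels = coh$labels)
x    <- quantileNormalizeToReference(x, "s01")
calls <- cohortDifferential(x)           # needs dWidth > 5 kb AND dCons > 0.3
table(calls$class)[c("shortened", "lengthened")]
#>  shortened lengthened
#>         24         12
all(coh$truth$shortened %in% calls$gene_id[calls$class == "shortened"])
#> [1] TRUE
```

Both counts match the planted truth exactly (24 shortened, 12
lengthened, no false calls). `mockShuffle(x)` reports how many calls
label shuffles produce by chance, and `candidateGenes()` /
`candidateLncRNAs()` run the filter cascade against a reference panel.
A command-line wrapper over the same functions is installed at
`inst/scripts/bgrd` (`bgrd call`, `enrich`, `conserve`, `diff`,
`diff-cohort`, `simulate`).

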