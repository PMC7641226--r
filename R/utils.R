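`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Strand-aware TSS / TTS in 0-based coordinates.
tssOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes) - 1L)
}
ttsOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes) - 1L, end(genes))
}

# Per-bp sum of a fixed-step track over [from, to) in 0-based bp
# coordinates; each bp takes the value of its bin, positions outside the
# stored track contribute 0.
trackWindowSum <- function(track, chrom, from, to) {
  if (to <= from) return(0)
  v <- trackValues(track)[[chrom]]
  if (is.null(v) || !length(v)) return(0)
  step <- trackStep(track)
  from <- max(from, 0)
  to <- min(to, length(v) * step)
  if (to <= from) return(0)
  b0 <- from %/% step  # 0-based bin of first bp
  b1 <- (to - 1) %/% step
  if (b0 == b1) return(v[b0 + 1] * (to - from))
  head_bp <- (b0 + 1) * step - from
  tail_bp <- to - b1 * step
  mid <- if (b1 - b0 > 1) sum(v[(b0 + 2):b1]) * step else 0
  v[b0 + 1] * head_bp + mid + v[b1 + 1] * tail_bp
}

trackWindowMean <- function(track, chrom, from, to) {
  if (to <= from) return(0)
  trackWindowSum(track, chrom, from, to) / (to - from)
}
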