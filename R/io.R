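#' Read gene annotation (BED6, BED12 or GTF-lite)
#'
#' All coordinates are converted to the internal 0-based half-open
#' convention at this boundary: BED input is already 0-based half-open;
#' GTF (1-based, inclusive) has 1 subtracted from the start.  BED12
#' blocks become exons.  For GTF-lite, rows with feature `gene` define
#' genes and rows with feature `exon` are attached to their gene via the
#' `gene_id` attribute.
#'
#' @param path file path
#' @param format one of "bed6", "bed12", "gtf-lite"
#' @return a gene-model GRanges (see [geneModels()])
#' @export
readGeneAnnotation <- function(path, format = c("bed6", "bed12", "gtf-lite")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(geneModels(character(0), character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t")
  if (format %in% c("bed6", "bed12")) {
    need <- if (format == "bed6") 6L else 12L
    nf <- lengths(fields)
    if (any(nf < need))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
        which(nf < need)[1], need, nf[which(nf < need)[1]]))
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
      stop(sprintf("parse error at line %d: non-numeric coordinate",
        which(is.na(start) | is.na(end))[1]))
    name <- vapply(fields, `[`, "", 4L)
    strand <- vapply(fields, `[`, "", 6L)
    if (any(end <= start))
      stop(sprintf("validation error at line %d: end <= start",
        which(end <= start)[1]))
    exons <- NULL
    if (format == "bed12") {
      exons <- lapply(seq_along(fields), function(i) {
        f <- fields[[i]]
        nb <- as.integer(f[10])
        sizes <- as.integer(strsplit(f[11], ",")[[1]])
        offs <- as.integer(strsplit(f[12], ",")[[1]])
        if (length(sizes) != nb || length(offs) != nb)
          stop(sprintf("parse error at line %d: block count mismatch", i))
        cbind(start[i] + offs, start[i] + offs + sizes)
      })
    }
    if (anyDuplicated(name))
      stop("duplicate gene_ids: ",
        paste(unique(name[duplicated(name)]), collapse = ", "))
    return(geneModels(name, chrom, start, end, strand, exons = exons))
  }
  # gtf-lite
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("parse error at line %d: expected 9 fields, got %d",
      which(nf < 9L)[1], nf[which(nf < 9L)[1]]))
  feat <- vapply(fields, `[`, "", 3L)
  gid <- vapply(fields, function(f) {
    m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }, "")
  if (anyNA(gid))
    stop(sprintf("parse error at line %d: missing gene_id attribute",
      which(is.na(gid))[1]))
  chrom <- vapply(fields, `[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  if (anyNA(start1) || anyNA(end1))
    stop(sprintf("parse error at line %d: non-numeric coordinate",
      which(is.na(start1) | is.na(end1))[1]))
  strand <- vapply(fields, `[`, "", 7L)
  start <- start1 - 1L  # 1-based inclusive -> 0-based half-open
  end <- end1
  if (any(end <= start))
    stop(sprintf("validation error at line %d: end <= start",
      which(end <= start)[1]))
  gi <- feat == "gene"
  if (!any(gi)) gi <- rep(TRUE, length(feat))  # all rows are genes
  if (anyDuplicated(gid[gi]))
    stop("duplicate gene_ids: ",
      paste(unique(gid[gi][duplicated(gid[gi])]), collapse = ", "))
  exons <- lapply(gid[gi], function(g) {
    ei <- which(feat == "exon" & gid == g)
    if (!length(ei)) return(NULL)
    o <- order(start[ei])
    cbind(start[ei][o], end[ei][o])
  })
  geneModels(gid[gi], chrom[gi], start[gi], end[gi], strand[gi],
    exons = exons)
}

#' Write gene annotation as BED6 or BED12
#'
#' @param genes gene-model GRanges
#' @param path output path
#' @param format "bed6" or "bed12"
#' @return path, invisibly
#' @export
writeGeneAnnotation <- function(genes, path, format = c("bed6", "bed12")) {
  format <- match.arg(format)
  if (format == "bed6") {
    df <- data.frame(as.character(seqnames(genes)), bedStart(genes),
      bedEnd(genes), genes$gene_id, 0L, as.character(strand(genes)))
  } else {
    ex <- genes$exons
    blocks <- vapply(seq_along(genes), function(i) {
      e <- ex[[i]]
      if (length(e) == 0L)  # single block spanning the gene
        e <- IRanges(start(genes)[i], end(genes)[i])
      sizes <- paste(IRanges::width(e), collapse = ",")
      offs <- paste(IRanges::start(e) - start(genes)[i], collapse = ",")
      paste(length(e), sizes, offs, sep = "\t")
    }, "")
    df <- data.frame(as.character(seqnames(genes)), bedStart(genes),
      bedEnd(genes), genes$gene_id, 0L, as.character(strand(genes)),
      bedStart(genes), bedEnd(genes), "0", blocks)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peak calls (BED with score-as-height, or DANPOS-style TSV)
#'
#' Peak width is always recomputed as `end - start`; a `width` column in
#' a DANPOS-style table is checked against the coordinates and a warning
#' is emitted on mismatch (coordinate truth).  For BED input the score
#' field (column 5) is the peak height.
#'
#' @param path file path
#' @param format "bed" or "danpos_tsv"
#' @return a peak GRanges (see [peakRanges()])
#' @export
readPeaks <- function(path, format = c("bed", "danpos_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (!length(lines))
      return(peakRanges(character(0), integer(0), integer(0), numeric(0)))
    fields <- strsplit(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 5L))
      stop(sprintf(
        "format error at line %d: BED peaks need 5 fields (score = height)",
        which(nf < 5L)[1]))
    chrom <- vapply(fields, `[`, "", 1L)
    start <- as.integer(vapply(fields, `[`, "", 2L))
    end <- as.integer(vapply(fields, `[`, "", 3L))
    height <- as.numeric(vapply(fields, `[`, "", 5L))
    if (anyNA(height)) stop("format error: non-numeric height (score) field")
    return(peakRanges(chrom, start, end, height))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    return(peakRanges(character(0), integer(0), integer(0), numeric(0)))
  cn <- tolower(colnames(tab))
  colnames(tab) <- cn
  ccol <- intersect(c("chr", "chrom"), cn)[1]
  hcol <- intersect(c("height", "summit_height", "smt_value"), cn)[1]
  if (is.na(ccol) || !all(c("start", "end") %in% cn))
    stop("format error: DANPOS-style table needs chr/chrom, start, end")
  if (is.na(hcol))
    stop("format error: missing height column")
  if ("width" %in% cn) {
    w <- tab$end - tab$start
    if (any(tab$width != w))
      warning(sprintf(
        "%d peak(s) had a width column disagreeing with end - start; coordinates win",
        sum(tab$width != w)))
  }
  peakRanges(tab[[ccol]], tab$start, tab$end, tab[[hcol]])
}

#' Write peaks as 5-column BED (score = height)
#'
#' @param peaks peak GRanges
#' @param path output path
#' @return path, invisibly
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(as.character(seqnames(peaks)), bedStart(peaks),
    bedEnd(peaks), sprintf("peak_%d", seq_along(peaks)), peaks$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a signal track (bedGraph or fixed-step wiggle)
#'
#' Imported via rtracklayer, then resampled to a fixed-step
#' [SignalTrack-class]: gaps are filled with 0 and each bin takes the
#' per-bp mean of the source intervals it covers.  Overlapping bedGraph
#' intervals are a format error.
#'
#' @param path file path
#' @param format "bedgraph" or "wiggle"
#' @param step output bin size in bp
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the last covered position rounded up to a bin
#' @return a [SignalTrack-class]
#' @export
readSignal <- function(path, format = c("bedgraph", "wiggle"), step = 1L,
                       chrom_lengths = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path,
    format = if (format == "bedgraph") "bedGraph" else "wig")
  for (chr in unique(as.character(seqnames(gr)))) {
    g <- gr[seqnames(gr) == chr]
    if (sum(IRanges::width(g)) > sum(IRanges::width(IRanges::reduce(ranges(g)))))
      stop("format error: overlapping intervals on ", chr)
  }
  chrs <- unique(as.character(seqnames(gr)))
  if (!is.null(chrom_lengths)) chrs <- union(chrs, names(chrom_lengths))
  step <- as.integer(step)
  vals <- lapply(chrs, function(chr) {
    g <- gr[seqnames(gr) == chr]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else if (length(g)) max(end(g)) else 0L
    nbin <- ceiling(len / step)
    if (nbin == 0L) return(numeric(0))
    out <- numeric(nbin)
    if (length(g)) {
      cov <- IRanges::coverage(ranges(g), weight = g$score,
        width = nbin * step)
      # per-bin mean of the per-bp expansion
      v <- as.numeric(cov)
      out <- colMeans(matrix(v, nrow = step))
    }
    out
  })
  names(vals) <- chrs
  SignalTrack(vals, step)
}

#' Write a SignalTrack as bedGraph
#'
#' Zero-valued bins are omitted; adjacent equal-valued bins are merged.
#'
#' @param track a [SignalTrack-class]
#' @param path output path
#' @return path, invisibly
#' @export
writeSignal <- function(track, path) {
  step <- trackStep(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in trackChroms(track)) {
    v <- trackValues(track)[[chr]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", chr, starts[keep] * step,
      ends[keep] * step, r$values[keep]), con)
  }
  invisible(path)
}

#' Read a gene set (one id per line)
#'
#' @param path file path
#' @param name set name (defaults to the file base name)
#' @return a list with elements `name` and `gene_ids` (unique character)
#' @export
readGeneSet <- function(path, name = NULL) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids) & !grepl("^#", ids)]
  list(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path))
       else name,
       gene_ids = unique(ids))
}

#' Write a gene set
#' @param gene_ids character vector of ids
#' @param path output path
#' @return path, invisibly
#' @export
writeGeneSet <- function(gene_ids, path) {
  writeLines(unique(gene_ids), path)
  invisible(path)
}

#' Read a two-column gene/value TSV (expression, mutation Q values)
#'
#' Expects a header row with the gene id in the first column and the
#' value in the second.
#'
#' @param path file path
#' @return named numeric vector
#' @export
readGeneValueTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected at least 2 columns (gene_id, value)")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a gene/value TSV
#' @param values named numeric vector
#' @param path output path
#' @param value_name header for the value column
#' @return path, invisibly
#' @export
writeGeneValueTable <- function(values, path, value_name = "value") {
  df <- data.frame(gene_id = names(values), v = as.numeric(values))
  colnames(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a WidthMatrix as TSV
#'
#' One row per gene: the per-sample widths, then `conservation` and
#' `max_width`.  Sample labels go in a `#label` comment line so that the
#' file round-trips through [readWidthMatrixTable()].
#'
#' @param x a [WidthMatrix-class]
#' @param path output path
#' @return path, invisibly
#' @export
writeWidthMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#label\t",
    paste(sampleLabels(x), collapse = "\t")), con)
  df <- data.frame(gene_id = rownames(x), widthValues(x),
    conservation = conservation(x), max_width = maxWidth(x),
    check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a WidthMatrix TSV written by [writeWidthMatrix()]
#'
#' The BGRD mask is rebuilt from the widths under the given rule, so the
#' file stores only widths and labels.
#'
#' @param path file path
#' @param bgrd_rule passed to [buildWidthMatrix()]
#' @return a [WidthMatrix-class]
#' @export
readWidthMatrixTable <- function(path, bgrd_rule = list(top_n = 500)) {
  first <- readLines(path, n = 1L)
  labels <- NULL
  skip <- 0L
  if (grepl("^#label\t", first)) {
    labels <- strsplit(sub("^#label\t", "", first), "\t")[[1]]
    skip <- 1L
  }
  tab <- utils::read.delim(path, skip = skip, check.names = FALSE)
  scol <- setdiff(colnames(tab), c("gene_id", "conservation", "max_width"))
  w <- as.matrix(tab[, scol, drop = FALSE])
  rownames(w) <- tab$gene_id
  if (is.null(labels)) labels <- rep(NA_character_, length(scol))
  newWidthMatrix(w, stats::setNames(labels, scol), bgrd_rule)
}
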