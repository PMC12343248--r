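#' Gene-body coverage profile
#'
#' For each gene the representative (longest) transcript is divided into
#' `n_bins` equal-length bins in transcript coordinates, oriented 5' (bin 1)
#' to 3' (bin `n_bins`) according to the annotated strand. Every read base
#' overlapping the transcript's exons contributes to its bin; `raw_depth` is
#' the per-bin base total summed over genes, and `normalized` is the per-bin
#' mean over expressed genes divided by the total read count, then
#' log10-transformed with a pseudocount.
#'
#' Reads are expected to be duplicate- and ambiguity-filtered first.
#'
#' @param reads read table (see [read_bed12()])
#' @param ann annotation_set
#' @param n_bins number of positional bins (default 100)
#' @param pseudocount added inside the log10 (default 1e-9)
#' @return data.table: bin, raw_depth, normalized
#' @export
gene_body_coverage <- function(reads, ann, n_bins = 100L, pseudocount = 1e-9) {
  if (nrow(reads) == 0L) stop("no reads")
  tx <- ann$transcripts
  rep_tx <- tx[order(-length, transcript_id), .SD[1L], by = gene_id]$transcript_id
  tei <- transcript_exon_index(ann, rep_tx)

  bl <- read_blocks(reads)
  bgr <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start + 1L, bl$end))
  egr <- GenomicRanges::GRanges(tei$chrom, IRanges::IRanges(tei$gstart + 1L, tei$gend))
  ov <- GenomicRanges::findOverlaps(bgr, egr)
  if (length(ov) == 0L) stop("no expressed genes: reads overlap no representative transcript")
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)

  seg <- data.table::data.table(
    bs = bl$start[qh], be = bl$end[qh],
    gs = tei$gstart[sh], ge = tei$gend[sh], c0 = tei$c0[sh],
    strand = tei$strand[sh], L = tei$L[sh], gene_id = tei$gene_id[sh])
  seg[, `:=`(os = pmax(bs, gs), oe = pmin(be, ge))]
  # exon-overlap interval in transcript coordinates (5'->3')
  seg[, `:=`(a = ifelse(strand == "+", c0 + (os - gs), c0 + (ge - oe)),
             b = ifelse(strand == "+", c0 + (oe - gs), c0 + (ge - os)))]

  # split transcript-coordinate intervals over equal-length bins:
  # base p (0-based) belongs to bin floor(p * n_bins / L) + 1
  nb <- as.integer(n_bins)
  seg[, `:=`(b1 = floor(a * nb / L), b2 = floor((b - 1) * nb / L))]
  nspan <- seg$b2 - seg$b1 + 1L
  idx <- rep(seq_len(nrow(seg)), nspan)
  k <- seg$b1[idx] + sequence(nspan) - 1L
  lo <- ceiling(k * seg$L[idx] / nb)
  hi <- ceiling((k + 1) * seg$L[idx] / nb)
  contrib <- pmin(seg$b[idx], hi) - pmax(seg$a[idx], lo)
  dt <- data.table::data.table(gene_id = seg$gene_id[idx], bin = k + 1L,
                               bases = contrib)[bases > 0]

  per_gene <- dt[, .(bases = sum(bases)), by = .(gene_id, bin)]
  n_expr <- data.table::uniqueN(per_gene$gene_id)
  prof <- per_gene[, .(raw_depth = sum(bases)), by = bin]
  out <- data.table::data.table(bin = seq_len(nb))
  out <- prof[out, on = "bin"]
  out[is.na(raw_depth), raw_depth := 0]
  data.table::setorder(out, bin)
  out[, normalized := log10(raw_depth / n_expr / nrow(reads) + pseudocount)]
  out[]
}

#' Genomic-region assignment of reads
#'
#' Assigns each read to exonic, intronic or intergenic by the majority of its
#' aligned bases, with precedence exonic > intronic > intergenic on ties.
#' Exonic bases fall in the union of all annotated exons; intronic bases fall
#' inside a gene's genomic span but outside exons; the rest are intergenic.
#'
#' @param reads read table (deduplicated, ambiguity-filtered)
#' @param ann annotation_set
#' @return named numeric vector with elements exonic, intronic, intergenic
#'   (fractions over all reads, summing to 1)
#' @export
region_fractions <- function(reads, ann) {
  if (nrow(reads) == 0L) stop("no reads")
  bl <- read_blocks(reads)
  bgr <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start + 1L, bl$end))
  ex <- ann$exons
  exu <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end)))
  g <- ann$genes
  spans <- GenomicRanges::reduce(GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end)))

  ov_bases <- function(target) {
    ov <- GenomicRanges::findOverlaps(bgr, target)
    if (length(ov) == 0L) return(numeric(nrow(reads)))
    w <- GenomicRanges::width(IRanges::pintersect(
      bgr[S4Vectors::queryHits(ov)], target[S4Vectors::subjectHits(ov)]))
    per_block <- tapply(w, bl$read_idx[S4Vectors::queryHits(ov)], sum)
    out <- numeric(nrow(reads))
    out[as.integer(names(per_block))] <- per_block
    out
  }
  len <- tapply(bl$end - bl$start, bl$read_idx, sum)
  read_len <- numeric(nrow(reads))
  read_len[as.integer(names(len))] <- len
  ex_b <- ov_bases(exu)
  sp_b <- ov_bases(spans)
  in_b <- sp_b - ex_b
  ig_b <- read_len - sp_b

  region <- ifelse(ex_b >= in_b & ex_b >= ig_b, "exonic",
                   ifelse(in_b >= ig_b, "intronic", "intergenic"))
  n <- length(region)
  c(exonic = sum(region == "exonic") / n,
    intronic = sum(region == "intronic") / n,
    intergenic = sum(region == "intergenic") / n)
}
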