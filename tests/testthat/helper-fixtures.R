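library(data.table)

# Two-gene toy annotation:
#   gA (species A, + strand): 3 exons [100,200) [300,400) [500,600);
#     isoforms gA_t1 (all three) and gA_t2 (middle exon skipped) -> one SE pair
#   gB (species B, - strand): 2 exons [1000,1200) [1500,1700), single isoform
toy_annotation <- function() {
  annotation_set(rbindlist(list(
    data.table(gene_id = "gA", transcript_id = "gA_t1", chrom = "A_chr1",
               strand = "+", start = c(100L, 300L, 500L),
               end = c(200L, 400L, 600L)),
    data.table(gene_id = "gA", transcript_id = "gA_t2", chrom = "A_chr1",
               strand = "+", start = c(100L, 500L), end = c(200L, 600L)),
    data.table(gene_id = "gB", transcript_id = "gB_t1", chrom = "B_chr1",
               strand = "-", start = c(1000L, 1500L),
               end = c(1200L, 1700L)))))
}

# single-exon genes, one per species, for coverage geometry tests
single_exon_annotation <- function(strand_A = "+", len = 1000L) {
  annotation_set(rbindlist(list(
    data.table(gene_id = "gA", transcript_id = "gA_t1", chrom = "A_chr1",
               strand = strand_A, start = 0L, end = len),
    data.table(gene_id = "gB", transcript_id = "gB_t1", chrom = "B_chr1",
               strand = "+", start = 0L, end = len))))
}

# droplet matrix from explicit per-barcode species counts; one gene per species
matrix_from_counts <- function(counts_A, counts_B, barcodes = NULL) {
  n <- length(counts_A)
  if (is.null(barcodes)) barcodes <- sprintf("BC%05d", seq_len(n))
  m <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 2L), j = rep(1:2, each = n),
    x = c(counts_A, counts_B), dims = c(n, 2L),
    dimnames = list(barcodes, c("gA", "gB")))
  droplet_matrix(m, data.table(gene_id = c("gA", "gB"), species = c("A", "B")))
}

# independent naive re-implementation of the droplet-calling rules
oracle_classify <- function(counts_A, counts_B, barcodes,
                            knee_rank = 100L, knee_divisor = 10,
                            min_counts = 1000, max_cross = 0.25,
                            contam_total = 30000) {
  total <- counts_A + counts_B
  ord <- order(-total, barcodes)
  thr <- total[ord][knee_rank] / knee_divisor
  out <- character(length(total))
  for (i in seq_along(total)) {
    t <- total[i]; a <- counts_A[i]; b <- counts_B[i]
    out[i] <- if (t <= thr) "empty"
    else if (a > min_counts && b / t < max_cross) "speciesA_cell"
    else if (b > min_counts && a / t < max_cross) "speciesB_cell"
    else if (min(a, b) / t > max_cross && t < contam_total) "contaminated"
    else "filtered"
  }
  out
}

# brute-force skipped-exon detector: exhaustive pairwise exon-set comparison
oracle_se_pairs <- function(ann) {
  ex <- ann$exons
  out <- list()
  for (g in unique(ex$gene_id)) {
    txs <- unique(ex[gene_id == g, transcript_id])
    if (length(txs) < 2L) next
    for (t1 in txs) for (t2 in txs) {
      if (t1 == t2) next
      e1 <- ex[transcript_id == t1][order(start)]
      e2 <- ex[transcript_id == t2][order(start)]
      k1 <- paste(e1$start, e1$end)
      k2 <- paste(e2$start, e2$end)
      miss <- setdiff(k1, k2)
      if (length(miss) != 1L || length(setdiff(k2, k1)) != 0L) next
      i <- which(k1 == miss)
      if (i == 1L || i == nrow(e1)) next  # terminal exon, not SE
      # flanks of the skipped exon must be directly adjacent in t2
      j <- which(k2 == k1[i - 1L])
      if (length(j) == 1L && j < nrow(e2) && k2[j + 1L] == k1[i + 1L]) {
        out[[length(out) + 1L]] <- data.table(
          gene_id = g, exon_start = e1$start[i], exon_end = e1$end[i],
          excl_donor = e1$end[i - 1L], excl_acceptor = e1$start[i + 1L])
      }
    }
  }
  if (!length(out)) return(data.table(gene_id = character(0),
                                      exon_start = integer(0),
                                      exon_end = integer(0),
                                      excl_donor = integer(0),
                                      excl_acceptor = integer(0)))
  unique(rbindlist(out))
}

# per-read brute-force junction gap scan
oracle_junctions <- function(reads) {
  tab <- new.env()
  for (i in seq_len(nrow(reads))) {
    sizes <- as.integer(strsplit(reads$block_sizes[i], ",")[[1]])
    starts <- as.integer(strsplit(reads$block_starts[i], ",")[[1]])
    if (length(sizes) < 2L) next
    abs_s <- reads$start[i] + starts
    abs_e <- abs_s + sizes
    for (k in seq_len(length(sizes) - 1L)) {
      key <- paste(reads$chrom[i], abs_e[k], abs_s[k + 1L])
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
  }
  keys <- ls(tab)
  if (!length(keys)) return(data.table(chrom = character(0), donor = integer(0),
                                       acceptor = integer(0), count = integer(0)))
  parts <- tstrsplit(keys, " ")
  dt <- data.table(chrom = parts[[1]], donor = as.integer(parts[[2]]),
                   acceptor = as.integer(parts[[3]]),
                   count = vapply(keys, function(k) tab[[k]], integer(1)))
  setorder(dt, chrom, donor, acceptor)
  dt[]
}
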