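#' Read a GTF annotation
#'
#' Parses gene/transcript/exon feature lines (via rtracklayer) into an
#' [annotation_set()]. GTF's 1-based closed coordinates are converted to the
#' package-wide 0-based half-open convention. Species is taken from a
#' `species` attribute when present, otherwise from the chromosome-name
#' prefix (`A_`/`B_`).
#'
#' @param path GTF file path
#' @return annotation_set
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  dat <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(dat)) {
    return(annotation_set(data.table::data.table(
      gene_id = character(0), transcript_id = character(0),
      chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0))))
  }
  nf <- vapply(strsplit(lines[dat], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 9L)) {
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                 dat[which(nf < 9L)[1]], nf[which(nf < 9L)[1]]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) {
    return(annotation_set(data.table::data.table(
      gene_id = character(0), transcript_id = character(0),
      chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0))))
  }
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id)) {
    stop("exon feature without a parent transcript_id attribute")
  }
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) {
    stop("exon feature without a gene_id attribute")
  }
  exons <- data.table::data.table(
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex))
  if (!is.null(ex$species) && !anyNA(ex$species)) {
    exons[, species := as.character(ex$species)]
  }
  annotation_set(exons)
}

#' Write an annotation set as GTF
#'
#' Emits gene, transcript and exon lines with `gene_id`, `transcript_id` and
#' `species` attributes, converting back to GTF's 1-based closed coordinates.
#' Output is deterministic: genes ordered by (chrom, start, gene_id),
#' transcripts by id, exons by genomic position.
#'
#' @param ann annotation_set
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path) {
  g <- ann$genes
  tx <- ann$transcripts[order(transcript_id)]
  ex <- ann$exons[order(transcript_id, start)]
  out <- character(0)
  fmt <- function(chrom, feature, start0, end0, strand, attrs) {
    sprintf("%s\tsplicedrop\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feature, start0 + 1L, end0, strand, attrs)
  }
  for (k in seq_len(nrow(g))) {
    gid <- g$gene_id[k]
    ga <- sprintf('gene_id "%s"; species "%s";', gid, g$species[k])
    out <- c(out, fmt(g$chrom[k], "gene", g$start[k], g$end[k], g$strand[k], ga))
    gtx <- tx[gene_id == gid]
    for (j in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[j]
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; species "%s";',
                    gid, tid, g$species[k])
      out <- c(out, fmt(gtx$chrom[j], "transcript", gtx$tx_start[j],
                        gtx$tx_end[j], gtx$strand[j], ta))
      tex <- ex[transcript_id == tid]
      nrs <- if (tex$strand[1] == "-") rev(seq_len(nrow(tex))) else seq_len(nrow(tex))
      out <- c(out, fmt(tex$chrom, "exon", tex$start, tex$end, tex$strand,
                        sprintf('%s exon_number "%d";', ta, nrs)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# canonical comma-joined integer list (no trailing comma)
.join_int <- function(x) paste(x, collapse = ",")

.split_int <- function(x) {
  lapply(strsplit(sub(",$", "", x), ",", fixed = TRUE), as.integer)
}

.empty_reads <- function() {
  data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    name = character(0), score = integer(0), strand = character(0),
    block_count = integer(0), block_sizes = character(0),
    block_starts = character(0), barcode = character(0),
    read_id = character(0), ambiguous = logical(0))
}

#' Read barcoded block-aligned reads from BED12
#'
#' Dialect: the name field is `"BARCODE:READID"`; the score column carries the
#' cross-genome ambiguity flag (0 = uniquely mapped, 1 = maps to both
#' genomes). BED12 is natively 0-based half-open, so coordinates are kept
#' as-is; relative blockStarts/blockSizes stay in their canonical
#' comma-joined form, with [read_blocks()] expanding them to absolute
#' intervals.
#'
#' @param path BED12 file path
#' @return data.table with one row per read: chrom, start, end, name, score,
#'   strand, block_count, block_sizes, block_starts, barcode, read_id,
#'   ambiguous
#' @export
read_bed12 <- function(path) {
  if (file.size(path) == 0L) return(.empty_reads())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6, 9, 11, 12)))
  if (ncol(dt) != 12L) {
    stop(sprintf("expected 12 BED columns, found %d", ncol(dt)))
  }
  data.table::setnames(dt, c("chrom", "start", "end", "name", "score",
                             "strand", "thick_start", "thick_end", "item_rgb",
                             "block_count", "block_sizes", "block_starts"))
  sizes <- .split_int(dt$block_sizes)
  starts <- .split_int(dt$block_starts)
  nb <- lengths(sizes)
  bad <- which(nb != dt$block_count | lengths(starts) != dt$block_count)
  if (length(bad)) {
    stop(sprintf("line %d: blockCount %d does not match blockSizes/blockStarts",
                 bad[1], dt$block_count[bad[1]]))
  }
  dt[, `:=`(
    block_sizes = vapply(sizes, .join_int, character(1)),
    block_starts = vapply(starts, .join_int, character(1)),
    barcode = sub(":.*$", "", name),
    read_id = sub("^[^:]*:", "", name),
    ambiguous = score == 1L,
    score = as.integer(score),
    thick_start = NULL, thick_end = NULL, item_rgb = NULL)]
  dt[]
}

#' Write reads as BED12
#'
#' Inverse of [read_bed12()]; emits the canonical 12-column form
#' (thickStart/thickEnd = start/end, itemRgb = 0, score = ambiguity flag).
#'
#' @param reads read table as returned by [read_bed12()] or [build_reads()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed12 <- function(reads, path) {
  out <- data.table::data.table(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = reads$name, score = as.integer(reads$ambiguous),
    strand = reads$strand, thick_start = reads$start, thick_end = reads$end,
    item_rgb = "0", block_count = reads$block_count,
    block_sizes = reads$block_sizes, block_starts = reads$block_starts)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Expand read blocks to absolute intervals
#'
#' @param reads read table (see [read_bed12()])
#' @return data.table with one row per alignment block: read_idx (row index
#'   into `reads`), chrom, start, end (absolute, 0-based half-open), barcode
#' @export
read_blocks <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.table::data.table(read_idx = integer(0), chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  barcode = character(0)))
  }
  sizes <- as.integer(unlist(strsplit(reads$block_sizes, ",", fixed = TRUE),
                             use.names = FALSE))
  starts <- as.integer(unlist(strsplit(reads$block_starts, ",", fixed = TRUE),
                              use.names = FALSE))
  n <- reads$block_count
  abs_start <- rep(reads$start, n) + starts
  data.table::data.table(
    read_idx = rep(seq_len(nrow(reads)), n),
    chrom = rep(reads$chrom, n),
    start = abs_start,
    end = abs_start + sizes,
    barcode = rep(reads$barcode, n))
}

#' Construct a read table from absolute block intervals
#'
#' Convenience constructor (used heavily in tests): takes one list element
#' per read holding a 2-column matrix/data.frame of absolute half-open
#' `(start, end)` blocks, validates the block invariants (sorted, disjoint,
#' inter-block gaps >= 1 bp) and assembles the canonical read table.
#'
#' @param blocks list of 2-column matrices of absolute block intervals
#' @param chrom,barcode,read_id character vectors (recycled to length of
#'   `blocks`)
#' @param ambiguous logical vector (default all FALSE)
#' @param strand character vector (default `"+"`)
#' @return read table (see [read_bed12()])
#' @export
build_reads <- function(blocks, chrom, barcode, read_id,
                        ambiguous = FALSE, strand = "+") {
  n <- length(blocks)
  chrom <- rep_len(chrom, n); barcode <- rep_len(barcode, n)
  read_id <- rep_len(read_id, n); ambiguous <- rep_len(ambiguous, n)
  strand <- rep_len(strand, n)
  starts <- character(n); sizes <- character(n)
  bstart <- integer(n); bend <- integer(n); bc <- integer(n)
  for (i in seq_len(n)) {
    b <- as.matrix(blocks[[i]])
    if (nrow(b) < 1L) stop("read must have at least one block")
    if (any(b[, 2] <= b[, 1])) stop("block with end <= start")
    if (nrow(b) > 1L) {
      if (is.unsorted(b[, 1], strictly = TRUE)) stop("blocks must be sorted")
      if (any(b[-1, 1] - b[-nrow(b), 2] < 1L)) {
        stop("gap between consecutive blocks must be >= 1 bp")
      }
    }
    bstart[i] <- b[1, 1]; bend[i] <- b[nrow(b), 2]; bc[i] <- nrow(b)
    sizes[i] <- .join_int(b[, 2] - b[, 1])
    starts[i] <- .join_int(b[, 1] - b[1, 1])
  }
  data.table::data.table(
    chrom = chrom, start = bstart, end = bend,
    name = paste0(barcode, ":", read_id),
    score = as.integer(ambiguous), strand = strand,
    block_count = bc, block_sizes = sizes, block_starts = starts,
    barcode = barcode, read_id = read_id, ambiguous = as.logical(ambiguous))
}

#' Construct a droplet count matrix
#'
#' @param counts barcode x gene matrix coercible to a sparse CsparseMatrix;
#'   non-negative integers; rownames = barcodes
#' @param features data.frame with columns `gene_id`, `species` (`"A"`/`"B"`),
#'   one row per matrix column
#' @return object of class `droplet_matrix`: list(counts, features)
#' @export
droplet_matrix <- function(counts, features) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  features <- data.table::as.data.table(features)
  if (!all(c("gene_id", "species") %in% names(features))) {
    stop("features must have columns gene_id and species")
  }
  if (ncol(counts) != nrow(features)) {
    stop(sprintf("matrix has %d columns but features has %d rows",
                 ncol(counts), nrow(features)))
  }
  if (anyNA(features$species) || !all(features$species %in% c("A", "B"))) {
    stop("every gene needs a species label 'A' or 'B'")
  }
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) stop("counts needs barcode rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate barcodes")
  colnames(counts) <- features$gene_id
  structure(list(counts = counts, features = features[]),
            class = "droplet_matrix")
}

#' @exportS3Method base::print
print.droplet_matrix <- function(x, ...) {
  cat(sprintf("droplet_matrix: %d barcodes x %d genes (A: %d, B: %d), %d nonzero, total %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$features$species == "A"),
              sum(x$features$species == "B"), length(x$counts@x),
              as.integer(sum(x$counts))))
  invisible(x)
}

#' Read a barcode x gene count matrix (MatrixMarket triplet + TSVs)
#'
#' Rows of the matrix are barcodes, columns are genes. `features.tsv` is
#' header-less with two tab-separated columns (gene_id, species), 10x-style;
#' `barcodes.tsv` one barcode per line. Duplicate triplet entries for one
#' cell are summed.
#'
#' @param matrix_path,barcodes_path,features_path file paths
#' @return droplet_matrix
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feats <- data.table::fread(features_path, header = FALSE, sep = "\t",
                             colClasses = "character")
  if (ncol(feats) < 2L) stop("features.tsv needs columns gene_id, species")
  data.table::setnames(feats, 1:2, c("gene_id", "species"))
  if (nrow(m) != length(barcodes)) {
    stop(sprintf("matrix header says %d rows but barcodes.tsv has %d lines",
                 nrow(m), length(barcodes)))
  }
  if (ncol(m) != nrow(feats)) {
    stop(sprintf("matrix header says %d columns but features.tsv has %d lines",
                 ncol(m), nrow(feats)))
  }
  counts <- as(m, "CsparseMatrix")  # sums duplicate triplets
  rownames(counts) <- barcodes
  droplet_matrix(counts, feats)
}

#' Write a droplet matrix as MatrixMarket triplet + TSVs
#'
#' @param dm droplet_matrix
#' @param dir output directory (created if needed); writes matrix.mtx,
#'   barcodes.tsv, features.tsv
#' @return `dir`, invisibly
#' @export
write_mtx <- function(dm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(dm$counts, "TsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(dm$counts), file.path(dir, "barcodes.tsv"))
  data.table::fwrite(dm$features[, .(gene_id, species)],
                     file.path(dir, "features.tsv"),
                     sep = "\t", col.names = FALSE, quote = FALSE, eol = "\n")
  invisible(dir)
}
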