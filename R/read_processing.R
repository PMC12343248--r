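#' Remove cross-genome-ambiguous reads
#'
#' Drops every read flagged as mapping to both genomes (score column 1 in the
#' BED12 dialect), preserving input order.
#'
#' @param reads read table (see [read_bed12()])
#' @param keep_ambiguous if TRUE, return the input unchanged
#' @return filtered read table
#' @export
filter_ambiguous <- function(reads, keep_ambiguous = FALSE) {
  if (keep_ambiguous) return(reads)
  reads[ambiguous == FALSE]
}

#' Remove PCR/optical duplicate reads
#'
#' Two reads are duplicates when they share barcode, chromosome and the exact
#' block structure (identical placement determines identical sequence here,
#' so (chrom, blocks) stands in for sequence identity). The first-seen read
#' of each duplicate set is retained, which keeps the result stable and
#' independent of duplicate multiplicity. `ignore_barcode = TRUE` gives the
#' bulk-mode behaviour where sequence identity alone defines a duplicate.
#'
#' @param reads read table
#' @param ignore_barcode drop the barcode from the duplicate key (bulk mode)
#' @return deduplicated read table, input order preserved
#' @export
dedup_reads <- function(reads, ignore_barcode = FALSE) {
  key <- paste(reads$chrom, reads$start, reads$block_sizes, reads$block_starts,
               sep = "\r")
  if (!ignore_barcode) key <- paste(reads$barcode, key, sep = "\r")
  reads[!duplicated(key)]
}
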