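#' Extract splice junctions from block-aligned reads
#'
#' Every gap between consecutive alignment blocks of a read is one junction
#' observation: donor = end of the left block (0-based exclusive), acceptor =
#' start of the right block. Observations are aggregated by (chrom, donor,
#' acceptor).
#'
#' @param reads read table (see [read_bed12()])
#' @return data.table: chrom, donor, acceptor, count, status (NA until
#'   [classify_junctions()]), gene_id (NA)
#' @export
extract_junctions <- function(reads) {
  bl <- read_blocks(reads)
  if (nrow(bl) == 0L) return(.empty_junctions())
  j <- bl[, if (.N >= 2L) list(chrom = chrom[-.N], donor = end[-.N],
                               acceptor = start[-1]),
          by = read_idx]
  if (nrow(j) == 0L) return(.empty_junctions())
  out <- j[, .(count = .N), by = .(chrom, donor, acceptor)]
  data.table::setorder(out, chrom, donor, acceptor)
  out[, `:=`(status = NA_character_, gene_id = NA_character_)]
  out[]
}

.empty_junctions <- function() {
  data.table::data.table(chrom = character(0), donor = integer(0),
                         acceptor = integer(0), count = integer(0),
                         status = character(0), gene_id = character(0))
}

#' Classify junctions against an annotation
#'
#' A junction is `annotated` iff its (chrom, donor, acceptor) coordinates
#' exactly match an adjacent-exon pair of some transcript; matching is
#' exact-coordinate, so a 1-bp shift of an annotated junction is `novel`.
#' A gene is assigned when both endpoints fall within a single gene's
#' genomic span; otherwise gene_id stays NA and the junction is `novel`.
#'
#' @param junctions output of [extract_junctions()]
#' @param ann annotation_set
#' @return the junction table with status and gene_id filled in
#' @export
classify_junctions <- function(junctions, ann) {
  j <- data.table::copy(junctions)
  if (nrow(j) == 0L) return(j)
  ann_j <- unique(ann$junctions[, .(chrom, donor, acceptor)])
  j[, status := "novel"]
  j[ann_j, on = c("chrom", "donor", "acceptor"), status := "annotated"]
  g <- ann$genes
  hit <- g[j, on = .(chrom, start <= donor, end >= acceptor),
           mult = "first", x.gene_id]
  j[, gene_id := hit]
  j[]
}

#' Detect skipped-exon event skeletons in an annotation
#'
#' For each gene, every internal exon E of a transcript whose flanking exons
#' are joined directly by a junction of another transcript of the same gene
#' defines one skipped-exon event. Events are unique per (gene, skipped
#' exon, flanking junction pair).
#'
#' @param ann annotation_set
#' @return data.table: gene_id, chrom, exon_start, exon_end, the two
#'   inclusion junction coordinates (incl1_donor/acceptor upstream,
#'   incl2_donor/acceptor downstream) and the exclusion junction
#'   (excl_donor/acceptor)
#' @export
detect_se_events <- function(ann) {
  ex <- ann$exons[order(transcript_id, start)]
  cand <- ex[, if (.N >= 3L) {
    i <- 2L:(.N - 1L)
    list(gene_id = gene_id[i], chrom = chrom[i],
         exon_start = start[i], exon_end = end[i],
         excl_donor = end[i - 1L], excl_acceptor = start[i + 1L])
  }, by = transcript_id]
  empty <- data.table::data.table(
    gene_id = character(0), chrom = character(0), exon_start = integer(0),
    exon_end = integer(0), incl1_donor = integer(0), incl1_acceptor = integer(0),
    incl2_donor = integer(0), incl2_acceptor = integer(0),
    excl_donor = integer(0), excl_acceptor = integer(0))
  if (nrow(cand) == 0L) return(empty)
  jx <- ann$junctions
  hit <- jx[cand,
            on = c("gene_id", "chrom", donor = "excl_donor",
                   acceptor = "excl_acceptor"),
            nomatch = NULL,
            .(gene_id, chrom, exon_start = i.exon_start,
              exon_end = i.exon_end, excl_donor = donor,
              excl_acceptor = acceptor,
              skip_tx = x.transcript_id, incl_tx = i.transcript_id)]
  hit <- hit[skip_tx != incl_tx]
  if (nrow(hit) == 0L) return(empty)
  ev <- unique(hit[, .(gene_id, chrom, exon_start, exon_end,
                       excl_donor, excl_acceptor)])
  ev[, `:=`(incl1_donor = excl_donor, incl1_acceptor = exon_start,
            incl2_donor = exon_end, incl2_acceptor = excl_acceptor)]
  data.table::setcolorder(ev, names(empty))
  data.table::setorder(ev, gene_id, exon_start)
  ev[]
}

#' Quantify skipped-exon events from junction counts
#'
#' Inclusion support is the minimum of the two inclusion-junction counts
#' (conservative combiner); exclusion support is the skip-junction count.
#' The inclusion proportion is inclusion/(inclusion+exclusion), NA when
#' neither junction is observed.
#'
#' @param events output of [detect_se_events()]
#' @param junctions junction count table ([extract_junctions()])
#' @return events with inclusion_count, exclusion_count, proportion
#' @export
quantify_se <- function(events, junctions) {
  ev <- data.table::copy(events)
  jc <- junctions[, .(chrom, donor, acceptor, count)]
  look <- function(chr, d, a) {
    m <- jc[data.table::data.table(chrom = chr, donor = d, acceptor = a),
            on = c("chrom", "donor", "acceptor"), x.count]
    ifelse(is.na(m), 0L, m)
  }
  ev[, `:=`(
    incl1 = look(chrom, incl1_donor, incl1_acceptor),
    incl2 = look(chrom, incl2_donor, incl2_acceptor),
    exclusion_count = look(chrom, excl_donor, excl_acceptor))]
  ev[, inclusion_count := pmin(incl1, incl2)]
  ev[, proportion := ifelse(inclusion_count + exclusion_count > 0,
                            inclusion_count / (inclusion_count + exclusion_count),
                            NA_real_)]
  ev[, c("incl1", "incl2") := NULL]
  ev[]
}

#' Gene-selection criteria for splicing analysis
#'
#' Thresholds for picking genes suitable for alternative-splicing
#' quantification: presence of a skipped-exon event, a majority
#' transcript-type proportion strictly above `min_type_proportion`, at least
#' `min_supporting_reads` reads supporting that type, and TPM strictly above
#' `min_tpm`.
#'
#' @param require_SE require a skipped-exon event (default TRUE)
#' @param min_type_proportion strict lower bound on the same-type proportion
#'   (default 0.5)
#' @param min_supporting_reads minimum supporting reads (default 5;
#'   inclusive)
#' @param min_tpm strict lower bound on expression (default 16)
#' @return list of class `selection_criteria`
#' @export
selection_criteria <- function(require_SE = TRUE, min_type_proportion = 0.5,
                               min_supporting_reads = 5, min_tpm = 16) {
  if (min_type_proportion <= 0 || min_supporting_reads <= 0 || min_tpm <= 0) {
    stop("selection thresholds must be positive")
  }
  structure(list(require_SE = isTRUE(require_SE),
                 min_type_proportion = min_type_proportion,
                 min_supporting_reads = min_supporting_reads,
                 min_tpm = min_tpm),
            class = "selection_criteria")
}

#' Select genes for splicing quantification
#'
#' @param gene_table data.frame with per-gene columns gene_id, has_SE
#'   (logical), type_proportion, supporting_reads, tpm
#' @param criteria selection_criteria
#' @return character vector of selected gene ids
#' @export
select_genes <- function(gene_table, criteria = selection_criteria()) {
  gt <- data.table::as.data.table(gene_table)
  keep <- (!criteria$require_SE | gt$has_SE) &
    gt$type_proportion > criteria$min_type_proportion &
    gt$supporting_reads >= criteria$min_supporting_reads &
    gt$tpm > criteria$min_tpm
  gt$gene_id[which(keep)]
}

#' Per-gene shared-junction concordance between two junction sets
#'
#' For every gene with at least one junction in the reference set `set2`,
#' the proportion of its reference junctions also detected in `set1`.
#'
#' @param set1 junction table with gene assignment (query, e.g. pseudo-bulk)
#' @param set2 junction table with gene assignment (reference, e.g. bulk)
#' @return data.table: gene_id, n_ref, n_shared, proportion
#' @export
junction_concordance <- function(set1, set2) {
  ref <- unique(data.table::as.data.table(set2)[!is.na(gene_id),
                                                .(chrom, donor, acceptor, gene_id)])
  if (nrow(ref) == 0L) {
    return(data.table::data.table(gene_id = character(0), n_ref = integer(0),
                                  n_shared = integer(0), proportion = numeric(0)))
  }
  q <- unique(data.table::as.data.table(set1)[, .(chrom, donor, acceptor)])
  ref[, shared := FALSE]
  if (nrow(q)) ref[q, on = c("chrom", "donor", "acceptor"), shared := TRUE]
  out <- ref[, .(n_ref = .N, n_shared = sum(shared)), by = gene_id]
  out[, proportion := n_shared / n_ref]
  data.table::setorder(out, gene_id)
  out[]
}
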