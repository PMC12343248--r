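#' Build an annotation set from an exon table
#'
#' The central annotation container: a validated exon table plus derived
#' per-transcript, per-gene and splice-junction indices. All coordinates are
#' 0-based half-open; GTF input is converted on read ([read_gtf()]).
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open) and optionally
#'   `species` (`"A"`/`"B"`). When `species` is absent it is inferred from the
#'   chromosome name prefix (`"A_..."` / `"B_..."`).
#' @return An object of class `annotation_set`: a list with data.tables
#'   `exons`, `transcripts`, `genes` and `junctions` (the donor/acceptor pairs
#'   of adjacent exons of every transcript, 0-based: donor = end of the left
#'   exon, acceptor = start of the right exon).
#' @export
annotation_set <- function(exons) {
  exons <- data.table::as.data.table(exons)
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))

  if (nrow(exons) == 0L) {
    empty <- exons[, req, with = FALSE]
    empty[, species := character(0)]
    return(structure(list(
      exons = empty,
      transcripts = data.table::data.table(
        transcript_id = character(0), gene_id = character(0),
        chrom = character(0), strand = character(0), species = character(0),
        n_exons = integer(0), length = integer(0),
        tx_start = integer(0), tx_end = integer(0)),
      genes = data.table::data.table(
        gene_id = character(0), species = character(0), chrom = character(0),
        strand = character(0), start = integer(0), end = integer(0),
        n_transcripts = integer(0)),
      junctions = data.table::data.table(
        chrom = character(0), donor = integer(0), acceptor = integer(0),
        transcript_id = character(0), gene_id = character(0))
    ), class = "annotation_set"))
  }

  exons[, `:=`(start = as.integer(start), end = as.integer(end),
               gene_id = as.character(gene_id),
               transcript_id = as.character(transcript_id),
               chrom = as.character(chrom), strand = as.character(strand))]
  if (!"species" %in% names(exons)) {
    exons[, species := sub("_.*$", "", chrom)]
  }
  exons[, species := as.character(species)]
  bad_sp <- setdiff(unique(exons$species), c("A", "B"))
  if (length(bad_sp)) {
    stop("cannot assign species (expected 'A'/'B' via species column or ",
         "chromosome prefix); offending value(s): ",
         paste(bad_sp, collapse = ", "))
  }
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (!all(exons$strand %in% c("+", "-"))) stop("exon strand must be '+' or '-'")

  data.table::setorder(exons, gene_id, transcript_id, start)
  # per-transcript invariants: disjoint sorted exons, single chrom/strand
  chk <- exons[, .(
    n_chrom = data.table::uniqueN(chrom),
    n_strand = data.table::uniqueN(strand),
    overlapping = any(start[-1] < end[-.N])
  ), by = .(gene_id, transcript_id)]
  if (any(chk$n_chrom > 1L) || any(chk$n_strand > 1L)) {
    stop("transcript spans multiple chromosomes or strands: ",
         chk[n_chrom > 1L | n_strand > 1L, transcript_id][1])
  }
  if (any(chk$overlapping)) {
    stop("overlapping exons within transcript: ",
         chk[overlapping == TRUE, transcript_id][1])
  }
  if (any(exons[, data.table::uniqueN(gene_id), by = transcript_id]$V1 > 1L)) {
    stop("transcript_id assigned to more than one gene")
  }
  gchk <- exons[, .(n_chrom = data.table::uniqueN(chrom),
                    n_strand = data.table::uniqueN(strand),
                    n_sp = data.table::uniqueN(species)), by = gene_id]
  if (any(gchk$n_chrom > 1L | gchk$n_strand > 1L | gchk$n_sp > 1L)) {
    stop("gene with inconsistent chrom/strand/species: ",
         gchk[n_chrom > 1L | n_strand > 1L | n_sp > 1L, gene_id][1])
  }

  transcripts <- exons[, .(
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
    species = species[1], n_exons = .N,
    length = sum(end - start),
    tx_start = min(start), tx_end = max(end)
  ), by = transcript_id]
  genes <- exons[, .(
    species = species[1], chrom = chrom[1], strand = strand[1],
    start = min(start), end = max(end),
    n_transcripts = data.table::uniqueN(transcript_id)
  ), by = gene_id]
  data.table::setorder(genes, chrom, start, gene_id)

  junctions <- exons[, {
    if (.N >= 2L) {
      list(chrom = chrom[-.N], donor = end[-.N], acceptor = start[-1],
           gene_id = gene_id[-.N])
    } else {
      list(chrom = character(0), donor = integer(0), acceptor = integer(0),
           gene_id = character(0))
    }
  }, by = transcript_id]
  data.table::setcolorder(junctions,
                          c("chrom", "donor", "acceptor", "transcript_id", "gene_id"))

  structure(list(exons = exons, transcripts = transcripts, genes = genes,
                 junctions = junctions),
            class = "annotation_set")
}

#' @exportS3Method base::print
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d genes (%s), %d transcripts, %d exons, %d junction records\n",
    nrow(x$genes),
    paste(sprintf("%s:%d", names(table(x$genes$species)),
                  as.integer(table(x$genes$species))), collapse = " "),
    nrow(x$transcripts), nrow(x$exons), nrow(x$junctions)))
  invisible(x)
}

#' Exons in transcript order with cumulative transcript coordinates
#'
#' For each transcript, exons ordered 5' to 3' (reversed genomic order on the
#' minus strand) with the cumulative transcript-coordinate offset `c0` at
#' which each exon begins and the total transcript length `L`. This is the
#' lookup used to map between transcript and genomic coordinates for read
#' placement and gene-body binning.
#'
#' @param ann annotation_set
#' @param transcript_ids optional character vector restricting the index
#' @return data.table with columns transcript_id, gene_id, chrom, strand,
#'   gstart, gend, len, c0, L
#' @export
transcript_exon_index <- function(ann, transcript_ids = NULL) {
  ex <- ann$exons
  if (!is.null(transcript_ids)) ex <- ex[transcript_id %in% transcript_ids]
  ex <- ex[order(transcript_id, start)]
  idx <- ex[, {
    o <- if (strand[1] == "-") rev(seq_len(.N)) else seq_len(.N)
    gs <- start[o]; ge <- end[o]
    len <- ge - gs
    list(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
         gstart = gs, gend = ge, len = len,
         c0 = cumsum(c(0L, len[-length(len)])), L = sum(len))
  }, by = transcript_id]
  idx
}

#' Exonic-union gene lengths
#'
#' Length of the merged (union) exonic footprint of each gene across all its
#' isoforms, in bp; the gene length used for TPM.
#'
#' @param ann annotation_set
#' @return named integer vector, names = gene_id
#' @export
gene_lengths <- function(ann) {
  ex <- ann$exons[order(gene_id, start, end)]
  if (nrow(ex) == 0L) return(stats::setNames(integer(0), character(0)))
  merged <- ex[, {
    s <- start; e <- end
    keep_s <- s[1]; tot <- 0L; cur_s <- s[1]; cur_e <- e[1]
    if (.N > 1L) for (i in 2L:.N) {
      if (s[i] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
      else cur_e <- max(cur_e, e[i])
    }
    list(len = tot + (cur_e - cur_s))
  }, by = gene_id]
  stats::setNames(merged$len, merged$gene_id)
}
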