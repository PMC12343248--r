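#' Simulation configuration for a two-species barnyard experiment
#'
#' Bundles and validates every tunable of the synthetic experiment: the
#' two-species gene annotation, droplet composition (pure cells, cross-species
#' doublets, ruptured/contaminated cells, ambient-only empties), per-droplet
#' count depths, ambient contamination, 3' positional bias of read placement,
#' PCR duplication and cross-genome mapping ambiguity.
#'
#' Defaults describe the emulated assay: 500 + 500 cells against 5,000
#' ambient-only empties whose totals sit near 1% of cell totals (a sharp
#' knee for rank-based empty calling), 2% ambient contamination, 5% doublets
#' (cross-species only), 5% ruptured cells at 60% ambient content, a mean of
#' 5,000 counts per cell with NB overdispersion, 150 bp reads with a mild
#' (lambda = 1) 3' bias, 10% PCR duplicates and 2% cross-genome-ambiguous
#' reads.
#'
#' @param seed integer seed; identical configs give byte-identical outputs
#' @param n_genes_per_species genes simulated per species
#' @param isoforms_min,isoforms_max range of isoform counts per gene
#' @param exons_min,exons_max range of exon counts per gene (>= 3 whenever
#'   skipped exons are requested)
#' @param exon_len_min,exon_len_max,intron_len_min,intron_len_max,intergenic_min,intergenic_max
#'   geometry ranges in bp (uniform draws)
#' @param frac_genes_with_SE fraction of multi-isoform genes given a
#'   skipped-exon isoform pair
#' @param se_inclusion_prop molar proportion of the inclusion isoform in
#'   skipped-exon genes
#' @param n_cells_A,n_cells_B cells per species
#' @param doublet_rate fraction of cell droplets replaced by merged A+B pairs
#' @param n_empty_droplets ambient-only barcodes
#' @param ambient_fraction fraction of each droplet's counts drawn from the
#'   cross-droplet ambient pool
#' @param contaminated_cell_rate fraction of cells given elevated ambient
#'   content (rupture model)
#' @param contaminated_ambient_fraction ambient fraction for ruptured cells
#' @param mean_counts_per_cell,dispersion negative-binomial depth per cell
#'   (mu, size)
#' @param empty_total_frac empty-droplet mean depth as a fraction of
#'   `mean_counts_per_cell`
#' @param three_prime_bias decay parameter lambda >= 0 of the fragment-start
#'   density exp(-lambda * d / L), d = distance of the start from the 3' end
#' @param read_length fragment length in bp
#' @param ambiguous_read_rate per-read rate of extra cross-genome-ambiguous
#'   decoy reads
#' @param duplicate_rate per-read PCR duplication rate
#' @param program_sdlog sdlog of the log-normal per-species expression program
#' @param program_seed optional separate seed for the expression programs,
#'   letting two simulations share one program (replicates); defaults to
#'   `seed + 1000`
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_species = 60L,
                       isoforms_min = 1L, isoforms_max = 2L,
                       exons_min = 4L, exons_max = 8L,
                       exon_len_min = 100L, exon_len_max = 400L,
                       intron_len_min = 200L, intron_len_max = 2000L,
                       intergenic_min = 1000L, intergenic_max = 5000L,
                       frac_genes_with_SE = 0.5,
                       se_inclusion_prop = 0.7,
                       n_cells_A = 500L, n_cells_B = 500L,
                       doublet_rate = 0.05,
                       n_empty_droplets = 5000L,
                       ambient_fraction = 0.02,
                       contaminated_cell_rate = 0.05,
                       contaminated_ambient_fraction = 0.6,
                       mean_counts_per_cell = 5000,
                       dispersion = 10,
                       empty_total_frac = 0.01,
                       three_prime_bias = 1,
                       read_length = 150L,
                       ambiguous_read_rate = 0.02,
                       duplicate_rate = 0.1,
                       program_sdlog = 1.5,
                       program_seed = NULL) {
  cfg <- as.list(environment())
  fracs <- c("frac_genes_with_SE", "se_inclusion_prop", "doublet_rate",
             "ambient_fraction", "contaminated_cell_rate",
             "contaminated_ambient_fraction", "empty_total_frac",
             "ambiguous_read_rate", "duplicate_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("config error: %s must be a fraction in [0,1]", f))
    }
  }
  pos <- c("n_genes_per_species", "isoforms_min", "isoforms_max", "exons_min",
           "exons_max", "exon_len_min", "exon_len_max", "intron_len_min",
           "intron_len_max", "intergenic_min", "intergenic_max", "n_cells_A",
           "n_cells_B", "mean_counts_per_cell", "dispersion", "read_length",
           "program_sdlog")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("config error: %s must be positive", f))
    }
  }
  if (cfg$n_empty_droplets < 0) stop("config error: n_empty_droplets must be >= 0")
  if (cfg$three_prime_bias < 0) stop("config error: three_prime_bias must be >= 0")
  if (cfg$isoforms_min > cfg$isoforms_max || cfg$exons_min > cfg$exons_max ||
      cfg$exon_len_min > cfg$exon_len_max ||
      cfg$intron_len_min > cfg$intron_len_max ||
      cfg$intergenic_min > cfg$intergenic_max) {
    stop("config error: min above max in a range parameter")
  }
  if (cfg$frac_genes_with_SE > 0 && cfg$exons_min < 3L) {
    stop("config error: skipped-exon isoforms need exons_min >= 3")
  }
  if (cfg$frac_genes_with_SE > 0 && cfg$isoforms_max < 2L) {
    stop("config error: skipped-exon isoforms need isoforms_max >= 2")
  }
  if (is.null(cfg$program_seed)) cfg$program_seed <- cfg$seed + 1000L
  cfg$seed <- as.integer(cfg$seed)
  cfg$program_seed <- as.integer(cfg$program_seed)
  structure(cfg, class = "sim_config")
}

.runif_int <- function(n, lo, hi) as.integer(lo) + as.integer(floor(runif(n) * (hi - lo + 1)))

#' Simulate a two-species annotation
#'
#' Lays out `n_genes_per_species` genes per species along one chromosome per
#' species (`A_chr1`, `B_chr1`), with uniform exon/intron/intergenic lengths
#' drawn from the configured ranges and random strand. A fraction
#' `frac_genes_with_SE` of multi-isoform genes gets exactly one skipped-exon
#' isoform pair (second isoform = first minus one random internal exon);
#' other multi-isoform genes differ by terminal-exon truncation only, so they
#' contribute no skipped-exon events. Deterministic under `config$seed`.
#'
#' @param config sim_config
#' @return annotation_set with attribute `se_truth`: data.table of the
#'   planted skipped-exon pairs (gene_id, exon_start, exon_end,
#'   inclusion_tx, exclusion_tx)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- vector("list", 2L * config$n_genes_per_species)
  se_rows <- list()
  ri <- 0L
  for (sp in c("A", "B")) {
    chrom <- paste0(sp, "_chr1")
    pos <- 0L
    for (i in seq_len(config$n_genes_per_species)) {
      gid <- sprintf("%s_g%03d", sp, i)
      pos <- pos + .runif_int(1L, config$intergenic_min, config$intergenic_max)
      n_ex <- .runif_int(1L, config$exons_min, config$exons_max)
      ex_len <- .runif_int(n_ex, config$exon_len_min, config$exon_len_max)
      in_len <- if (n_ex > 1L) {
        .runif_int(n_ex - 1L, config$intron_len_min, config$intron_len_max)
      } else integer(0)
      strand <- if (runif(1) < 0.5) "+" else "-"
      starts <- pos + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len
      pos <- ends[n_ex]

      k <- .runif_int(1L, config$isoforms_min, config$isoforms_max)
      is_se <- k >= 2L && n_ex >= 3L && runif(1) < config$frac_genes_with_SE
      iso_exons <- list(seq_len(n_ex))  # isoform 1: full chain
      if (is_se) {
        k <- 2L  # skipped-exon genes carry exactly the inclusion/exclusion pair
        skip <- .runif_int(1L, 2L, n_ex - 1L)
        iso_exons[[2L]] <- setdiff(seq_len(n_ex), skip)
        se_rows[[length(se_rows) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = chrom,
          exon_start = starts[skip], exon_end = ends[skip],
          inclusion_tx = sprintf("%s_t1", gid),
          exclusion_tx = sprintf("%s_t2", gid))
      } else if (k >= 2L) {
        # truncation isoforms: drop terminal exons, never creating SE pairs
        for (j in 2L:k) {
          keep <- max(1L, n_ex - (j - 1L))
          iso_exons[[j]] <- seq_len(keep)
        }
        iso_exons <- unique(iso_exons)
      }
      for (j in seq_along(iso_exons)) {
        sel <- iso_exons[[j]]
        ri <- ri + 1L
        rows[[ri]] <- data.table::data.table(
          gene_id = gid, transcript_id = sprintf("%s_t%d", gid, j),
          chrom = chrom, strand = strand,
          start = starts[sel], end = ends[sel], species = sp)
      }
    }
  }
  ann <- annotation_set(data.table::rbindlist(rows[seq_len(ri)]))
  attr(ann, "se_truth") <- if (length(se_rows)) {
    data.table::rbindlist(se_rows)
  } else {
    data.table::data.table(gene_id = character(0), chrom = character(0),
                           exon_start = integer(0), exon_end = integer(0),
                           inclusion_tx = character(0),
                           exclusion_tx = character(0))
  }
  ann
}

# Truncated-exponential fragment start in transcript coordinates.
# Density of the start's distance d from the 3' end is ~ exp(-lambda*d/L) on
# [read_length, L]; lambda = 0 gives uniform starts over [0, L - read_length].
.sample_starts <- function(L, rl, lambda) {
  n <- length(L)
  M <- pmax(0L, L - rl)
  u <- runif(n)
  if (lambda == 0) {
    s <- floor(u * (M + 1))
  } else {
    q0 <- exp(-lambda * pmin(rl, L) / L)
    q1 <- exp(-lambda)
    d <- -(L / lambda) * log(q0 - u * (q0 - q1))
    s <- floor(L - d)
  }
  as.integer(pmin(M, pmax(0, s)))
}

# Map per-read transcript intervals [s, e) to genomic blocks and build the
# canonical read table. pos: data.table(transcript_id, s, e, barcode, read_id,
# ambiguous).
.reads_from_positions <- function(pos, tei) {
  pos[, rid := .I]
  bl <- merge(pos[, .(rid, transcript_id, s, e)], tei,
              by = "transcript_id", allow.cartesian = TRUE)
  bl <- bl[c0 < e & c0 + len > s]
  bl[, `:=`(a = pmax(s, c0), b = pmin(e, c0 + len))]
  bl[, `:=`(blk_start = ifelse(strand == "+", gstart + (a - c0), gend - (b - c0)),
            blk_end   = ifelse(strand == "+", gstart + (b - c0), gend - (a - c0)))]
  data.table::setorder(bl, rid, blk_start)
  asm <- bl[, .(chrom = chrom[1], strand = strand[1],
                start = blk_start[1], end = blk_end[.N], block_count = .N,
                block_sizes = paste(blk_end - blk_start, collapse = ","),
                block_starts = paste(blk_start - blk_start[1], collapse = ",")),
            by = rid]
  out <- asm[pos, on = "rid"]
  data.table::data.table(
    chrom = out$chrom, start = as.integer(out$start), end = as.integer(out$end),
    name = paste0(out$barcode, ":", out$read_id),
    score = as.integer(out$ambiguous), strand = out$strand,
    block_count = out$block_count, block_sizes = out$block_sizes,
    block_starts = out$block_starts, barcode = out$barcode,
    read_id = out$read_id, ambiguous = out$ambiguous,
    transcript_id = out$transcript_id)
}

#' Simulate droplets: counts, reads and ground truth
#'
#' Composes the droplet population (pure A, pure B, cross-species doublets,
#' ruptured cells, ambient-only empties), draws per-droplet totals from a
#' negative binomial, splits each total into own-program and ambient counts
#' (the ambient pool is the cell-number-weighted average of the two species'
#' expression programs), and — when `emit_reads` — places one block-aligned
#' read per matrix count along a transcript chosen within its gene
#' proportionally to isoform molar weight x transcript length, with
#' 3'-biased fragment starts. Cross-genome-ambiguous decoy reads and PCR
#' duplicates are emitted on top and flagged; the count matrix therefore
#' equals the read set after ambiguity and duplicate filtering.
#'
#' @param config sim_config
#' @param ann annotation from [simulate_annotation()]
#' @param emit_reads generate per-count reads (set FALSE for droplet-scale
#'   experiments where only the matrix and truth are needed)
#' @return list with elements `matrix` (droplet_matrix), `reads` (read table
#'   or NULL), `droplet_truth` (barcode, true_category, true_species,
#'   true_ambient_fraction, total), `read_truth` (read_id, barcode,
#'   transcript_id, is_ambient, is_duplicate), and `programs` (gene_id,
#'   species, weight)
#' @export
simulate_droplets <- function(config, ann, emit_reads = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "annotation_set"))
  genes <- ann$genes
  nG <- nrow(genes)
  iA <- which(genes$species == "A"); iB <- which(genes$species == "B")

  # expression programs under their own seed so replicates can share them
  set.seed(config$program_seed)
  wA <- rlnorm(length(iA), 0, config$program_sdlog)
  wB <- rlnorm(length(iB), 0, config$program_sdlog)
  pA <- numeric(nG); pA[iA] <- wA / sum(wA)
  pB <- numeric(nG); pB[iB] <- wB / sum(wB)
  nA <- as.integer(config$n_cells_A); nB <- as.integer(config$n_cells_B)
  p_amb <- (nA * pA + nB * pB) / (nA + nB)
  programs <- data.table::data.table(gene_id = genes$gene_id,
                                     species = genes$species,
                                     weight = pA + pB)

  set.seed(config$seed + 1L)
  nd <- min(round(config$doublet_rate * (nA + nB)), nA, nB)
  n_pure_A <- nA - nd; n_pure_B <- nB - nd
  n_empty <- as.integer(config$n_empty_droplets)
  cat_v <- c(rep("pureA", n_pure_A), rep("pureB", n_pure_B),
             rep("doublet", nd), rep("empty", n_empty))
  sp_v <- c(rep("A", n_pure_A), rep("B", n_pure_B),
            rep(NA_character_, nd + n_empty))
  is_cell <- cat_v %in% c("pureA", "pureB")
  rupture <- is_cell & runif(length(cat_v)) < config$contaminated_cell_rate
  cat_v[rupture] <- "contaminated"
  f_v <- ifelse(cat_v == "empty", 1,
                ifelse(cat_v == "contaminated",
                       config$contaminated_ambient_fraction,
                       config$ambient_fraction))
  n_drop <- length(cat_v)

  bc_pool <- unique(apply(matrix(sample(c("A", "C", "G", "T"),
                                        12L * (2L * n_drop + 50L),
                                        replace = TRUE),
                                 ncol = 12L), 1L, paste, collapse = ""))
  if (length(bc_pool) < n_drop) stop("barcode collision overflow")  # ~impossible
  barcodes <- bc_pool[seq_len(n_drop)]

  mu <- config$mean_counts_per_cell
  totals <- integer(n_drop)
  cellish <- cat_v %in% c("pureA", "pureB", "contaminated")
  totals[cellish] <- rnbinom(sum(cellish), size = config$dispersion, mu = mu)
  totals[cat_v == "doublet"] <-
    rnbinom(nd, size = config$dispersion, mu = mu) +
    rnbinom(nd, size = config$dispersion, mu = mu)
  totals[cat_v == "empty"] <- rnbinom(n_empty, size = config$dispersion,
                                      mu = config$empty_total_frac * mu)
  totals <- pmax(totals, 1L)
  # doublet member split for the own-program mixture
  db_wA <- runif(nd, 0.3, 0.7)

  ii <- vector("list", n_drop); xx <- vector("list", n_drop)
  amb_flag <- vector("list", n_drop)
  di <- 0L
  for (d in seq_len(n_drop)) {
    tot <- totals[d]
    n_amb <- rbinom(1L, tot, f_v[d])
    own <- tot - n_amb
    own_c <- integer(nG)
    if (own > 0L) {
      own_c <- switch(cat_v[d],
        pureA = rmultinom(1L, own, pA)[, 1L],
        pureB = rmultinom(1L, own, pB)[, 1L],
        contaminated = rmultinom(1L, own,
                                 if (sp_v[d] == "A") pA else pB)[, 1L],
        doublet = {
          oA <- rbinom(1L, own, db_wA[d - (n_pure_A + n_pure_B)])
          rmultinom(1L, oA, pA)[, 1L] + rmultinom(1L, own - oA, pB)[, 1L]
        },
        integer(nG))
    }
    amb_c <- if (n_amb > 0L) rmultinom(1L, n_amb, p_amb)[, 1L] else integer(nG)
    nz_o <- which(own_c > 0L); nz_a <- which(amb_c > 0L)
    ii[[d]] <- c(nz_o, nz_a)
    xx[[d]] <- c(own_c[nz_o], amb_c[nz_a])
    amb_flag[[d]] <- c(rep(FALSE, length(nz_o)), rep(TRUE, length(nz_a)))
  }
  trip <- data.table::data.table(
    droplet = rep(seq_len(n_drop), lengths(ii)),
    gene_idx = unlist(ii, use.names = FALSE),
    count = unlist(xx, use.names = FALSE),
    is_ambient = unlist(amb_flag, use.names = FALSE))

  counts <- Matrix::sparseMatrix(
    i = trip$droplet, j = trip$gene_idx, x = trip$count,
    dims = c(n_drop, nG),
    dimnames = list(barcodes, genes$gene_id))
  dm <- droplet_matrix(counts, genes[, .(gene_id, species)])
  droplet_truth <- data.table::data.table(
    barcode = barcodes, true_category = cat_v, true_species = sp_v,
    true_ambient_fraction = f_v, total = totals)

  if (!emit_reads) {
    return(list(matrix = dm, reads = NULL, droplet_truth = droplet_truth,
                read_truth = NULL, programs = programs))
  }

  tx <- data.table::copy(ann$transcripts)
  # per-gene isoform sampling weights: molar weight x length (shotgun model)
  sew <- attr(ann, "se_truth")
  tx[, weight := 1]
  if (!is.null(sew) && nrow(sew)) {
    tx[sew, on = c(transcript_id = "inclusion_tx"),
       weight := config$se_inclusion_prop]
    tx[sew, on = c(transcript_id = "exclusion_tx"),
       weight := 1 - config$se_inclusion_prop]
  }
  tx[, weight := weight * length]

  rd <- trip[, .(droplet, gene_idx, is_ambient, count)]
  rd <- rd[rep(seq_len(.N), count)]
  rd[, `:=`(gene_id = genes$gene_id[gene_idx], barcode = barcodes[droplet],
            count = NULL)]
  data.table::setorder(rd, droplet, gene_idx, is_ambient)
  rd[, transcript_id := {
    cand <- tx[gene_id == .BY[[1L]]]
    if (nrow(cand) == 1L) rep(cand$transcript_id, .N)
    else sample(cand$transcript_id, .N, replace = TRUE,
                prob = cand$weight / sum(cand$weight))
  }, by = gene_id]
  n_clean <- nrow(rd)
  rd[, read_id := sprintf("r%08d", seq_len(.N))]
  rd[, `:=`(ambiguous = FALSE, is_duplicate = FALSE)]

  # cross-genome-ambiguous decoys: fresh placements re-drawn from the clean
  # read population, flagged in the score column, never counted in the matrix
  n_dec <- rbinom(1L, n_clean, config$ambiguous_read_rate)
  if (n_dec > 0L) {
    src <- sample(n_clean, n_dec, replace = TRUE)
    dec <- rd[src, .(droplet, gene_idx, is_ambient = FALSE, gene_id, barcode,
                     transcript_id)]
    dec[, read_id := sprintf("a%08d", seq_len(.N))]
    dec[, `:=`(ambiguous = TRUE, is_duplicate = FALSE)]
    rd <- data.table::rbindlist(list(rd, dec), use.names = TRUE)
  }

  # fragment placement for every emitted read
  rd[tx, on = "transcript_id", L := i.length]
  rd[, s := .sample_starts(L, config$read_length, config$three_prime_bias)]
  rd[, e := pmin(L, s + as.integer(config$read_length))]

  # PCR duplicates: identical placement re-emitted under a new read id
  dup_sel <- which(runif(nrow(rd)) < config$duplicate_rate)
  if (length(dup_sel)) {
    dup <- rd[dup_sel]
    dup[, read_id := sprintf("d%08d", seq_len(.N))]
    dup[, is_duplicate := TRUE]
    rd <- data.table::rbindlist(list(rd, dup), use.names = TRUE)
  }

  tei <- transcript_exon_index(ann)
  reads <- .reads_from_positions(
    rd[, .(transcript_id, s, e, barcode, read_id, ambiguous)], tei)
  read_truth <- data.table::data.table(
    read_id = rd$read_id, barcode = rd$barcode,
    transcript_id = rd$transcript_id, is_ambient = rd$is_ambient,
    is_duplicate = rd$is_duplicate, is_ambiguous = rd$ambiguous)

  list(matrix = dm, reads = reads, droplet_truth = droplet_truth,
       read_truth = read_truth, programs = programs)
}
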