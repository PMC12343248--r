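test_that("coverage geometry: a 5' read fills the first tenth of the bins", {
  ann <- single_exon_annotation(strand_A = "+")
  r <- build_reads(list(cbind(0L, 100L)), chrom = "A_chr1",
                   barcode = "AAAA", read_id = "r1")
  prof <- gene_body_coverage(r, ann)
  expect_equal(nrow(prof), 100L)
  # 100 read bases over 10-bp bins: bins 1-10 hold 10 bases (1x depth) each
  expect_equal(prof$raw_depth, c(rep(10, 10), rep(0, 90)))

  # same read on a minus-strand gene lands in bins 91-100
  ann_m <- single_exon_annotation(strand_A = "-")
  prof_m <- gene_body_coverage(r, ann_m)
  expect_equal(prof_m$raw_depth, c(rep(0, 90), rep(10, 10)))
})

test_that("raw depth conserves exon-overlapping bases; binning is exact", {
  cfg <- sim_config(seed = 12, n_genes_per_species = 10, n_cells_A = 10,
                    n_cells_B = 10, n_empty_droplets = 0,
                    mean_counts_per_cell = 300, duplicate_rate = 0,
                    ambiguous_read_rate = 0)
  ann <- simulate_annotation(cfg)
  sim <- simulate_droplets(cfg, ann)
  prof <- gene_body_coverage(sim$reads, ann)
  # oracle: per-base overlap of read blocks with representative transcripts
  tx <- ann$transcripts
  rep_tx <- tx[order(-length, transcript_id), .SD[1], by = gene_id]$transcript_id
  tei <- transcript_exon_index(ann, rep_tx)
  bl <- read_blocks(sim$reads)
  total <- 0
  for (i in seq_len(nrow(tei))) {
    e <- tei[i]
    seg <- bl[chrom == e$chrom & start < e$gend & end > e$gstart]
    if (nrow(seg)) {
      total <- total + sum(pmin(seg$end, e$gend) - pmax(seg$start, e$gstart))
    }
  }
  expect_equal(sum(prof$raw_depth), total)
  expect_true(all(prof$raw_depth >= 0))
  expect_false(anyNA(prof$normalized))
})

test_that("3'-biased simulation shifts depth-weighted mean bin past 50", {
  base <- list(seed = 19, n_genes_per_species = 15, n_cells_A = 8,
               n_cells_B = 8, n_empty_droplets = 0,
               mean_counts_per_cell = 800, duplicate_rate = 0,
               ambiguous_read_rate = 0, doublet_rate = 0,
               ambient_fraction = 0, contaminated_cell_rate = 0)
  wmean <- function(lambda) {
    cfg <- do.call(sim_config, c(base, list(three_prime_bias = lambda)))
    ann <- simulate_annotation(cfg)
    sim <- simulate_droplets(cfg, ann)
    prof <- gene_body_coverage(sim$reads, ann)
    sum(prof$bin * prof$raw_depth) / sum(prof$raw_depth)
  }
  expect_gt(wmean(3), 50)
})

test_that("read region assignment follows base majority with tie precedence", {
  ann <- toy_annotation()  # gA exons [100,200) [300,400) [500,600), span 100-600
  reads <- build_reads(
    list(cbind(120L, 180L),    # fully exonic
         cbind(160L, 260L),    # 40 exon + 60 intron -> intronic
         cbind(150L, 250L),    # 50/50 exon/intron tie -> exonic
         cbind(560L, 660L),    # 40 exon + 60 downstream intergenic -> intergenic
         cbind(700L, 800L)),   # fully intergenic
    chrom = "A_chr1", barcode = "AAAA", read_id = sprintf("r%d", 1:5))
  rf <- region_fractions(reads, ann)
  expect_equal(unname(rf), c(2, 1, 2) / 5)
  expect_equal(sum(rf), 1)

  # brute-force per-base labelling oracle for the majority read
  labels <- vapply(c(160, 560), function(s) {
    bases <- s:(s + 99)
    ex <- sum(bases >= 100 & bases < 200 | bases >= 300 & bases < 400 |
                bases >= 500 & bases < 600)
    sp <- sum(bases >= 100 & bases < 600)
    ig <- 100 - sp
    int <- sp - ex
    if (ex >= int && ex >= ig) "exonic" else if (int >= ig) "intronic" else "intergenic"
  }, character(1))
  expect_equal(labels, c("intronic", "intergenic"))
})

test_that("transcript-only simulations are essentially all exonic", {
  cfg <- sim_config(seed = 14, n_genes_per_species = 10, n_cells_A = 10,
                    n_cells_B = 10, n_empty_droplets = 0,
                    mean_counts_per_cell = 250)
  ann <- simulate_annotation(cfg)
  sim <- simulate_droplets(cfg, ann)
  rf <- region_fractions(dedup_reads(filter_ambiguous(sim$reads)), ann)
  expect_gte(rf[["exonic"]], 0.99)
})

test_that("coverage without reads or without overlap errors out", {
  ann <- toy_annotation()
  expect_error(gene_body_coverage(ann = ann,
                                  reads = build_reads(list(), character(0),
                                                      character(0), character(0))),
               "no reads")
  far <- build_reads(list(cbind(900000L, 900100L)), chrom = "A_chr1",
                     barcode = "AAAA", read_id = "r1")
  expect_error(gene_body_coverage(far, ann), "no expressed genes")
})
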