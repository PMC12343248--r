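test_that("block gaps become junctions; single-block reads contribute none", {
  reads <- build_reads(
    list(cbind(c(100L, 200L), c(150L, 250L)),
         cbind(c(100L, 200L), c(150L, 250L)),
         cbind(300L, 400L)),
    chrom = "A_chr1", barcode = "AAAA", read_id = sprintf("r%d", 1:3))
  j <- extract_junctions(reads)
  expect_equal(nrow(j), 1L)
  expect_equal(j$donor, 150L)
  expect_equal(j$acceptor, 200L)
  expect_equal(j$count, 2L)
  expect_equal(nrow(extract_junctions(reads[3])), 0L)
})

test_that("aggregated junction counts equal a per-read brute-force gap scan", {
  cfg <- sim_config(seed = 23, n_genes_per_species = 12, n_cells_A = 6,
                    n_cells_B = 6, n_empty_droplets = 0,
                    mean_counts_per_cell = 200)
  sim <- simulate_droplets(cfg, simulate_annotation(cfg))
  j <- extract_junctions(sim$reads)
  o <- oracle_junctions(sim$reads)
  expect_equal(as.data.frame(j[, .(chrom, donor, acceptor, count)]),
               as.data.frame(o))
  # conservation: total junction observations = total inter-block gaps
  expect_equal(sum(j$count), sum(sim$reads$block_count - 1L))
})

test_that("junction classification is exact-coordinate", {
  ann <- toy_annotation()
  reads <- build_reads(
    list(cbind(c(150L, 300L), c(200L, 350L)),   # gA_t1 intron 1: annotated
         cbind(c(150L, 500L), c(200L, 550L)),   # skip junction of gA_t2: annotated
         cbind(c(150L, 301L), c(200L, 350L))),  # acceptor off by one: novel
    chrom = "A_chr1", barcode = "AAAA", read_id = sprintf("r%d", 1:3))
  j <- classify_junctions(extract_junctions(reads), ann)
  expect_equal(j[order(donor, acceptor)]$status,
               c("annotated", "novel", "annotated"))
  expect_equal(unique(j$gene_id), "gA")

  # shifting every annotated junction by 1 bp makes all of them novel
  shifted <- data.table::copy(j)[status == "annotated"]
  shifted[, `:=`(donor = donor + 1L, acceptor = acceptor + 1L, count = 1L)]
  expect_true(all(classify_junctions(shifted, ann)$status == "novel"))
})

test_that("skipped-exon skeletons match the brute-force pairwise detector", {
  ann <- toy_annotation()
  ev <- detect_se_events(ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_id, "gA")
  expect_equal(ev$exon_start, 300L)
  expect_equal(ev$exon_end, 400L)
  expect_equal(ev$excl_donor, 200L)
  expect_equal(ev$excl_acceptor, 500L)

  cfg <- sim_config(seed = 6, n_genes_per_species = 20, isoforms_min = 1,
                    isoforms_max = 2, frac_genes_with_SE = 0.6)
  ann2 <- simulate_annotation(cfg)
  ev2 <- detect_se_events(ann2)
  o2 <- oracle_se_pairs(ann2)
  cols <- c("gene_id", "exon_start", "exon_end", "excl_donor", "excl_acceptor")
  expect_equal(as.data.frame(data.table::setorderv(ev2[, ..cols], cols)),
               as.data.frame(data.table::setorderv(o2[, ..cols], cols)))
  # single-isoform genes never yield events
  expect_false(any(ev2$gene_id %in% ann2$genes[n_transcripts == 1, gene_id]))
})

test_that("skipped-exon quantification combines junction counts conservatively", {
  ann <- toy_annotation()
  ev <- detect_se_events(ann)
  jc <- data.table::data.table(
    chrom = "A_chr1", donor = c(200L, 400L, 200L),
    acceptor = c(300L, 500L, 500L), count = c(12L, 7L, 3L))
  q <- quantify_se(ev, jc)
  expect_equal(q$inclusion_count, 7L)   # min(12, 7)
  expect_equal(q$exclusion_count, 3L)
  expect_equal(q$proportion, 0.7)

  # only inclusion evidence -> proportion 1; no evidence -> NA
  q1 <- quantify_se(ev, jc[1:2])
  expect_equal(q1$proportion, 1)
  q0 <- quantify_se(ev, jc[0])
  expect_true(is.na(q0$proportion))
})

test_that("simulated 70/30 isoform mixture is recovered from junctions", {
  cfg <- sim_config(seed = 29, n_genes_per_species = 2, isoforms_min = 2,
                    isoforms_max = 2, frac_genes_with_SE = 1,
                    exons_min = 4, exons_max = 5, exon_len_min = 250,
                    exon_len_max = 350, n_cells_A = 1, n_cells_B = 1,
                    n_empty_droplets = 0, doublet_rate = 0,
                    ambient_fraction = 0, contaminated_cell_rate = 0,
                    duplicate_rate = 0, ambiguous_read_rate = 0,
                    three_prime_bias = 0, mean_counts_per_cell = 4000,
                    se_inclusion_prop = 0.7)
  ann <- simulate_annotation(cfg)
  sim <- simulate_droplets(cfg, ann)
  q <- quantify_se(detect_se_events(ann), extract_junctions(sim$reads))
  expect_gt(nrow(q), 0L)
  for (i in seq_len(nrow(q))) {
    n <- q$inclusion_count[i] + q$exclusion_count[i]
    expect_lt(abs(q$proportion[i] - 0.7), 3 * sqrt(0.7 * 0.3 / n) + 0.02)
  }
})

test_that("gene selection applies the four criteria with strict TPM bound", {
  gt <- data.table::data.table(
    gene_id = sprintf("g%d", 1:6),
    has_SE = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    type_proportion = c(0.6, 0.6, 0.5, 0.9, 0.8, 0.51),
    supporting_reads = c(10, 10, 10, 20, 4, 5),
    tpm = c(20, 16, 30, 40, 25, 16.01))
  sel <- select_genes(gt)
  expect_setequal(sel, c("g1", "g6"))
  # g2: tpm not exceeding 16; g3: proportion not exceeding 0.5;
  # g4: no SE; g5: fewer than 5 supporting reads
  expect_setequal(select_genes(gt, selection_criteria(require_SE = FALSE)),
                  c("g1", "g4", "g6"))
  # brute-force filter agreement on random tables
  set.seed(77)
  rnd <- data.table::data.table(
    gene_id = sprintf("r%04d", 1:1000),
    has_SE = sample(c(TRUE, FALSE), 1000, TRUE),
    type_proportion = runif(1000),
    supporting_reads = sample(0:20, 1000, TRUE),
    tpm = 10^runif(1000, 0, 3))
  keep <- character(0)
  for (i in seq_len(1000)) {
    if (rnd$has_SE[i] && rnd$type_proportion[i] > 0.5 &&
        rnd$supporting_reads[i] >= 5 && rnd$tpm[i] > 16) {
      keep <- c(keep, rnd$gene_id[i])
    }
  }
  expect_equal(select_genes(rnd), keep)
})

test_that("junction concordance: identical sets give 1, empty query gives 0", {
  ann <- toy_annotation()
  jset <- data.table::data.table(
    chrom = "A_chr1", donor = c(200L, 400L, 200L),
    acceptor = c(300L, 500L, 500L), count = 1L,
    status = "annotated", gene_id = "gA")
  conc <- junction_concordance(jset, jset)
  expect_equal(conc$proportion, 1)
  expect_equal(conc$n_ref, 3L)
  conc0 <- junction_concordance(jset[0], jset)
  expect_equal(conc0$proportion, 0)
})
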