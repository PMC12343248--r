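test_that("config validation catches bad fractions and infeasible SE geometry", {
  expect_error(sim_config(ambient_fraction = 1.2), "fraction")
  expect_error(sim_config(doublet_rate = -0.1), "fraction")
  expect_error(sim_config(exons_min = 2, exons_max = 2,
                          frac_genes_with_SE = 0.5), "exons_min")
  expect_error(sim_config(isoforms_min = 1, isoforms_max = 1,
                          frac_genes_with_SE = 1), "isoforms_max")
  expect_error(sim_config(mean_counts_per_cell = 0), "positive")
})

test_that("skipped-exon planting matches a brute-force pairwise detector", {
  cfg1 <- sim_config(seed = 3, n_genes_per_species = 15, isoforms_min = 2,
                     isoforms_max = 2, frac_genes_with_SE = 1)
  ann1 <- simulate_annotation(cfg1)
  se <- oracle_se_pairs(ann1)
  multi <- ann1$genes[n_transcripts >= 2, gene_id]
  # every multi-isoform gene carries exactly one SE pair
  expect_setequal(se$gene_id, multi)
  expect_equal(nrow(se), length(multi))
  # and the planted truth agrees with the brute-force detector
  truth <- attr(ann1, "se_truth")
  expect_equal(
    as.data.frame(se[order(gene_id), .(gene_id, exon_start, exon_end)]),
    as.data.frame(truth[order(gene_id), .(gene_id, exon_start, exon_end)]))

  cfg0 <- sim_config(seed = 3, n_genes_per_species = 15, isoforms_min = 2,
                     isoforms_max = 3, frac_genes_with_SE = 0)
  expect_equal(nrow(oracle_se_pairs(simulate_annotation(cfg0))), 0L)
})

test_that("same seed reproduces byte-identical annotation and droplets", {
  cfg <- sim_config(seed = 9, n_genes_per_species = 10, n_cells_A = 15,
                    n_cells_B = 15, n_empty_droplets = 40,
                    mean_counts_per_cell = 200)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gtf(simulate_annotation(cfg), f1)
  write_gtf(simulate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  ann <- simulate_annotation(cfg)
  s1 <- simulate_droplets(cfg, ann)
  s2 <- simulate_droplets(cfg, ann)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(as.data.frame(s1$reads), as.data.frame(s2$reads))
  expect_identical(as.data.frame(s1$droplet_truth),
                   as.data.frame(s2$droplet_truth))
})

test_that("count conservation: matrix total equals clean reads emitted", {
  cfg <- sim_config(seed = 21, n_genes_per_species = 12, n_cells_A = 20,
                    n_cells_B = 20, n_empty_droplets = 50,
                    mean_counts_per_cell = 300, duplicate_rate = 0.15,
                    ambiguous_read_rate = 0.05)
  sim <- simulate_droplets(cfg, simulate_annotation(cfg))
  clean <- sim$read_truth[is_duplicate == FALSE & is_ambiguous == FALSE]
  expect_equal(sum(sim$matrix$counts), nrow(clean))
  expect_equal(nrow(sim$reads), nrow(sim$read_truth))
  # every barcode and read has exactly one truth record
  expect_equal(anyDuplicated(sim$read_truth$read_id), 0L)
  expect_setequal(rownames(sim$matrix$counts), sim$droplet_truth$barcode)
})

test_that("zero-rate simulation keeps droplets species-pure", {
  cfg <- sim_config(seed = 4, n_genes_per_species = 10, n_cells_A = 25,
                    n_cells_B = 25, n_empty_droplets = 0, doublet_rate = 0,
                    ambient_fraction = 0, contaminated_cell_rate = 0,
                    ambiguous_read_rate = 0, mean_counts_per_cell = 200)
  sim <- simulate_droplets(cfg, simulate_annotation(cfg), emit_reads = FALSE)
  sp <- sim$matrix$features$species
  cA <- Matrix::rowSums(sim$matrix$counts[, sp == "A", drop = FALSE])
  cB <- Matrix::rowSums(sim$matrix$counts[, sp == "B", drop = FALSE])
  truth <- sim$droplet_truth
  expect_true(all(cB[truth$true_category == "pureA"] == 0))
  expect_true(all(cA[truth$true_category == "pureB"] == 0))
})

test_that("unbiased fragment starts are uniform (chi-square at n = 50,000)", {
  set.seed(123)
  L <- 1000L; rl <- 150L
  s <- splicedrop:::.sample_starts(rep(L, 50000L), rl, 0)
  expect_true(all(s >= 0 & s <= L - rl))
  h <- table(cut(s, breaks = seq(0, L - rl + 1, length.out = 18),
                 right = FALSE))
  expect_gt(stats::chisq.test(as.integer(h))$p.value, 0.001)
})

test_that("3'-bias parameter shifts mean fragment start monotonically", {
  set.seed(7)
  L <- rep(2000L, 20000L); rl <- 150L
  mean_pos <- vapply(c(0, 1, 3), function(lam) {
    mean(splicedrop:::.sample_starts(L, rl, lam) / (2000 - 150))
  }, numeric(1))
  expect_lt(abs(mean_pos[1] - 0.5), 0.01)
  expect_true(all(diff(mean_pos) > 0.02))
})

test_that("ambient pool recovery: cross-species fraction in pure cells", {
  cfg <- sim_config(seed = 31, n_cells_A = 500, n_cells_B = 500,
                    ambient_fraction = 0.05, doublet_rate = 0,
                    contaminated_cell_rate = 0, n_empty_droplets = 0,
                    mean_counts_per_cell = 2000)
  sim <- simulate_droplets(cfg, simulate_annotation(cfg), emit_reads = FALSE)
  sp <- sim$matrix$features$species
  cA <- Matrix::rowSums(sim$matrix$counts[, sp == "A", drop = FALSE])
  cB <- Matrix::rowSums(sim$matrix$counts[, sp == "B", drop = FALSE])
  truth <- sim$droplet_truth
  cross <- ifelse(truth$true_category == "pureA", cB, cA) / (cA + cB)
  observed <- mean(cross[truth$true_category %in% c("pureA", "pureB")])
  # ambient pool is half cross-species here (equal cell numbers)
  expected <- 0.05 * 0.5
  expect_lt(abs(observed - expected) / expected, 0.20)
})

test_that("isoform truth: reads split between SE isoforms near the molar mix", {
  cfg <- sim_config(seed = 13, n_genes_per_species = 4, isoforms_min = 2,
                    isoforms_max = 2, frac_genes_with_SE = 1,
                    n_cells_A = 5, n_cells_B = 5, n_empty_droplets = 0,
                    doublet_rate = 0, ambient_fraction = 0,
                    contaminated_cell_rate = 0, duplicate_rate = 0,
                    ambiguous_read_rate = 0, mean_counts_per_cell = 2000,
                    se_inclusion_prop = 0.7)
  ann <- simulate_annotation(cfg)
  sim <- simulate_droplets(cfg, ann)
  truth <- attr(ann, "se_truth")
  tallies <- sim$read_truth[, .N, by = transcript_id]
  tx <- ann$transcripts
  for (g in truth$gene_id) {
    n_in <- tallies[transcript_id == truth[gene_id == g, inclusion_tx], N]
    n_ex <- tallies[transcript_id == truth[gene_id == g, exclusion_tx], N]
    if (length(n_in) == 0L || length(n_ex) == 0L) next
    # molar 70/30 with length-proportional read emission
    L_in <- tx[transcript_id == truth[gene_id == g, inclusion_tx], length]
    L_ex <- tx[transcript_id == truth[gene_id == g, exclusion_tx], length]
    p_exp <- 0.7 * L_in / (0.7 * L_in + 0.3 * L_ex)
    p_obs <- n_in / (n_in + n_ex)
    expect_lt(abs(p_obs - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / (n_in + n_ex)))
  }
})
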