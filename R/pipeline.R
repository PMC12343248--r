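.stage <- function(name, expr, verbose = TRUE) {
  if (verbose) message("[splicedrop] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulated barnyard pipeline
#'
#' Orchestrates simulate -> preprocess -> call -> coverage/regions ->
#' junctions/skipped exons -> quantify/correlate as one reproducible,
#' seed-deterministic run, writing every intermediate as a plain-text file:
#' annotation.gtf, reads.bed, matrix.mtx + barcodes.tsv + features.tsv,
#' truth.tsv, read_truth.tsv, clean.bed, calls.tsv, profile.tsv,
#' regions.tsv, junctions.tsv, se_events.tsv, tpm_A.tsv, tpm_B.tsv,
#' summary.tsv and the resolved config.yaml.
#'
#' The summary reports droplet category counts, read-filter tallies, the
#' exonic read fraction, the median number of genes detected per called pure
#' cell, and the Pearson correlation between each species' called-cell
#' pseudo-bulk log-TPM and the TPM implied by that species' simulated
#' expression program (expression-recovery check).
#'
#' @param outdir output directory (created)
#' @param config sim_config; the simulation conditions
#' @param thresholds calling_thresholds
#' @param n_bins,coverage_pseudocount gene-body coverage options
#' @param log_pseudocount pseudocount of the correlation log-transform
#' @param verbose log stage progress and record counts via message()
#' @return invisibly, a list with the in-memory results (annotation, sim,
#'   clean_reads, calls, summary table, ...) and `paths` to every file
#' @export
run_pipeline <- function(outdir,
                         config = sim_config(),
                         thresholds = calling_thresholds(),
                         n_bins = 100L,
                         coverage_pseudocount = 1e-9,
                         log_pseudocount = 1,
                         verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  ann <- .stage("simulate_annotation", {
    a <- simulate_annotation(config)
    write_gtf(a, p("annotation.gtf"))
    a
  }, verbose)

  sim <- .stage("simulate_droplets", {
    s <- simulate_droplets(config, ann, emit_reads = TRUE)
    write_bed12(s$reads, p("reads.bed"))
    write_mtx(s$matrix, outdir)
    data.table::fwrite(s$droplet_truth, p("truth.tsv"), sep = "\t", eol = "\n")
    data.table::fwrite(s$read_truth, p("read_truth.tsv"), sep = "\t", eol = "\n")
    s
  }, verbose)

  clean <- .stage("preprocess", {
    kept <- filter_ambiguous(sim$reads)
    n_ambig <- nrow(sim$reads) - nrow(kept)
    deduped <- dedup_reads(kept)
    if (verbose) {
      message(sprintf("[splicedrop]   reads in: %d; ambiguous removed: %d; duplicates removed: %d; out: %d",
                      nrow(sim$reads), n_ambig, nrow(kept) - nrow(deduped),
                      nrow(deduped)))
    }
    write_bed12(deduped, p("clean.bed"))
    deduped
  }, verbose)

  calls <- .stage("cell_calling", {
    cl <- classify_droplets(sim$matrix, thresholds)
    data.table::fwrite(cl, p("calls.tsv"), sep = "\t", eol = "\n")
    cl
  }, verbose)

  profile <- .stage("coverage", {
    pr <- gene_body_coverage(clean, ann, n_bins = n_bins,
                             pseudocount = coverage_pseudocount)
    data.table::fwrite(pr, p("profile.tsv"), sep = "\t", eol = "\n")
    pr
  }, verbose)

  regions <- .stage("regions", {
    rf <- region_fractions(clean, ann)
    data.table::fwrite(data.table::data.table(region = names(rf),
                                              fraction = as.numeric(rf)),
                       p("regions.tsv"), sep = "\t", eol = "\n")
    rf
  }, verbose)

  junc <- .stage("junctions", {
    j <- classify_junctions(extract_junctions(clean), ann)
    data.table::fwrite(j, p("junctions.tsv"), sep = "\t", eol = "\n")
    j
  }, verbose)

  se <- .stage("skipped_exons", {
    ev <- quantify_se(detect_se_events(ann), junc)
    data.table::fwrite(ev, p("se_events.tsv"), sep = "\t", eol = "\n")
    ev
  }, verbose)

  quant <- .stage("quantify_correlate", {
    lens <- gene_lengths(ann)
    out <- list()
    for (sp in c("A", "B")) {
      categ <- paste0("species", sp, "_cell")
      pb <- pseudo_bulk(sim$matrix, calls, categ)
      tp <- if (any(pb > 0)) tpm(pb, lens) else stats::setNames(
        numeric(length(pb)), names(pb))
      data.table::fwrite(data.table::data.table(gene_id = names(tp), tpm = tp),
                         p(sprintf("tpm_%s.tsv", sp)), sep = "\t", eol = "\n")
      # expected TPM from the simulated program (counts ~ program weight)
      prog <- sim$programs[species == sp]
      expw <- stats::setNames(prog$weight, prog$gene_id)
      sp_genes <- names(expw)
      r <- if (any(tp[sp_genes] > 0)) {
        correlate_expression(tp[sp_genes], tpm(expw, lens[sp_genes]),
                             log_pseudocount = log_pseudocount)$r
      } else NA_real_
      out[[sp]] <- list(tpm = tp, program_r = r)
    }
    out
  }, verbose)

  summary_dt <- .stage("summary", {
    cs <- calling_summary(calls)
    pure <- calls[category %in% c("speciesA_cell", "speciesB_cell"), barcode]
    genes_per_cell <- if (length(pure)) {
      stats::median(Matrix::rowSums(sim$matrix$counts[pure, , drop = FALSE] > 0))
    } else NA_real_
    sdt <- data.table::data.table(
      metric = c(paste0("n_", as.character(cs$category)),
                 "exonic_fraction", "intronic_fraction", "intergenic_fraction",
                 "median_genes_per_cell", "program_tpm_r_A", "program_tpm_r_B",
                 "n_reads_raw", "n_reads_clean", "n_junctions", "n_se_events"),
      value = c(cs$n, regions[["exonic"]], regions[["intronic"]],
                regions[["intergenic"]], genes_per_cell,
                quant$A$program_r, quant$B$program_r,
                nrow(sim$reads), nrow(clean), nrow(junc), nrow(se)))
    data.table::fwrite(sdt, p("summary.tsv"), sep = "\t", eol = "\n")
    sdt
  }, verbose)

  yaml::write_yaml(unclass(config), p("config.yaml"))

  invisible(list(
    annotation = ann, sim = sim, clean_reads = clean, calls = calls,
    profile = profile, regions = regions, junctions = junc, se_events = se,
    tpm_A = quant$A$tpm, tpm_B = quant$B$tpm, summary = summary_dt,
    paths = stats::setNames(
      p(c("annotation.gtf", "reads.bed", "matrix.mtx", "barcodes.tsv",
          "features.tsv", "truth.tsv", "read_truth.tsv", "clean.bed",
          "calls.tsv", "profile.tsv", "regions.tsv", "junctions.tsv",
          "se_events.tsv", "tpm_A.tsv", "tpm_B.tsv", "summary.tsv",
          "config.yaml")),
      c("annotation", "reads", "matrix", "barcodes", "features", "truth",
        "read_truth", "clean", "calls", "profile", "regions", "junctions",
        "se_events", "tpm_A", "tpm_B", "summary", "config"))))
}
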