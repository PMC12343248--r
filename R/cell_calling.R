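#' Thresholds for droplet calling
#'
#' The rank-knee empty-droplet rule and the species-classification cutoffs:
#' empties fall at or below 1/`knee_divisor` of the total counts of the
#' barcode at descending rank `knee_rank`; a droplet is a species cell when
#' its counts for that species exceed `min_species_counts` and the other
#' species contributes less than `cross_fraction_max` of its total; droplets
#' failing both species rules are contaminated when their cross-species
#' fraction exceeds `cross_fraction_max` and their total stays below
#' `contaminated_total_max`, and filtered (low-quality or doublet) otherwise.
#' All inequalities are strict.
#'
#' @param knee_rank 1-based descending rank defining the knee (default 100)
#' @param knee_divisor divisor applied to the knee total (default 10)
#' @param min_species_counts per-species count floor for a pure call
#'   (default 1000)
#' @param cross_fraction_max cross-species count fraction ceiling
#'   (default 0.25)
#' @param contaminated_total_max total-count ceiling for the contaminated
#'   category (default 30000)
#' @return list of class `calling_thresholds`
#' @export
calling_thresholds <- function(knee_rank = 100L, knee_divisor = 10,
                               min_species_counts = 1000,
                               cross_fraction_max = 0.25,
                               contaminated_total_max = 30000) {
  th <- list(knee_rank = as.integer(knee_rank), knee_divisor = knee_divisor,
             min_species_counts = min_species_counts,
             cross_fraction_max = cross_fraction_max,
             contaminated_total_max = contaminated_total_max)
  if (any(vapply(th, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all calling thresholds must be positive")
  }
  if (th$cross_fraction_max >= 1) stop("cross_fraction_max must be in (0,1)")
  structure(th, class = "calling_thresholds")
}

#' @rdname classify_droplets
#' @export
droplet_category_levels <- c("speciesA_cell", "speciesB_cell", "contaminated",
                             "filtered", "empty")

# per-barcode species count table
.species_counts <- function(dm) {
  cA <- Matrix::rowSums(dm$counts[, dm$features$species == "A", drop = FALSE])
  cB <- Matrix::rowSums(dm$counts[, dm$features$species == "B", drop = FALSE])
  total <- cA + cB
  data.table::data.table(
    barcode = rownames(dm$counts),
    total_counts = total, counts_A = cA, counts_B = cB,
    cross_fraction = ifelse(total > 0, pmin(cA, cB) / total, 0))
}

#' Empty-droplet threshold from the barcode-rank knee
#'
#' Sorts barcode totals in decreasing order (ties broken by barcode,
#' lexicographically) and returns the total at rank `knee_rank` divided by
#' `knee_divisor`. Barcodes with totals at or below the returned value are
#' treated as empty droplets.
#'
#' @param dm droplet_matrix
#' @param thresholds calling_thresholds
#' @return numeric threshold
#' @export
empty_threshold <- function(dm, thresholds = calling_thresholds()) {
  sc <- .species_counts(dm)
  nz <- sum(sc$total_counts > 0)
  if (nz < thresholds$knee_rank) {
    stop(sprintf(paste0(
      "only %d barcodes with nonzero totals but knee_rank is %d; ",
      "lower knee_rank"), nz, thresholds$knee_rank))
  }
  ord <- order(-sc$total_counts, sc$barcode)
  sc$total_counts[ord][thresholds$knee_rank] / thresholds$knee_divisor
}

#' Classify droplets into the five barnyard categories
#'
#' Applies, in order, to every barcode: (empty) total at or below the
#' rank-knee threshold; (1) species-A cell: counts_A > min_species_counts and
#' counts_B/total < cross_fraction_max; (2) species-B cell: symmetric;
#' (3) contaminated: cross-species fraction > cross_fraction_max and total <
#' contaminated_total_max; (4) filtered otherwise (low-quality cells and
#' doublets; barcodes whose both species counts exceed min_species_counts are
#' additionally flagged `is_likely_doublet`). Categories are exhaustive and
#' mutually exclusive.
#'
#' @param dm droplet_matrix with species-labelled genes
#' @param thresholds calling_thresholds
#' @return data.table: barcode, category (factor over
#'   `droplet_category_levels`), total_counts, counts_A, counts_B,
#'   cross_fraction, is_likely_doublet
#' @export
classify_droplets <- function(dm, thresholds = calling_thresholds()) {
  thr <- empty_threshold(dm, thresholds)
  sc <- .species_counts(dm)
  mn <- thresholds$min_species_counts
  xf <- thresholds$cross_fraction_max
  ct <- thresholds$contaminated_total_max
  fracA <- ifelse(sc$total_counts > 0, sc$counts_A / sc$total_counts, 0)
  fracB <- ifelse(sc$total_counts > 0, sc$counts_B / sc$total_counts, 0)
  categ <- rep("filtered", nrow(sc))
  categ[sc$cross_fraction > xf & sc$total_counts < ct] <- "contaminated"
  categ[sc$counts_B > mn & fracA < xf] <- "speciesB_cell"
  categ[sc$counts_A > mn & fracB < xf] <- "speciesA_cell"
  categ[sc$total_counts <= thr] <- "empty"
  sc[, category := factor(categ, levels = droplet_category_levels)]
  sc[, is_likely_doublet := category == "filtered" & counts_A > mn & counts_B > mn]
  data.table::setcolorder(sc, c("barcode", "category", "total_counts",
                                "counts_A", "counts_B", "cross_fraction",
                                "is_likely_doublet"))
  sc[]
}

#' Per-category droplet summary
#'
#' @param calls output of [classify_droplets()]
#' @return data.table with one row per category: n barcodes, mean/median
#'   total counts; `n` sums to the number of barcodes
#' @export
calling_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no droplet calls to summarise")
  out <- calls[, .(n = .N, mean_counts = mean(total_counts),
                   median_counts = stats::median(total_counts)),
               by = category]
  skel <- data.table::data.table(
    category = factor(droplet_category_levels,
                      levels = droplet_category_levels))
  out <- out[skel, on = "category"]
  out[is.na(n), `:=`(n = 0L, mean_counts = NA_real_, median_counts = NA_real_)]
  out[]
}
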