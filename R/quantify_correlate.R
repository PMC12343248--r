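#' TPM (transcripts per million) from counts and gene lengths
#'
#' rate_g = count_g / length_g; tpm_g = 1e6 * rate_g / sum(rate). Gene
#' lengths are exonic-union lengths in bp (see [gene_lengths()]). The result
#' sums to 1e6 whenever any gene is expressed.
#'
#' @param counts named non-negative numeric vector of per-gene counts
#' @param lengths named positive numeric vector of gene lengths covering
#'   every count gene
#' @return named numeric vector of TPM values (an expression vector)
#' @export
tpm <- function(counts, lengths) {
  if (!is.null(names(counts)) && !is.null(names(lengths))) {
    lengths <- lengths[names(counts)]
  }
  if (length(lengths) != length(counts) || anyNA(lengths)) {
    stop("lengths must cover every count gene")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts are zero; TPM undefined")
  rate <- counts / lengths
  out <- 1e6 * rate / sum(rate)
  names(out) <- names(counts)
  out
}

#' Pseudo-bulk aggregation over called droplets
#'
#' Sums counts per gene over all barcodes carrying the requested category.
#'
#' @param dm droplet_matrix
#' @param calls output of [classify_droplets()]
#' @param category one of `droplet_category_levels`
#' @return named numeric vector of per-gene summed counts; zero vector with
#'   a warning when the category is absent
#' @export
pseudo_bulk <- function(dm, calls, category) {
  bcs <- calls$barcode[calls$category == category]
  bcs <- intersect(bcs, rownames(dm$counts))
  if (length(bcs) == 0L) {
    warning(sprintf("no droplets with category '%s'; returning zero counts",
                    category))
    return(stats::setNames(numeric(ncol(dm$counts)), colnames(dm$counts)))
  }
  Matrix::colSums(dm$counts[bcs, , drop = FALSE])
}

#' Pearson correlation between two expression vectors
#'
#' Computed over the intersection of gene sets after a log10(x + pseudocount)
#' transform. By default all shared genes enter, including double zeros;
#' `expressed_only` restricts to genes expressed in either vector.
#'
#' @param expr1,expr2 named numeric expression vectors (e.g. TPM)
#' @param log_pseudocount pseudocount inside the log10 (default 1)
#' @param expressed_only drop genes with zero in both vectors
#' @return list with r (Pearson coefficient), p (two-sided p-value),
#'   n (genes used)
#' @export
correlate_expression <- function(expr1, expr2, log_pseudocount = 1,
                                 expressed_only = FALSE) {
  shared <- intersect(names(expr1), names(expr2))
  x <- expr1[shared]; y <- expr2[shared]
  if (expressed_only) {
    keep <- x > 0 | y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3L) stop("fewer than 3 shared genes; correlation undefined")
  ct <- stats::cor.test(log10(x + log_pseudocount), log10(y + log_pseudocount),
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
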