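# Alternate-promoter usage statistics.

#' TSS-per-gene distribution across the atlas
#'
#' Counts gene-assigned tag clusters (promoter + intragenic classes) per
#' gene, the mean TSS-per-gene, and the list of genes with at least `k`
#' TSSs (the many-promoter genes that feed enrichment analyses).
#'
#' @param atlas annotated, filtered `tss_atlas`.
#' @param k threshold for the many-TSS gene list (default 10).
#' @return A `usage_summary`: list with `n_tss` (named integer per gene),
#'   `mean_tss_per_gene`, `histogram` (data.table `n_tss, n_genes`) and
#'   `genes_ge_k`.
#' @export
tss_per_gene <- function(atlas, k = 10L) {
  cl <- atlas$clusters
  genic <- cl[annotation_class %in% c("promoter", "intragenic") &
                !is.na(gene_id)]
  n_tss <- sort(table(genic$gene_id), decreasing = TRUE)
  n_tss <- setNames(as.integer(n_tss), names(n_tss))
  hist <- as.data.table(table(n_tss))
  setnames(hist, c("n_tss", "n_genes"))
  hist[, n_tss := as.integer(n_tss)]
  structure(list(
    n_tss = n_tss,
    mean_tss_per_gene = if (length(n_tss)) mean(n_tss) else NA_real_,
    histogram = hist[],
    k = k,
    genes_ge_k = names(n_tss)[n_tss >= k]), class = "usage_summary")
}

#' @export
print.usage_summary <- function(x, ...) {
  cat("usage_summary:", length(x$n_tss), "genes, mean",
      round(x$mean_tss_per_gene, 3), "TSS/gene;", length(x$genes_ge_k),
      "genes with >=", x$k, "TSSs\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 contingency table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table (with a 1e-7 relative tolerance against floating
#' point ties, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d the four cells, row-wise.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("fisher_2x2 needs non-negative integer cells")
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0) return(1)
  lo <- max(0L, c1 - (n - r1))
  hi <- min(c1, r1)
  kk <- lo:hi
  probs <- dhyper(kk, c1, n - c1, r1)
  p_obs <- probs[kk == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Per-sample vs atlas-wide promoter usage contrast
#'
#' Tests whether a sample's TSS:gene balance differs from the rest of the
#' atlas with a two-sided Fisher exact test on the 2x2 table
#' `[[n_tss_sample, n_gene_sample], [n_tss_atlas - n_tss_sample,
#' n_gene_atlas - n_gene_sample]]`.
#'
#' @param n_tss_sample,n_gene_sample expressed TSS and gene counts in one
#'   sample.
#' @param n_tss_atlas,n_gene_atlas atlas-wide totals (must be at least the
#'   sample counts).
#' @export
usage_fisher <- function(n_tss_sample, n_gene_sample,
                         n_tss_atlas, n_gene_atlas) {
  if (any(c(n_tss_sample, n_gene_sample, n_tss_atlas, n_gene_atlas) <= 0))
    stop("all counts must be positive")
  c2 <- n_tss_atlas - n_tss_sample
  d2 <- n_gene_atlas - n_gene_sample
  if (c2 < 0 || d2 < 0)
    stop("sample counts exceed atlas counts")
  fisher_2x2(n_tss_sample, n_gene_sample, c2, d2)
}

#' Cell-type signature (up / down) gene calls
#'
#' A gene is "up" in cell type T iff its mean TPM over T's replicates is
#' at least `fold` times the mean over all other samples and at least
#' `min_tpm`; "down" iff its mean in T is at most `mean(rest) / fold` and
#' the rest mean is at least `min_tpm`.  Gene expression should be the sum
#' of the gene's TSS cluster TPMs (see [gene_expression()]).
#'
#' @param mat gene-by-sample TPM matrix.
#' @param sheet sample sheet with `sample_id` and `cell_type`.
#' @param fold fold-change threshold (> 1), default 4.
#' @param min_tpm expression floor, default 5 TPM.
#' @return named list per cell type: `list(up = ..., down = ...)`.
#' @export
signature_genes <- function(mat, sheet, fold = 4, min_tpm = 5) {
  stopifnot(fold > 1)
  sheet <- as.data.table(sheet)
  if (!all(sheet$sample_id %in% colnames(mat)))
    stop("sample sheet samples missing from matrix")
  types <- unique(sheet$cell_type)
  out <- lapply(types, function(tt) {
    sT <- sheet[cell_type == tt, sample_id]
    sR <- sheet[cell_type != tt, sample_id]
    if (length(sT) < 2)
      warning("cell type ", tt, " has fewer than 2 replicates")
    mT <- rowMeans(mat[, sT, drop = FALSE])
    mR <- rowMeans(mat[, sR, drop = FALSE])
    list(up = rownames(mat)[mT >= fold * mR & mT >= min_tpm],
         down = rownames(mat)[mT <= mR / fold & mR >= min_tpm])
  })
  names(out) <- types
  out
}
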