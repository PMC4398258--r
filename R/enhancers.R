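# Candidate enhancer calling from balanced bidirectional transcription,
# cell-type restriction scoring, and coexpression-based gene linking.

#' Call candidate enhancers from divergent tag-cluster pairs
#'
#' A candidate is a (reverse-strand, forward-strand) tag-cluster pair with
#' the reverse summit left of the forward summit and summit separation at
#' most `pair_window` bp -- the divergent geometry of enhancer RNA
#' transcription.  Candidates whose spanning region lies within 500 bp of
#' any transcript 5' end or overlaps any gene body are rejected (those are
#' promoter-associated antisense pairs, not enhancers).  The directionality
#' score `D = (F - R) / (F + R)` uses pooled (across-sample) tag counts;
#' calls require `|D| <= balance` (inclusive) and pooled expression of at
#' least `min_tpm` TPM in at least one sample.  Overlapping candidates are
#' resolved by keeping the highest-expression pair.
#'
#' @param atlas annotated, TPM-normalised `tss_atlas`.
#' @param models `gene_models` used for the genic exclusion.
#' @param pair_window maximum summit separation in bp (default 400).
#' @param balance inclusive bound on `|D|` (default 0.8).
#' @param min_tpm minimum pooled per-sample TPM in at least one sample
#'   (default 2).
#' @param promoter_window exclusion distance around transcript 5' ends
#'   (default 500).
#' @return An `enhancer_calls` object: list with `calls` (data.table
#'   `enhancer_id, chrom, start, end, center, rev_cluster, fwd_cluster,
#'   F, R, D, max_tpm`) and `tpm` (enhancers x samples pooled TPM).
#' @export
call_enhancers <- function(atlas, models, pair_window = 400L, balance = 0.8,
                           min_tpm = 2, promoter_window = 500L) {
  if (is.null(atlas$tpm)) stop("run normalize_tpm() first")
  cl <- atlas$clusters
  empty <- structure(list(
    calls = data.table(enhancer_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       center = integer(), rev_cluster = character(),
                       fwd_cluster = character(), F = numeric(),
                       R = numeric(), D = numeric(), max_tpm = numeric()),
    tpm = matrix(0, 0, length(atlas$samples),
                 dimnames = list(NULL, atlas$samples))),
    class = "enhancer_calls")
  minus <- cl[strand == "-"]
  plus <- cl[strand == "+"]
  if (!nrow(minus) || !nrow(plus)) return(empty)

  # divergent pairs: rev summit strictly left of fwd summit, close by
  cand <- minus[, .(chrom, rev_cluster = cluster_id, rev_summit = summit,
                    rev_start = start, rev_end = end)][
    plus[, .(chrom, fwd_cluster = cluster_id, fwd_summit = summit,
             fwd_start = start, fwd_end = end)],
    on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  cand <- cand[fwd_summit > rev_summit &
                 fwd_summit - rev_summit <= pair_window]
  if (!nrow(cand)) return(empty)
  cand[, `:=`(start = pmin(rev_start, fwd_start),
              end = pmax(rev_end, fwd_end),
              center = as.integer(floor((rev_summit + fwd_summit) / 2)))]

  # genic exclusion: near a transcript 5' end or overlapping a gene body
  tx <- models$transcripts
  qr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1L, cand$end))
  p5 <- GenomicRanges::GRanges(tx$chrom,
                               IRanges::IRanges(tx$tss + 1L - promoter_window,
                                                tx$tss + 1L + promoter_window))
  gb <- GenomicRanges::GRanges(models$genes$chrom,
                               IRanges::IRanges(models$genes$start + 1L,
                                                models$genes$end))
  bad <- union(
    S4Vectors::queryHits(GenomicRanges::findOverlaps(qr, p5,
                                                     ignore.strand = TRUE)),
    S4Vectors::queryHits(GenomicRanges::findOverlaps(qr, gb,
                                                     ignore.strand = TRUE)))
  if (length(bad)) cand <- cand[-bad]
  if (!nrow(cand)) return(empty)

  pooled <- rowSums(atlas$counts)
  cand[, `:=`(F = pooled[fwd_cluster], R = pooled[rev_cluster])]
  cand <- cand[F + R > 0]
  cand[, D := (F - R) / (F + R)]
  cand <- cand[abs(D) <= balance]
  if (!nrow(cand)) return(empty)
  ptpm <- atlas$tpm[cand$fwd_cluster, , drop = FALSE] +
    atlas$tpm[cand$rev_cluster, , drop = FALSE]
  cand[, max_tpm := apply(ptpm, 1, max)]
  keep <- cand$max_tpm >= min_tpm
  cand <- cand[keep]; ptpm <- ptpm[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  # resolve overlapping candidates: highest total expression wins
  tot <- rowSums(ptpm)
  ord <- order(-tot, cand$chrom, cand$start)
  taken_cl <- character()
  kept <- logical(nrow(cand))
  regions <- list()
  for (i in ord) {
    if (cand$rev_cluster[i] %in% taken_cl ||
        cand$fwd_cluster[i] %in% taken_cl) next
    ov <- FALSE
    for (r in regions) {
      if (r$chrom == cand$chrom[i] && cand$start[i] < r$end &&
          r$start < cand$end[i]) { ov <- TRUE; break }
    }
    if (ov) next
    kept[i] <- TRUE
    taken_cl <- c(taken_cl, cand$rev_cluster[i], cand$fwd_cluster[i])
    regions[[length(regions) + 1]] <- list(chrom = cand$chrom[i],
                                           start = cand$start[i],
                                           end = cand$end[i])
  }
  cand <- cand[kept]; ptpm <- ptpm[kept, , drop = FALSE]
  ord2 <- order(cand$chrom, cand$start)
  cand <- cand[ord2]; ptpm <- ptpm[ord2, , drop = FALSE]
  cand[, enhancer_id := sprintf("ENH%04d", .I)]
  rownames(ptpm) <- cand$enhancer_id
  setcolorder(cand, c("enhancer_id", "chrom", "start", "end", "center",
                      "rev_cluster", "fwd_cluster", "F", "R", "D",
                      "max_tpm"))
  structure(list(calls = cand[, .(enhancer_id, chrom, start, end, center,
                                  rev_cluster, fwd_cluster, F, R, D,
                                  max_tpm)],
                 tpm = ptpm), class = "enhancer_calls")
}

#' @export
print.enhancer_calls <- function(x, ...) {
  cat("enhancer_calls:", nrow(x$calls), "candidate enhancers\n")
  invisible(x)
}

#' Cell-type restriction of an expression profile
#'
#' An enhancer (or any feature) is restricted to cell type T iff its mean
#' TPM over T's replicates is at least `on_tpm` and the mean of every
#' other cell type is below `off_tpm`; `NA` if no type (or more than one)
#' qualifies.
#'
#' @param tpm numeric matrix features x samples (e.g. `enhancer_calls$tpm`)
#'   or a single named vector.
#' @param sheet sample sheet with `sample_id`, `cell_type`.
#' @param on_tpm,off_tpm thresholds (defaults 5 and 1).
#' @return character vector (one per feature) of cell types or `NA`.
#' @export
restriction_call <- function(tpm, sheet, on_tpm = 5, off_tpm = 1) {
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = 1,
                                       dimnames = list("x", names(tpm)))
  sheet <- as.data.table(sheet)
  types <- unique(sheet$cell_type)
  tm <- vapply(types, function(tt) {
    rowMeans(tpm[, sheet[cell_type == tt, sample_id], drop = FALSE])
  }, numeric(nrow(tpm)))
  if (is.null(dim(tm))) tm <- matrix(tm, nrow = 1)
  colnames(tm) <- types
  apply(tm, 1, function(v) {
    qual <- names(v)[v >= on_tpm & vapply(seq_along(v), function(j)
      all(v[-j] < off_tpm), TRUE)]
    if (length(qual) == 1) qual else NA_character_
  })
}

#' Link enhancers to genes by expression correlation
#'
#' For every promoter-class TSS cluster whose summit lies within
#' `max_dist` of the enhancer center (same chromosome), computes Pearson r
#' between the log2(TPM + 1) profiles of the enhancer and the promoter;
#' genes are linked iff `r >= min_r`, reported best-r-first (one row per
#' gene, keeping its best promoter).  Zero-variance profiles are skipped.
#'
#' @param enhancers an `enhancer_calls` object.
#' @param atlas annotated, TPM-normalised `tss_atlas`.
#' @param max_dist linking distance in bp (default 500 kb).
#' @param min_r correlation threshold (default 0.7).
#' @return named list (per enhancer id) of data.tables `gene_id,
#'   cluster_id, r`.
#' @export
link_genes <- function(enhancers, atlas, max_dist = 5e5, min_r = 0.7) {
  if (ncol(atlas$tpm) < 3) stop("need >= 3 samples for correlation linking")
  cl <- atlas$clusters
  prom <- cl[annotation_class == "promoter"]
  elog <- log2(enhancers$tpm + 1)
  plog <- log2(atlas$tpm[prom$cluster_id, , drop = FALSE] + 1)
  out <- lapply(seq_len(nrow(enhancers$calls)), function(i) {
    e <- enhancers$calls[i]
    inrange <- prom[chrom == e$chrom & abs(summit - e$center) <= max_dist]
    res <- data.table(gene_id = character(), cluster_id = character(),
                      r = numeric())
    ev <- elog[i, ]
    if (nrow(inrange) && sd(ev) > 0) {
      rs <- vapply(inrange$cluster_id, function(cid) {
        pv <- plog[cid, ]
        if (sd(pv) == 0) NA_real_ else cor(ev, pv)
      }, 0)
      ok <- !is.na(rs) & rs >= min_r
      if (any(ok)) {
        res <- data.table(gene_id = inrange$gene_id[ok],
                          cluster_id = inrange$cluster_id[ok],
                          r = rs[ok])
        res <- res[order(-r)][, head(.SD, 1), by = gene_id]
        setorder(res, -r)
      }
    }
    res[]
  })
  names(out) <- enhancers$calls$enhancer_id
  out
}
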