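# Multi-sample TSS atlas: tag clustering, TPM normalisation, expression
# filtering, strand-aware annotation and gene assignment.

#' Cluster neighboring CAGE tags into strand-specific TSS regions
#'
#' Single-linkage clustering of pooled tag positions per (chromosome,
#' strand): two positions join one cluster iff their gap is at most
#' `max_gap` base pairs.  Clusters never span strands or chromosomes.
#' This is a deterministic, distance-based stand-in for decomposition
#' style peak calling used by large CAGE consortia pipelines.
#'
#' @param tracks named list of CTSS data.tables (see [read_ctss()]); names
#'   are sample ids.
#' @param max_gap maximum gap (bp) between neighboring tag positions that
#'   still join one cluster.  Default 20.
#' @return A `tss_atlas`: list with `clusters` (data.table: `cluster_id,
#'   chrom, start, end, strand, summit, total_count, annotation_class,
#'   gene_id, distance_to_5p`), a `counts` matrix (clusters x samples) and
#'   placeholders for `tpm` / `library_sizes`.
#' @export
cluster_tags <- function(tracks, max_gap = 20L) {
  stopifnot(max_gap >= 0)
  if (!length(tracks) || all(vapply(tracks, nrow, 0L) == 0L)) {
    return(empty_atlas(names(tracks)))
  }
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list (sample ids)")
  pooled <- rbindlist(lapply(names(tracks), function(s) {
    dt <- tracks[[s]]
    data.table(chrom = dt$chrom, pos = dt$start, strand = dt$strand,
               count = dt$count, sample = s)
  }))
  bypos <- pooled[, .(pooled = sum(count)), by = .(chrom, pos, strand)]
  setorder(bypos, chrom, strand, pos)
  bypos[, gap_break := {
    d <- pos - shift(pos)
    as.integer(is.na(d) | d > max_gap)
  }, by = .(chrom, strand)]
  bypos[, cl := cumsum(gap_break)]
  clusters <- bypos[, .(chrom = chrom[1], strand = strand[1],
                        start = min(pos), end = max(pos) + 1L,
                        summit = pos[which.max(pooled)],
                        total_count = sum(pooled)),
                    by = cl]
  setorder(clusters, chrom, start, strand)
  clusters[, cluster_id := sprintf("TC%06d", .I)]
  clusters[, `:=`(annotation_class = NA_character_, gene_id = NA_character_,
                  distance_to_5p = NA_integer_)]
  # per-sample counts
  key <- bypos[, .(chrom, pos, strand, cl)]
  pooled <- merge(pooled, key, by = c("chrom", "pos", "strand"))
  idmap <- clusters[, setNames(cluster_id, cl)]
  pooled[, cluster_id := idmap[as.character(cl)]]
  agg <- pooled[, .(count = sum(count)), by = .(cluster_id, sample)]
  counts <- matrix(0, nrow = nrow(clusters), ncol = length(tracks),
                   dimnames = list(clusters$cluster_id, names(tracks)))
  counts[cbind(agg$cluster_id, agg$sample)] <- agg$count
  setcolorder(clusters, c("cluster_id", "chrom", "start", "end", "strand",
                          "summit", "total_count", "annotation_class",
                          "gene_id", "distance_to_5p"))
  clusters[, cl := NULL]
  structure(list(clusters = clusters[], counts = counts, tpm = NULL,
                 library_sizes = NULL, samples = names(tracks)),
            class = "tss_atlas")
}

empty_atlas <- function(samples = character()) {
  clusters <- data.table(cluster_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), summit = integer(),
                         total_count = numeric(),
                         annotation_class = character(),
                         gene_id = character(), distance_to_5p = integer())
  structure(list(clusters = clusters,
                 counts = matrix(0, 0, length(samples),
                                 dimnames = list(NULL, samples)),
                 tpm = NULL, library_sizes = NULL,
                 samples = samples %||% character()),
            class = "tss_atlas")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tss_atlas <- function(x, ...) {
  cat("tss_atlas:", nrow(x$clusters), "tag clusters x", length(x$samples),
      "samples;", if (is.null(x$tpm)) "counts only" else "TPM normalised", "\n")
  if (!all(is.na(x$clusters$annotation_class))) {
    print(table(x$clusters$annotation_class))
  }
  invisible(x)
}

#' Subset an atlas to a set of cluster ids
#' @param atlas a `tss_atlas`.
#' @param ids cluster ids to keep.
#' @export
subset_atlas <- function(atlas, ids) {
  keep <- atlas$clusters$cluster_id %in% ids
  atlas$clusters <- atlas$clusters[keep]
  atlas$counts <- atlas$counts[keep, , drop = FALSE]
  if (!is.null(atlas$tpm)) atlas$tpm <- atlas$tpm[keep, , drop = FALSE]
  atlas
}

#' Normalise atlas counts to tags per million (TPM)
#'
#' `tpm[i, s] = counts[i, s] * 1e6 / library_size[s]`.  The library size is
#' the total mapped tag count of the full per-sample track, not a
#' post-filter total; by default it is taken from the column sums of the
#' (unfiltered) atlas, which equal the track totals because clustering
#' partitions every tag position.
#'
#' @param atlas a `tss_atlas`.
#' @param library_sizes optional named numeric vector of per-sample totals.
#' @export
normalize_tpm <- function(atlas, library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- colSums(atlas$counts)
  library_sizes <- library_sizes[colnames(atlas$counts)]
  if (anyNA(library_sizes)) stop("library_sizes missing for some samples")
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  atlas$tpm <- sweep(atlas$counts, 2, library_sizes, "/") * 1e6
  atlas$library_sizes <- library_sizes
  atlas
}

#' Keep tag clusters expressed at or above a TPM threshold in any sample
#'
#' A cluster is kept iff its maximum TPM over samples is `>= min_tpm`
#' (inclusive, reading "at least" literally).
#' @param atlas TPM-normalised `tss_atlas`.
#' @param min_tpm inclusive threshold, default 5 tags/million.
#' @export
filter_expressed <- function(atlas, min_tpm = 5) {
  if (is.null(atlas$tpm)) stop("run normalize_tpm() first")
  if (!nrow(atlas$clusters)) return(atlas)
  keep <- apply(atlas$tpm, 1, max) >= min_tpm
  subset_atlas(atlas, atlas$clusters$cluster_id[keep])
}

#' Annotate tag clusters relative to gene models
#'
#' Class `promoter` if the cluster summit lies within `window` bp of a
#' same-strand transcript 5' end (nearest wins; ties broken by the
#' lexicographically smaller gene id); else `intragenic` if the summit
#' falls inside a same-strand gene body (assigned to that gene); else
#' `intergenic`.  Precedence promoter > intragenic > intergenic.
#' Antisense clusters near a 5' end are deliberately NOT promoters:
#' antisense transcription at promoters/enhancers is handled by the
#' enhancer caller.
#'
#' `distance_to_5p` is signed and transcription-oriented: positive means
#' the summit is downstream of the 5' end.
#'
#' @param atlas a `tss_atlas`.
#' @param models a `gene_models` object.
#' @param window promoter window in bp (default 500).
#' @export
annotate_tss <- function(atlas, models, window = 500L) {
  cl <- copy(atlas$clusters)
  if (!nrow(cl)) { atlas$clusters <- cl; return(atlas) }
  tx <- models$transcripts
  cl[, annotation_class := "intergenic"]
  cl[, gene_id := NA_character_]
  cl[, distance_to_5p := NA_integer_]

  # promoter assignment: nearest same-strand transcript 5' end within window
  for (grp in split(seq_len(nrow(cl)),
                    list(cl$chrom, cl$strand), drop = TRUE)) {
    ch <- cl$chrom[grp[1]]; st <- cl$strand[grp[1]]
    cand <- tx[chrom == ch & strand == st]
    if (!nrow(cand)) next
    tssv <- cand$tss; gv <- cand$gene_id
    ord <- order(tssv, gv)
    tssv <- tssv[ord]; gv <- gv[ord]
    for (i in grp) {
      s <- cl$summit[i]
      j <- findInterval(s, tssv)
      idx <- unique(pmax(1L, pmin(length(tssv), c(j, j + 1L))))
      dmin <- min(abs(s - tssv[idx]))
      if (dmin <= window) {
        vals <- unique(tssv[idx][abs(s - tssv[idx]) == dmin])
        g <- min(gv[tssv %in% vals])
        cl[i, `:=`(annotation_class = "promoter", gene_id = g,
                   distance_to_5p = as.integer(
                     if (st == "+") s - vals[1] else vals[1] - s))]
      }
    }
  }

  # intragenic: summit inside a same-strand gene body
  todo <- which(cl$annotation_class == "intergenic")
  if (length(todo) && nrow(models$genes)) {
    g <- models$genes
    qr <- GenomicRanges::GRanges(cl$chrom[todo],
                                 IRanges::IRanges(cl$summit[todo] + 1L,
                                                  width = 1L),
                                 strand = cl$strand[todo])
    sr <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start + 1L, g$end),
                                 strand = g$strand)
    ov <- GenomicRanges::findOverlaps(qr, sr, ignore.strand = FALSE)
    if (length(ov)) {
      hit <- data.table(q = S4Vectors::queryHits(ov),
                        gene = g$gene_id[S4Vectors::subjectHits(ov)])
      hit <- hit[, .(gene = min(gene)), by = q]
      cl[todo[hit$q], `:=`(annotation_class = "intragenic", gene_id = hit$gene)]
    }
  }
  atlas$clusters <- cl[]
  atlas
}

#' Per-sample expressed-TSS and gene counts
#'
#' For each sample: the number of clusters with TPM at or above `min_tpm`
#' in that sample, the number of distinct genes among them (promoter and
#' intragenic classes), and the TSS-per-gene ratio.  Samples with zero
#' expressed gene-assigned TSSs get `NA` ratio.
#'
#' @param atlas annotated, TPM-normalised `tss_atlas`.
#' @param min_tpm inclusive per-sample expression threshold (default 5).
#' @return data.table `sample, n_tss, n_genes, ratio`.
#' @export
per_sample_expressed <- function(atlas, min_tpm = 5) {
  if (is.null(atlas$tpm)) stop("run normalize_tpm() first")
  cl <- atlas$clusters
  genic <- cl$annotation_class %in% c("promoter", "intragenic")
  rbindlist(lapply(atlas$samples, function(s) {
    expr <- atlas$tpm[, s] >= min_tpm
    n_tss <- sum(expr)
    genes <- unique(cl$gene_id[expr & genic])
    n_genes <- length(genes)
    data.table(sample = s, n_tss = n_tss, n_genes = n_genes,
               ratio = if (n_genes > 0) n_tss / n_genes else NA_real_)
  }))
}

#' Intergenic clusters overlapping noncoding annotation
#'
#' Returns the subset of intergenic-class clusters whose interval overlaps
#' at least 1 bp of any interval in `noncoding` (strand-agnostic).
#' @param atlas annotated `tss_atlas`.
#' @param noncoding interval data.table (e.g. from [read_bed()]).
#' @export
overlap_noncoding <- function(atlas, noncoding) {
  cl <- atlas$clusters
  inter <- which(cl$annotation_class == "intergenic")
  if (!length(inter) || !nrow(noncoding))
    return(subset_atlas(atlas, character()))
  qr <- GenomicRanges::GRanges(cl$chrom[inter],
                               IRanges::IRanges(cl$start[inter] + 1L,
                                                cl$end[inter]))
  sr <- GenomicRanges::GRanges(noncoding$chrom,
                               IRanges::IRanges(noncoding$start + 1L,
                                                noncoding$end))
  ov <- GenomicRanges::findOverlaps(qr, sr, ignore.strand = TRUE)
  keep <- cl$cluster_id[inter[unique(S4Vectors::queryHits(ov))]]
  subset_atlas(atlas, keep)
}

#' Gene-level expression matrix (sum of a gene's TSS cluster TPMs)
#' @param atlas annotated, TPM-normalised `tss_atlas`.
#' @param units which per-cluster matrix to aggregate.
#' @export
gene_expression <- function(atlas, units = c("tpm", "counts")) {
  units <- match.arg(units)
  m <- if (units == "tpm") atlas$tpm else atlas$counts
  if (is.null(m)) stop("matrix not available; run normalize_tpm() first")
  cl <- atlas$clusters
  genic <- cl$annotation_class %in% c("promoter", "intragenic") &
    !is.na(cl$gene_id)
  m <- m[genic, , drop = FALSE]
  gid <- cl$gene_id[genic]
  out <- rowsum(m, gid)
  attr(out, "units") <- units
  out
}

#' Serialize / read an atlas as TSV
#'
#' One row per cluster with metadata columns followed by `count_<sample>`
#' columns; library sizes are stored in a `#library_sizes` header comment
#' so TPM can be reconstituted.
#' @param atlas a `tss_atlas`.
#' @param path TSV path.
#' @export
write_atlas <- function(atlas, path) {
  dt <- copy(atlas$clusters)
  cm <- as.data.table(atlas$counts)
  setnames(cm, paste0("count_", colnames(atlas$counts)))
  dt <- cbind(dt, cm)
  hdr <- if (!is.null(atlas$library_sizes)) {
    paste0("#library_sizes\t",
           paste(sprintf("%s=%.10g", names(atlas$library_sizes),
                         atlas$library_sizes), collapse = ";"))
  }
  writeLines(c(hdr, paste(names(dt), collapse = "\t")), path)
  if (nrow(dt)) {
    fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
           append = TRUE)
  }
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  first <- readLines(path, n = 1L)
  lib <- NULL
  if (startsWith(first, "#library_sizes")) {
    spec <- strsplit(sub("^#library_sizes\t", "", first), ";")[[1]]
    kv <- strsplit(spec, "=")
    lib <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  }
  dt <- fread(path, sep = "\t", header = TRUE, skip = if (is.null(lib)) 0 else 1)
  ccols <- grep("^count_", names(dt), value = TRUE)
  counts <- as.matrix(dt[, ccols, with = FALSE])
  colnames(counts) <- sub("^count_", "", ccols)
  rownames(counts) <- dt$cluster_id
  clusters <- dt[, !ccols, with = FALSE]
  for (col in c("annotation_class", "gene_id")) {
    if (is.logical(clusters[[col]])) clusters[, (col) := NA_character_]
    else clusters[get(col) == "", (col) := NA_character_]
  }
  if (is.logical(clusters$distance_to_5p))
    clusters[, distance_to_5p := NA_integer_]
  atlas <- structure(list(clusters = clusters[], counts = counts, tpm = NULL,
                          library_sizes = NULL,
                          samples = colnames(counts)),
                     class = "tss_atlas")
  if (!is.null(lib)) atlas <- normalize_tpm(atlas, lib)
  atlas
}
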