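#' @import data.table
#' @importFrom stats cor p.adjust phyper dhyper rnbinom rpois runif rmultinom
#'   quantile setNames sd
#' @importFrom utils head tail
NULL

# All genomic intervals in this package are 0-based half-open [start, end)
# with strand in {+, -, .}.  GTF input/output is the only place 1-based
# closed coordinates appear.

.check_interval_dt <- function(x) {
  stopifnot(all(x$start >= 0), all(x$end > x$start))
  invisible(x)
}

#' Read a CTSS track (BED6, one row per tag position)
#'
#' A CTSS (CAGE transcription start site) track stores per-base, per-strand
#' 5' tag counts as BED6: `chrom, start, end, name, count, strand` with
#' `end == start + 1`.  The score column carries the raw integer tag count.
#'
#' @param path path to a CTSS BED file.
#' @return A `data.table` with columns `chrom, start, end, name, count,
#'   strand`, sorted by `(chrom, start, strand)`.
#' @export
read_ctss <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) != 6L)
    stop("CTSS file must have exactly 6 columns, got ", ncol(dt), ": ", path)
  setnames(dt, c("chrom", "start", "end", "name", "count", "strand"))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0)
  if (length(bad))
    stop("malformed CTSS line ", bad[1], " in ", path)
  bad <- which(dt$end != dt$start + 1L)
  if (length(bad))
    stop("CTSS format error at line ", bad[1], ": end must equal start + 1")
  cnt <- suppressWarnings(as.integer(dt$count))
  bad <- which(is.na(cnt) | cnt < 0)
  if (length(bad))
    stop("CTSS format error at line ", bad[1], ": count must be a non-negative integer")
  dt[, count := cnt]
  if (!all(dt$strand %in% c("+", "-")))
    stop("CTSS strand must be '+' or '-': ", path)
  if (anyDuplicated(dt, by = c("chrom", "start", "strand")))
    stop("duplicate (chrom, start, strand) rows in CTSS file: ", path)
  setorder(dt, chrom, start, strand)
  dt[]
}

#' Write a CTSS track as BED6
#'
#' @param track a CTSS `data.table` as returned by [read_ctss()].
#' @param path output path.
#' @export
write_ctss <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "count", "strand") %in% names(track)))
  out <- data.table(chrom = track$chrom, start = track$start, end = track$end,
                    name = if ("name" %in% names(track)) track$name else ".",
                    count = track$count, strand = track$strand)
  setorder(out, chrom, start, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file (BED6 or first 6 columns of BED12)
#'
#' @param path BED path; 0-based half-open coordinates are kept as-is.
#' @return `data.table` with `chrom, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("BED needs >= 3 columns: ", path)
  res <- data.table(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    name = if (ncol(dt) >= 4) as.character(dt[[4]]) else ".",
                    score = if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]])) else 0,
                    strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".")
  .check_interval_dt(res)
  res[]
}

#' Write intervals as BED6
#' @param intervals `data.table` with at least `chrom, start, end`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.table(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end,
                    name = if ("name" %in% names(intervals)) intervals$name else ".",
                    score = if ("score" %in% names(intervals)) intervals$score else 0,
                    strand = if ("strand" %in% names(intervals)) intervals$strand else ".")
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_gtf_attr <- function(attr, key) {
  m <- regexpr(paste0(key, ' "[^"]*"'), attr)
  out <- rep(NA_character_, length(attr))
  ok <- m != -1L
  val <- regmatches(attr, m)
  val <- sub(paste0(key, ' "'), "", val, fixed = TRUE)
  val <- sub('"', "", val, fixed = TRUE)
  out[ok] <- val
  out
}

#' Read gene models from GTF
#'
#' GTF coordinates (1-based, closed) are converted to the package-internal
#' 0-based half-open convention.  Transcripts are grouped under `gene_id`;
#' each transcript's 5' end is computed strand-aware (`start` on `+`,
#' `end - 1` on `-`).
#'
#' @param path GTF path.
#' @return An object of class `gene_models`: a list with `genes` and
#'   `transcripts` data.tables; `transcripts$tss` holds the 5' end position.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty GTF: ", path)
  dt <- fread(text = lines, header = FALSE, sep = "\t", quote = "",
              colClasses = list(character = 1))
  if (ncol(dt) != 9L) stop("GTF must have 9 columns: ", path)
  setnames(dt, c("chrom", "source", "feature", "start1", "end1", "score",
                 "strand", "frame", "attr"))
  keep <- dt$feature %in% c("transcript", "exon")
  tx <- dt[keep]
  if (!nrow(tx)) stop("GTF contains no transcript/exon features: ", path)
  tx[, gene_id := .parse_gtf_attr(attr, "gene_id")]
  tx[, transcript_id := .parse_gtf_attr(attr, "transcript_id")]
  if (anyNA(tx$transcript_id))
    stop("GTF transcript/exon feature without transcript_id: ", path)
  if (anyNA(tx$gene_id))
    stop("GTF transcript without gene_id: ", path)
  # 1-based closed [start1, end1] -> 0-based half-open [start1-1, end1)
  tx[, `:=`(start = start1 - 1L, end = end1)]
  transcripts <- tx[, .(chrom = chrom[1], start = min(start), end = max(end),
                        strand = strand[1], gene_id = gene_id[1]),
                    by = transcript_id]
  transcripts[, tss := fifelse(strand == "+", start, end - 1L)]
  genes <- transcripts[, .(chrom = chrom[1], start = min(start),
                           end = max(end), strand = strand[1]), by = gene_id]
  setorder(transcripts, chrom, start)
  setorder(genes, chrom, start)
  gene_models(genes, transcripts)
}

#' Construct a gene_models object
#' @param genes data.table `gene_id, chrom, start, end, strand`.
#' @param transcripts data.table `transcript_id, gene_id, chrom, start, end,
#'   strand, tss`.
#' @export
gene_models <- function(genes, transcripts) {
  genes <- as.data.table(genes); transcripts <- as.data.table(transcripts)
  .check_interval_dt(genes); .check_interval_dt(transcripts)
  if (!"tss" %in% names(transcripts))
    transcripts[, tss := fifelse(strand == "+", start, end - 1L)]
  structure(list(genes = genes[], transcripts = transcripts[]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts\n")
  invisible(x)
}

#' Write gene models as GTF (gene, transcript and single-exon rows)
#' @param models a `gene_models` object.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes; tx <- models$transcripts
  gl <- sprintf('%s\tcageatlas\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  tl <- sprintf(paste0('%s\tcageatlas\ttranscript\t%d\t%d\t.\t%s\t.\t',
                       'gene_id "%s"; transcript_id "%s";'),
                tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$gene_id,
                tx$transcript_id)
  el <- sprintf(paste0('%s\tcageatlas\texon\t%d\t%d\t.\t%s\t.\t',
                       'gene_id "%s"; transcript_id "%s"; exon_number "1";'),
                tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$gene_id,
                tx$transcript_id)
  ord <- order(c(g$chrom, tx$chrom, tx$chrom),
               c(g$start, tx$start, tx$start))
  writeLines(c(gl, tl, el)[ord], path)
  invisible(path)
}

#' Read gene models from BED12
#'
#' The BED12 `name` column is used as both transcript id and gene id
#' (BED12 carries no gene grouping).  Coordinates stay 0-based half-open;
#' 5' ends are strand-aware as in [read_gtf()].
#' @param path BED12 path.
#' @export
read_bed12 <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) < 12L) stop("BED12 needs 12 columns: ", path)
  transcripts <- data.table(transcript_id = as.character(dt[[4]]),
                            gene_id = as.character(dt[[4]]),
                            chrom = as.character(dt[[1]]),
                            start = as.integer(dt[[2]]),
                            end = as.integer(dt[[3]]),
                            strand = as.character(dt[[6]]))
  transcripts[, tss := fifelse(strand == "+", start, end - 1L)]
  genes <- transcripts[, .(chrom = chrom[1], start = min(start),
                           end = max(end), strand = strand[1]), by = gene_id]
  gene_models(genes, transcripts)
}

#' Read / write a genome FASTA
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs named `DNAStringSet` or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a sample sheet (TSV: sample_id, cell_type, replicate[, stage_order])
#' @param path TSV path with header.
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1))
  need <- c("sample_id", "cell_type", "replicate")
  if (!all(need %in% names(dt)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample ids in sheet")
  dt[]
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.table.
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(sheet, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a feature-by-sample expression matrix as TSV
#'
#' Serialized with a header row of sample ids and a first column of feature
#' ids.  The `units` attribute records `counts`, `tpm` or `log2tpm`.
#' @param path TSV path.
#' @param units units flag stored on the returned matrix.
#' @export
read_matrix_tsv <- function(path, units = "tpm") {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (anyNA(m)) stop("expression matrix contains missing values: ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in matrix")
  attr(m, "units") <- units
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix with rownames (features) and colnames (samples).
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table(feature_id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
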