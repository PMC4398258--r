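# Cis-regulatory motif scanning and enrichment statistics: an own
# log-odds PWM scanner plus hypergeometric tests with Benjamini-Hochberg
# FDR control.  Replaces external motif tooling with a transparent,
# fully-parameterised equivalent.

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a count matrix
#'
#' Counts are converted to column-stochastic probabilities with a
#' pseudocount added to every cell: `p = (count + pseudocount) /
#' (colsum + 4 * pseudocount)`.
#'
#' @param counts 4 x L non-negative matrix, rows in A, C, G, T order.
#' @param id motif identifier.
#' @param pseudocount added to every cell (default 1).
#' @param background length-4 background base probabilities (default
#'   uniform).
#' @return a `pwm` object: list with `id`, `probs` (4 x L), `background`,
#'   `pseudocount`.
#' @export
pwm_from_counts <- function(counts, id = "pwm", pseudocount = 1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 4 * pseudocount, "/")
  rownames(probs) <- .BASES
  structure(list(id = id, probs = probs, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", ncol(x$probs), "consensus",
      paste(.BASES[apply(x$probs, 2, which.max)], collapse = ""), "\n")
  invisible(x)
}

#' Read a JASPAR-style plain-text PWM file
#'
#' Accepts records of the form
#' ```
#' >MA0001.1 NAME
#' A [ 1 2 3 ]
#' C [ ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' as well as bare 4-row numeric blocks under each `>` header.  Rows must
#' have equal lengths.
#'
#' @param path motif file path.
#' @param pseudocount passed to [pwm_from_counts()].
#' @return named list of `pwm` objects.
#' @export
read_pwm <- function(path, pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no '>' motif headers in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4)
      stop("motif ", id, ": expected 4 matrix rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("motif ", id, ": non-numeric matrix entry")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif ", id, ": ragged matrix rows")
    counts <- do.call(rbind, rows)
    out[[id]] <- pwm_from_counts(counts, id = id, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR-style text
#' @param pwms named list of `pwm` objects or 4 x L count matrices.
#' @param path output path.
#' @export
write_pwm <- function(pwms, path) {
  lines <- unlist(lapply(names(pwms), function(id) {
    m <- pwms[[id]]
    counts <- if (inherits(m, "pwm")) round(m$probs * 100) else m
    c(paste0(">", id),
      sprintf("%s [ %s ]", .BASES,
              apply(counts, 1, function(r) paste(r, collapse = " "))))
  }))
  writeLines(lines, path)
  invisible(path)
}

.encode_seq <- function(sequence) {
  match(strsplit(chartr("acgtn", "ACGTN", sequence), "")[[1]],
        c(.BASES, "N"))
}

.revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", sequence), "")[[1]]),
        collapse = "")
}

.scan_one_strand <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes)
  if (n < L) return(numeric(0))
  n_off <- n - L + 1L
  # lo5: row 5 = N, contributes 0
  lo5 <- rbind(lo, 0)
  score <- numeric(n_off)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n_off - 1L)]
    cj[is.na(cj)] <- 5L
    score <- score + lo5[cbind(cj, j)]
  }
  score
}

#' Scan a sequence with a PWM (both strands, log2-odds scoring)
#'
#' Scores every offset on both strands with
#' `sum_j log2(p_j(base) / background(base))`; the reverse strand scores
#' the reverse complement.  `N` bases contribute 0 (neutral).  A hit is an
#' offset whose score is at least `score_fraction` times the maximum
#' attainable score of the PWM.
#'
#' @param sequence character scalar over A, C, G, T, N.
#' @param pwm a `pwm` object.
#' @param score_fraction fraction of the maximal score required, in
#'   (0, 1]; default 0.8.
#' @return data.table `pos` (1-based leftmost position of the match on the
#'   input sequence), `strand`, `score`, sorted by position.
#' @export
scan_pwm <- function(sequence, pwm, score_fraction = 0.8) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  lo <- log2(sweep(pwm$probs, 1, pwm$background, "/"))
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_fraction * max_score
  n <- nchar(sequence)
  empty <- data.table(pos = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  fwd <- .scan_one_strand(.encode_seq(sequence), lo)
  rc <- .scan_one_strand(.encode_seq(.revcomp(sequence)), lo)
  hits <- rbind(
    if (any(fwd >= thr)) {
      data.table(pos = which(fwd >= thr), strand = "+",
                 score = fwd[fwd >= thr])
    } else empty,
    if (any(rc >= thr)) {
      # offset o on the reverse complement covers input positions
      # [n - o - L + 2, n - o + 1]
      data.table(pos = n - which(rc >= thr) - L + 2L, strand = "-",
                 score = rc[rc >= thr])
    } else empty)
  setorder(hits, pos, strand)
  hits[]
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' `X ~ Hypergeometric(N, K, n)`: `k` successes drawn in `n` draws from a
#' universe of `N` with `K` successes.  Vectorised over `k`.
#' @param k observed overlap (vector ok).
#' @param N universe size; `K` annotated; `n` drawn.
#' @export
hyper_upper_p <- function(k, N, K, n) {
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Hypergeometric enrichment of term sets in a foreground
#'
#' For each term set: `k` foreground hits out of `n` foreground ids, `K`
#' background hits out of `N` background ids; upper-tail p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; Benjamini-Hochberg `q`
#' across all terms tested in the call.
#'
#' @param foreground id set (must be a subset of `background`); must be
#'   non-empty.
#' @param background universe id set.
#' @param term_sets named list of id sets; each is intersected with the
#'   background before testing.
#' @return data.table `term, k, n, K, N, p, q`, sorted by p.
#' @export
hypergeom_enrich <- function(foreground, background, term_sets) {
  foreground <- unique(foreground); background <- unique(background)
  if (!length(foreground)) stop("empty foreground")
  if (length(setdiff(foreground, background)))
    stop("foreground must be a subset of background")
  N <- length(background)
  n <- length(foreground)
  res <- rbindlist(lapply(names(term_sets), function(term) {
    ts <- intersect(unique(term_sets[[term]]), background)
    K <- length(ts)
    k <- length(intersect(ts, foreground))
    data.table(term = term, k = k, n = n, K = K, N = N,
               p = hyper_upper_p(k, N, K, n))
  }))
  res[, q := p.adjust(p, method = "BH")]
  setorder(res, p, term)
  res[]
}

.summit_windows <- function(atlas, window, chrom_lengths = NULL) {
  cl <- atlas$clusters
  start <- pmax(0L, cl$summit - window)
  end <- cl$summit + window + 1L
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[cl$chrom])
  data.table(cluster_id = cl$cluster_id, chrom = cl$chrom,
             start = start, end = end)
}

#' Motif hit table over atlas summit windows
#'
#' Scans the `summit +/- window` sequence of every atlas cluster with each
#' PWM and records whether the window holds at least one hit.  The result
#' can be reused across many enrichment calls.
#'
#' @param atlas a `tss_atlas`.
#' @param genome named `DNAStringSet` (or character vector) of chromosome
#'   sequences.
#' @param pwms named list of `pwm` objects.
#' @param window half-window around the summit in bp (default 300).
#' @param score_fraction passed to [scan_pwm()].
#' @return logical matrix clusters x motifs.
#' @export
motif_hit_table <- function(atlas, genome, pwms, window = 300L,
                            score_fraction = 0.8) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  w <- .summit_windows(atlas, window, lens)
  hits <- matrix(FALSE, nrow(w), length(pwms),
                 dimnames = list(w$cluster_id, names(pwms)))
  for (i in seq_len(nrow(w))) {
    s <- as.character(Biostrings::subseq(genome[[w$chrom[i]]],
                                         start = w$start[i] + 1L,
                                         end = w$end[i]))
    for (m in names(pwms)) {
      hits[i, m] <- nrow(scan_pwm(s, pwms[[m]],
                                  score_fraction = score_fraction)) > 0
    }
  }
  hits
}

#' Motif enrichment of a TSS cluster set against the atlas background
#'
#' Foreground = the given TSS set; background = all atlas clusters; for
#' each motif the "annotated" set is the clusters with at least one PWM
#' hit in their summit window.  Delegates to [hypergeom_enrich()].
#'
#' @param tss_set character vector of atlas cluster ids (the coexpression
#'   cluster under test).
#' @param atlas filtered `tss_atlas` (the background universe).
#' @param genome,pwms,window,score_fraction see [motif_hit_table()].
#' @param hits optional precomputed [motif_hit_table()] result.
#' @export
motif_enrich <- function(tss_set, atlas, genome = NULL, pwms = NULL,
                         window = 300L, score_fraction = 0.8, hits = NULL) {
  if (is.null(hits))
    hits <- motif_hit_table(atlas, genome, pwms, window, score_fraction)
  term_sets <- lapply(colnames(hits), function(m) rownames(hits)[hits[, m]])
  names(term_sets) <- colnames(hits)
  hypergeom_enrich(tss_set, atlas$clusters$cluster_id, term_sets)
}

#' Interval-overlap enrichment of a TSS cluster set
#'
#' Membership in a factor's set = the cluster's summit window
#' (`summit +/- window`) overlaps at least 1 bp of that factor's peaks.
#' Statistics as in [hypergeom_enrich()].
#'
#' @param tss_set atlas cluster ids under test.
#' @param atlas filtered `tss_atlas` (background universe).
#' @param peak_sets named list of interval data.tables (`chrom, start,
#'   end`).
#' @param window half-window around the summit in bp (default 300).
#' @export
overlap_enrich <- function(tss_set, atlas, peak_sets, window = 300L) {
  w <- .summit_windows(atlas, window)
  qr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
  term_sets <- lapply(peak_sets, function(pk) {
    sr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L,
                                                            pk$end))
    ov <- GenomicRanges::findOverlaps(qr, sr, ignore.strand = TRUE)
    w$cluster_id[unique(S4Vectors::queryHits(ov))]
  })
  hypergeom_enrich(tss_set, atlas$clusters$cluster_id, term_sets)
}
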