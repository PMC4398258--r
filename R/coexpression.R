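# Correlation graphs, Markov clustering and the stage-ordered trajectory
# variant.

#' log2(TPM + 1) transform
#' @param mat non-negative matrix (TPM).
#' @export
log_transform <- function(mat) {
  if (any(mat < 0)) stop("log_transform needs non-negative input")
  out <- log2(mat + 1)
  attr(out, "units") <- "log2tpm"
  out
}

#' Row-wise Pearson correlation graph
#'
#' Builds an undirected weighted graph over the matrix rows with an edge
#' (i, j) iff Pearson r(i, j) >= cutoff.  Rows with zero variance get no
#' edges and are reported in `zero_variance`.  To build a sample-to-sample
#' graph, pass the transposed matrix.
#'
#' @param mat feature-by-sample matrix (log2 TPM recommended); needs at
#'   least 3 columns.
#' @param cutoff correlation cutoff in (-1, 1]; edges keep their r as
#'   weight.
#' @return A `correlation_graph`: list with `nodes`, `edges` (data.table
#'   `from, to, weight`), `cutoff`, `zero_variance`.
#' @export
pearson_graph <- function(mat, cutoff) {
  if (ncol(mat) < 3)
    stop("need >= 3 observations (columns) for correlation")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  sds <- apply(mat, 1, sd)
  zv <- rownames(mat)[sds == 0]
  ok <- sds > 0
  edges <- data.table(from = character(), to = character(),
                      weight = numeric())
  if (sum(ok) >= 2) {
    r <- suppressWarnings(cor(t(mat[ok, , drop = FALSE])))
    r[lower.tri(r, diag = TRUE)] <- NA
    hit <- which(r >= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- data.table(from = rownames(r)[hit[, 1]],
                          to = colnames(r)[hit[, 2]],
                          weight = r[hit])
      setorder(edges, from, to)
    }
  }
  structure(list(nodes = rownames(mat), edges = edges, cutoff = cutoff,
                 zero_variance = zv), class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("correlation_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges at r >=", x$cutoff, "\n")
  invisible(x)
}

#' Markov cluster algorithm (MCL) on a weighted graph
#'
#' Classic MCL: add unit self-loops to the weighted adjacency, normalise
#' columns to stochastic, then iterate expansion (matrix power) and
#' inflation (entry-wise power followed by column renormalisation), pruning
#' entries below `prune_threshold`, until the matrix changes by less than
#' `tol`.  Clusters are read from the limit matrix as weakly connected
#' components of its non-zero structure.  Nodes isolated in the input
#' graph are reported as `unassigned` rather than singleton clusters.
#'
#' @param graph a `correlation_graph` (or list with `nodes` and `edges`).
#' @param inflation inflation exponent (granularity; default 2.2).
#' @param expansion expansion power (default 2).
#' @param max_iter iteration cap; non-convergence returns the current
#'   interpretation with a warning.
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the max absolute change.
#' @return A `cluster_partition`: list with `clusters` (named list of node
#'   id vectors, largest first), `unassigned`, `converged`, `iterations`.
#' @export
mcl <- function(graph, inflation = 2.2, expansion = 2, max_iter = 200,
                prune_threshold = 1e-5, tol = 1e-8) {
  nodes <- graph$nodes
  if (!length(nodes)) stop("mcl needs a non-empty graph")
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    e <- graph$edges
    A[cbind(idx[e$from], idx[e$to])] <- e$weight
    A[cbind(idx[e$to], idx[e$from])] <- e$weight
  }
  isolated <- nodes[rowSums(A) == 0]
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M
    for (k in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2 ^ inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {            # pruning killed a column; restore its argmax
      mx <- apply(M[, dead, drop = FALSE], 2, which.max)
      M2[cbind(mx, which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  g <- igraph::graph_from_adjacency_matrix(M > 0, mode = "max", diag = FALSE)
  comp <- igraph::components(g)$membership
  members <- split(nodes, comp)
  members <- lapply(members, function(m) setdiff(m, isolated))
  members <- members[lengths(members) > 0]
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1], ""))
  members <- members[ord]
  names(members) <- if (length(members)) paste0("C", seq_along(members))
  structure(list(clusters = members, unassigned = isolated,
                 converged = converged, iterations = it),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", length(x$clusters), "clusters (",
      sum(lengths(x$clusters)), "nodes ),", length(x$unassigned),
      "unassigned\n")
  invisible(x)
}

#' Partition membership as a named vector (node -> cluster id)
#' @param partition a `cluster_partition`.
#' @param include_unassigned if TRUE, unassigned nodes get singleton labels.
#' @export
partition_membership <- function(partition, include_unassigned = FALSE) {
  m <- unlist(lapply(names(partition$clusters), function(cid) {
    setNames(rep(cid, length(partition$clusters[[cid]])),
             partition$clusters[[cid]])
  }))
  if (include_unassigned && length(partition$unassigned)) {
    m <- c(m, setNames(paste0("U", seq_along(partition$unassigned)),
                       partition$unassigned))
  }
  if (is.null(m)) m <- setNames(character(), character())
  m
}

#' Keep clusters with enough TSS members and distinct genes
#'
#' @param partition a `cluster_partition` over atlas cluster ids.
#' @param atlas annotated `tss_atlas` supplying gene assignments.
#' @param min_members minimum TSS member count (inclusive, default 20).
#' @param min_genes minimum distinct gene count among members (promoter or
#'   intragenic classes; intergenic members count toward `min_members`
#'   only).  Inclusive, default 5.
#' @export
filter_clusters <- function(partition, atlas, min_members = 20L,
                            min_genes = 5L) {
  cl <- atlas$clusters
  gmap <- setNames(cl$gene_id, cl$cluster_id)
  genic <- setNames(cl$annotation_class %in% c("promoter", "intragenic"),
                    cl$cluster_id)
  keep <- vapply(partition$clusters, function(members) {
    g <- gmap[members[genic[members] %in% TRUE]]
    length(members) >= min_members &&
      length(unique(g[!is.na(g)])) >= min_genes
  }, TRUE)
  partition$clusters <- partition$clusters[keep]
  if (length(partition$clusters))
    names(partition$clusters) <- paste0("C", seq_along(partition$clusters))
  partition
}

#' Mean expression profile of each cluster
#' @param partition a `cluster_partition` whose members are rownames of
#'   `mat`.
#' @param mat feature-by-sample matrix.
#' @return matrix clusters x samples of arithmetic means.
#' @export
cluster_profile <- function(partition, mat) {
  miss <- setdiff(unlist(partition$clusters), rownames(mat))
  if (length(miss)) stop("members missing from matrix: ", miss[1])
  t(vapply(partition$clusters, function(m) {
    colMeans(mat[m, , drop = FALSE])
  }, numeric(ncol(mat))))
}

#' Stage-ordered trajectory clustering
#'
#' Computes per-gene stage means over samples ordered by `stage_order`,
#' keeps "dynamic" genes whose stage-mean range is at least `min_log2_fc`
#' (log2 TPM scale), then clusters the dynamic genes' stage-mean profiles
#' with [pearson_graph()] (cutoff 0.9) and [mcl()] (inflation 2.2).
#'
#' @param mat gene-by-sample matrix in log2 TPM.
#' @param sheet sample sheet with `sample_id` and integer `stage_order`;
#'   at least 3 ordered stages are required.
#' @param min_log2_fc dynamic-gene threshold (default 1).
#' @param cutoff,inflation clustering parameters.
#' @return list with `partition` (over dynamic genes), `dynamic_genes`,
#'   `stage_means` (gene x stage matrix).
#' @export
trajectory_clusters <- function(mat, sheet, min_log2_fc = 1, cutoff = 0.9,
                                inflation = 2.2) {
  sheet <- as.data.table(sheet)
  if (!"stage_order" %in% names(sheet))
    stop("sample sheet needs a stage_order column")
  sheet <- sheet[sample_id %in% colnames(mat)]
  stages <- sort(unique(sheet$stage_order))
  if (length(stages) < 3) stop("need >= 3 ordered stages")
  sm <- vapply(stages, function(st) {
    rowMeans(mat[, sheet[stage_order == st, sample_id], drop = FALSE])
  }, numeric(nrow(mat)))
  colnames(sm) <- paste0("stage", stages)
  dyn <- rownames(mat)[apply(sm, 1, max) - apply(sm, 1, min) >= min_log2_fc]
  if (!length(dyn))
    return(list(partition = structure(list(clusters = list(),
                                           unassigned = character(),
                                           converged = TRUE, iterations = 0L),
                                      class = "cluster_partition"),
                dynamic_genes = character(), stage_means = sm))
  g <- pearson_graph(sm[dyn, , drop = FALSE], cutoff)
  list(partition = mcl(g, inflation = inflation),
       dynamic_genes = dyn, stage_means = sm)
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value for independent
#' random labelings.
#' @param a,b label vectors; if named, aligned on the intersection of
#'   names, else positionally.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
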