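library(data.table)

# Shared fixtures, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

# The default stated world: 5 cell types x 3 replicates, 200 genes,
# 8 modules, 30 enhancers, seed 42.  `with_sequence` additionally draws
# the genome and plants motifs.
default_world <- function(with_sequence = FALSE) {
  key <- if (with_sequence) "seq" else "noseq"
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- sim_config()
  ann <- generate_annotation(cfg, sequence = with_sequence)
  sim <- generate_ctss(cfg, ann)
  atlas <- normalize_tpm(cluster_tags(sim$tracks, max_gap = 20),
                         sim$library_sizes)
  annotated <- annotate_tss(atlas, ann$models)
  filtered <- annotate_tss(filter_expressed(atlas, 5), ann$models)
  matches <- match_planted_tss(filtered, sim$truth$tss)
  w <- list(cfg = cfg, ann = ann, sim = sim, atlas = atlas,
            annotated = annotated, filtered = filtered, matches = matches)
  .world_cache[[key]] <- w
  w
}

tiny_config <- function(seed = 7, ...) {
  sim_config(n_chromosomes = 2, chrom_length = 2e5, n_genes = 16,
             n_cell_types = 3, replicates_per_type = 2, n_modules = 3,
             n_enhancers = 4, seed = seed, ...)
}

# minimal hand-built atlas for unit tests that do not need the simulator
make_atlas <- function(clusters, counts, library_sizes = NULL) {
  clusters <- as.data.table(clusters)
  if (!"annotation_class" %in% names(clusters))
    clusters[, annotation_class := NA_character_]
  if (!"gene_id" %in% names(clusters)) clusters[, gene_id := NA_character_]
  if (!"distance_to_5p" %in% names(clusters))
    clusters[, distance_to_5p := NA_integer_]
  rownames(counts) <- clusters$cluster_id
  a <- structure(list(clusters = clusters, counts = counts, tpm = NULL,
                      library_sizes = NULL, samples = colnames(counts)),
                 class = "tss_atlas")
  if (!is.null(library_sizes)) a <- normalize_tpm(a, library_sizes)
  a
}

# one-sample CTSS track from bare positions
track_from_positions <- function(pos, strand = "+", count = 1,
                                 chrom = "chr1") {
  dt <- data.table(chrom = chrom, start = as.integer(pos),
                   end = as.integer(pos) + 1L, name = ".",
                   count = as.integer(rep_len(count, length(pos))),
                   strand = rep_len(strand, length(pos)))
  setorder(dt, chrom, start, strand)
  dt
}

# recovered-vs-truth ARI over planted module TSSs: truth labels against
# the filtered MCL partition, unclustered planted TSSs as singletons
module_recovery_ari <- function(world, partition) {
  map <- setNames(world$matches$cluster_id, world$matches$tss_id)
  tm <- world$sim$truth$module_membership
  truth_labels <- tm[!is.na(map[names(tm)])]
  ids <- map[names(truth_labels)]
  rec <- partition_membership(partition)[ids]
  rec[is.na(rec)] <- paste0("singleton", seq_len(sum(is.na(rec))))
  adjusted_rand_index(unname(truth_labels), unname(rec))
}

# enhancer call vs truth confusion counts (match = center within tol)
enhancer_confusion <- function(calls, truth_loci, tol = 100) {
  if (!nrow(truth_loci))
    return(list(tp = 0, fp = nrow(calls$calls), fn = 0))
  hit_truth <- vapply(seq_len(nrow(truth_loci)), function(i) {
    any(calls$calls$chrom == truth_loci$chrom[i] &
          abs(calls$calls$center - truth_loci$center[i]) <= tol)
  }, TRUE)
  hit_call <- vapply(seq_len(nrow(calls$calls)), function(i) {
    any(truth_loci$chrom == calls$calls$chrom[i] &
          abs(truth_loci$center - calls$calls$center[i]) <= tol)
  }, TRUE)
  list(tp = sum(hit_call), fp = sum(!hit_call), fn = sum(!hit_truth))
}
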