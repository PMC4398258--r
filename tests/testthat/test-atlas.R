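test_that("tag clustering respects max_gap and strand", {
  tr <- list(s1 = track_from_positions(c(100, 105, 140), count = c(3, 5, 2)))
  atlas <- cluster_tags(tr, max_gap = 20)
  cl <- atlas$clusters
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(100, 140))
  expect_equal(cl$end, c(106, 141))
  expect_equal(cl$summit[1], 105)  # highest pooled count wins

  tr2 <- list(s1 = rbind(track_from_positions(100, "+"),
                         track_from_positions(100, "-")))
  expect_equal(nrow(cluster_tags(tr2, 20)$clusters), 2)
})

test_that("max_gap = 0 yields one cluster per distinct position (brute force)", {
  set.seed(42)
  n <- 10000
  dt <- data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   pos = sample.int(5e4, n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE))
  dt <- unique(dt)
  tr <- list(s1 = data.table(chrom = dt$chrom, start = dt$pos,
                             end = dt$pos + 1L, name = ".", count = 1L,
                             strand = dt$strand))
  setorder(tr$s1, chrom, start, strand)
  atlas <- cluster_tags(tr, max_gap = 0)
  expect_equal(nrow(atlas$clusters), nrow(dt))
})

test_that("clustering partitions all tags (counts conserved)", {
  w <- default_world()
  total_in <- sum(vapply(w$sim$tracks, function(t) sum(t$count), 0))
  expect_equal(sum(w$atlas$counts), total_in)
  expect_equal(unname(colSums(w$atlas$counts)),
               unname(vapply(w$sim$tracks, function(t) sum(t$count), 0)))
})

test_that("re-clustering summits never merges clusters", {
  w <- default_world()
  cl <- w$atlas$clusters
  tr <- list(s1 = data.table(chrom = cl$chrom, start = cl$summit,
                             end = cl$summit + 1L, name = ".", count = 1L,
                             strand = cl$strand))
  setorder(tr$s1, chrom, start, strand)
  tr$s1 <- unique(tr$s1, by = c("chrom", "start", "strand"))
  re <- cluster_tags(tr, max_gap = 20)
  # neighbouring clusters are > max_gap apart, so summits never merge:
  # one cluster per distinct summit, i.e. at least as many as before
  expect_equal(nrow(re$clusters), nrow(tr$s1))
  expect_gte(nrow(re$clusters), nrow(unique(cl[, .(chrom, summit, strand)])))
})

test_that("TPM normalisation and conservation", {
  tr <- list(s1 = track_from_positions(c(100, 500), count = c(10, 1999990)))
  atlas <- normalize_tpm(cluster_tags(tr, 20))
  expect_equal(atlas$tpm["TC000001", "s1"], 5)         # 10 / 2e6 * 1e6
  expect_equal(sum(atlas$tpm[, "s1"]), 1e6)            # conservation
  one <- normalize_tpm(cluster_tags(list(s1 = track_from_positions(7, count = 12)), 0))
  expect_equal(unname(one$tpm[1, 1]), 1e6)             # all tags in one cluster
  expect_error(normalize_tpm(cluster_tags(tr, 20), c(s1 = 0)), "library size")
})

test_that("expression filter is inclusive at the threshold", {
  tr <- list(s1 = track_from_positions(c(100, 10000), count = c(499, 500)),
             s2 = track_from_positions(c(100, 10000), count = c(50000, 49001)))
  atlas2 <- normalize_tpm(cluster_tags(tr, 20), c(s1 = 1e8, s2 = 1e11))
  expect_equal(unname(atlas2$tpm[, "s1"]), c(4.99, 5.00))
  expect_true(all(atlas2$tpm[, "s2"] < 1))
  kept <- filter_expressed(atlas2, 5)
  expect_equal(kept$clusters$start, 10000)             # 4.99 dropped, 5.0 kept
  expect_equal(nrow(filter_expressed(atlas2, 0)$clusters), 2)  # identity
})

test_that("annotation classes follow the promoter > intragenic > intergenic rules", {
  models <- gene_models(
    genes = data.table(gene_id = c("A", "B"), chrom = "chr1",
                       start = c(1000, 5000), end = c(3000, 7000),
                       strand = "+"),
    transcripts = data.table(transcript_id = c("A.1", "B.1"),
                             gene_id = c("A", "B"), chrom = "chr1",
                             start = c(1000, 5000), end = c(3000, 7000),
                             strand = "+"))
  tr <- list(s1 = track_from_positions(c(600, 1600, 3500), count = 10))
  atlas <- annotate_tss(normalize_tpm(cluster_tags(tr, 0)), models)
  cl <- atlas$clusters
  expect_equal(cl$annotation_class, c("promoter", "intragenic", "intergenic"))
  expect_equal(cl$gene_id, c("A", "A", NA))
  expect_equal(cl$distance_to_5p[1], -400L)            # 400 bp upstream

  # 600 bp downstream of the 5' end but inside the body -> intragenic
  tr2 <- list(s1 = track_from_positions(1600, count = 10))
  a2 <- annotate_tss(normalize_tpm(cluster_tags(tr2, 0)), models)
  expect_equal(a2$clusters$annotation_class, "intragenic")

  # equidistant tie -> lexicographically smaller gene id
  models_tie <- gene_models(
    genes = data.table(gene_id = c("B", "A"), chrom = "chr1",
                       start = c(1000, 1600), end = c(1300, 1900),
                       strand = "+"),
    transcripts = data.table(transcript_id = c("B.1", "A.1"),
                             gene_id = c("B", "A"), chrom = "chr1",
                             start = c(1000, 1600), end = c(1300, 1900),
                             strand = "+"))
  tr3 <- list(s1 = track_from_positions(1300, count = 10))
  a3 <- annotate_tss(normalize_tpm(cluster_tags(tr3, 0)), models_tie)
  expect_equal(a3$clusters$gene_id, "A")

  # antisense near a 5' end is NOT a promoter
  tr4 <- list(s1 = track_from_positions(990, "-", count = 10))
  a4 <- annotate_tss(normalize_tpm(cluster_tags(tr4, 0)), models)
  expect_equal(a4$clusters$annotation_class, "intergenic")
})

test_that("every cluster gets exactly one annotation class", {
  w <- default_world()
  expect_true(all(w$filtered$clusters$annotation_class %in%
                    c("promoter", "intragenic", "intergenic")))
  expect_false(anyNA(w$filtered$clusters$annotation_class))
})

test_that("per-sample expressed summaries", {
  models <- gene_models(
    genes = data.table(gene_id = c("A", "B"), chrom = "chr1",
                       start = c(1000, 5000), end = c(3000, 7000),
                       strand = "+"),
    transcripts = data.table(
      transcript_id = c("A.1", "A.2", "B.1"), gene_id = c("A", "A", "B"),
      chrom = "chr1", start = c(1000, 1700, 5000), end = c(3000, 3000, 7000),
      strand = "+"))
  tr <- list(s1 = track_from_positions(c(1000, 1700, 5000), count = 100))
  atlas <- annotate_tss(normalize_tpm(cluster_tags(tr, 0)), models)
  ps <- per_sample_expressed(atlas, min_tpm = 5)
  expect_equal(ps$n_tss, 3L)
  expect_equal(ps$n_genes, 2L)
  expect_equal(ps$ratio, 1.5)

  tr2 <- list(s1 = track_from_positions(c(1000, 5000), count = 100))
  a2 <- annotate_tss(normalize_tpm(cluster_tags(tr2, 0)), models)
  expect_equal(per_sample_expressed(a2)$ratio, 1)
})

test_that("per-sample TSS:gene ratio sits below the atlas-wide ratio", {
  w <- default_world()
  ps <- per_sample_expressed(w$filtered)
  us <- tss_per_gene(w$filtered)
  atlas_ratio <- nrow(w$filtered$clusters) / length(us$n_tss)
  expect_true(all(ps$ratio < atlas_ratio))
})

test_that("noncoding overlap keeps only intergenic clusters", {
  models <- gene_models(
    genes = data.table(gene_id = "A", chrom = "chr1", start = 1000,
                       end = 3000, strand = "+"),
    transcripts = data.table(transcript_id = "A.1", gene_id = "A",
                             chrom = "chr1", start = 1000, end = 3000,
                             strand = "+"))
  tr <- list(s1 = track_from_positions(c(1000, 9000), count = 10))
  atlas <- annotate_tss(normalize_tpm(cluster_tags(tr, 0)), models)
  linc <- data.table(chrom = "chr1", start = c(800, 8000),
                     end = c(1200, 9500))
  hit <- overlap_noncoding(atlas, linc)
  expect_equal(hit$clusters$start, 9000)   # promoter-class excluded
  none <- overlap_noncoding(atlas, linc[0])
  expect_equal(nrow(none$clusters), 0)
})

test_that("95% of planted TSSs map 1:1 to clusters within 20 bp", {
  w <- default_world()
  m <- w$matches
  expect_gte(mean(!is.na(m$cluster_id)), 0.95)
  matched <- m$cluster_id[!is.na(m$cluster_id)]
  expect_equal(anyDuplicated(matched), 0)
  expect_true(all(m$dist[!is.na(m$dist)] <= 20))
})
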