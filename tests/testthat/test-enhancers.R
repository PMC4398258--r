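far_models <- gene_models(
  genes = data.table(gene_id = "G", chrom = "chr1", start = 50000L,
                     end = 52000L, strand = "+"),
  transcripts = data.table(transcript_id = "G.1", gene_id = "G",
                           chrom = "chr1", start = 50000L, end = 52000L,
                           strand = "+"))

divergent_atlas <- function(F, R, rev_pos = 1000L, fwd_pos = 1180L) {
  tr <- list(s1 = rbind(track_from_positions(rev_pos, "-", R),
                        track_from_positions(fwd_pos, "+", F)))
  setorder(tr$s1, chrom, start, strand)
  annotate_tss(normalize_tpm(cluster_tags(tr, 20), c(s1 = 1e6)), far_models)
}

test_that("directionality gating at the inclusive 0.8 boundary", {
  balanced <- call_enhancers(divergent_atlas(10, 10), far_models)
  expect_equal(nrow(balanced$calls), 1)
  expect_equal(balanced$calls$D, 0)

  skewed <- call_enhancers(divergent_atlas(99, 1), far_models)
  expect_equal(nrow(skewed$calls), 0)              # |D| = 0.98 > 0.8

  boundary <- call_enhancers(divergent_atlas(90, 10), far_models)
  expect_equal(nrow(boundary$calls), 1)            # D = 0.8 inclusive
  expect_equal(boundary$calls$D, 0.8)
})

test_that("pairs inside gene bodies or promoter windows are rejected", {
  genic <- divergent_atlas(10, 10, rev_pos = 50500L, fwd_pos = 50680L)
  expect_equal(nrow(call_enhancers(genic, far_models)$calls), 0)
  near5p <- divergent_atlas(10, 10, rev_pos = 49600L, fwd_pos = 49780L)
  expect_equal(nrow(call_enhancers(near5p, far_models)$calls), 0)
})

test_that("summit separation beyond the pairing window is not called", {
  wide <- divergent_atlas(10, 10, rev_pos = 1000L, fwd_pos = 1450L)
  expect_equal(nrow(call_enhancers(wide, far_models)$calls), 0)
  expect_equal(nrow(call_enhancers(wide, far_models,
                                   pair_window = 500)$calls), 1)
})

test_that("D is antisymmetric under swapping the pair's counts", {
  d1 <- call_enhancers(divergent_atlas(30, 10), far_models)$calls$D
  d2 <- call_enhancers(divergent_atlas(10, 30), far_models)$calls$D
  expect_equal(d1, -d2)
})

test_that("calls are invariant to sample order", {
  w <- default_world()
  atlas1 <- w$annotated
  perm <- rev(w$sim$sheet$sample_id)
  tracks2 <- w$sim$tracks[perm]
  atlas2 <- annotate_tss(normalize_tpm(cluster_tags(tracks2, 20),
                                       w$sim$library_sizes[perm]),
                         w$ann$models)
  c1 <- call_enhancers(atlas1, w$ann$models)
  c2 <- call_enhancers(atlas2, w$ann$models)
  expect_equal(as.data.frame(c1$calls), as.data.frame(c2$calls))
})

test_that("no emitted call touches a promoter window or gene body", {
  w <- default_world()
  calls <- call_enhancers(w$annotated, w$ann$models)$calls
  g <- w$ann$genes; tx <- w$ann$models$transcripts
  for (i in seq_len(nrow(calls))) {
    gg <- g[chrom == calls$chrom[i]]
    expect_false(any(gg$start < calls$end[i] & calls$start[i] < gg$end))
    t5 <- tx[chrom == calls$chrom[i], tss]
    d <- pmax(0, pmax(calls$start[i] - t5, t5 - (calls$end[i] - 1L)))
    expect_true(all(d > 500))
  }
})

test_that("planted enhancers are recovered with high precision and recall", {
  w <- default_world()
  calls <- call_enhancers(w$annotated, w$ann$models)
  cm <- enhancer_confusion(calls, w$sim$truth$enhancer_loci)
  expect_gte(cm$tp / (cm$tp + cm$fp), 0.9)
  expect_gte(cm$tp / (cm$tp + cm$fn), 0.9)
})

test_that("restriction calls require one on-type and all-off others", {
  sheet <- data.table(sample_id = paste0("s", 1:6),
                      cell_type = rep(c("mast", "mono", "neut"), each = 2),
                      replicate = rep(1:2, 3))
  v <- setNames(c(20, 20, 0, 0, 0, 0), sheet$sample_id)
  expect_equal(unname(restriction_call(v, sheet)), "mast")
  v2 <- setNames(c(20, 20, 30, 30, 0, 0), sheet$sample_id)
  expect_true(is.na(restriction_call(v2, sheet)))
  v3 <- setNames(c(20, 20, 2, 0, 0, 0), sheet$sample_id)  # off-type >= 1
  expect_true(is.na(restriction_call(v3, sheet)))
})

test_that("planted cell-type-specific enhancers are recovered as restricted", {
  w <- default_world()
  calls <- call_enhancers(w$annotated, w$ann$models)
  rc <- restriction_call(calls$tpm, w$sim$sheet)
  el <- w$sim$truth$enhancer_loci
  got <- vapply(seq_len(nrow(el)), function(i) {
    j <- which(calls$calls$chrom == el$chrom[i] &
                 abs(calls$calls$center - el$center[i]) <= 100)
    length(j) == 1 && !is.na(rc[j]) && rc[j] == el$cell_type[i]
  }, TRUE)
  expect_gte(mean(got), 0.9)
})

test_that("gene linking respects distance and correlation gates", {
  w <- default_world()
  calls <- call_enhancers(w$annotated, w$ann$models)
  links <- link_genes(calls, w$annotated)
  el <- w$sim$truth$enhancer_loci
  # planted partner genes should be among each enhancer's linked genes,
  # essentially tied with the top correlation
  ok <- vapply(seq_len(nrow(el)), function(i) {
    if (is.na(el$partner_gene[i])) return(NA)
    j <- which(calls$calls$chrom == el$chrom[i] &
                 abs(calls$calls$center - el$center[i]) <= 100)
    if (length(j) != 1) return(FALSE)
    l <- links[[j]]
    el$partner_gene[i] %in% l$gene_id &&
      l[gene_id == el$partner_gene[i], r] >= max(l$r) - 0.05
  }, NA)
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
  # distance gate: a perfectly correlated promoter 600 kb away cannot link
  some <- links[[1]]
  if (nrow(some)) {
    prom <- w$annotated$clusters[cluster_id %in% some$cluster_id]
    expect_true(all(abs(prom$summit - calls$calls$center[1]) <= 5e5))
  }
})

test_that("identical profiles link with r = 1 and distance excludes far genes", {
  # enhancer pair and one promoter sharing the exact same profile
  counts <- c(5, 50, 5, 40, 5, 60)
  tr <- lapply(seq_along(counts), function(s) {
    rbind(track_from_positions(1000L, "-", counts[s]),
          track_from_positions(1180L, "+", counts[s]),
          track_from_positions(50000L, "+", counts[s]),
          track_from_positions(900000L, "+", counts[s]))
  })
  names(tr) <- paste0("s", seq_along(counts))
  models <- gene_models(
    genes = data.table(gene_id = c("NEAR", "FAR"), chrom = "chr1",
                       start = c(50000L, 900000L),
                       end = c(52000L, 902000L), strand = "+"),
    transcripts = data.table(transcript_id = c("NEAR.1", "FAR.1"),
                             gene_id = c("NEAR", "FAR"), chrom = "chr1",
                             start = c(50000L, 900000L),
                             end = c(52000L, 902000L), strand = "+"))
  atlas <- annotate_tss(normalize_tpm(cluster_tags(tr, 20),
                                      setNames(rep(1e6, 6), names(tr))),
                        models)
  calls <- call_enhancers(atlas, models)
  expect_equal(nrow(calls$calls), 1)
  links <- link_genes(calls, atlas)[[1]]
  expect_equal(links$gene_id, "NEAR")
  expect_gt(links$r, 0.999)
})

test_that("noise-only worlds stay below 0.5 false calls per megabase", {
  # scaled-down version of the acceptance sweep: 5 seeds here
  rates <- vapply(1:5, function(sd) {
    cfg <- sim_config(n_enhancers = 0, seed = sd)
    ann <- generate_annotation(cfg, sequence = FALSE)
    sim <- generate_ctss(cfg, ann)
    atlas <- annotate_tss(normalize_tpm(cluster_tags(sim$tracks, 20),
                                        sim$library_sizes), ann$models)
    mb <- cfg$n_chromosomes * cfg$chrom_length / 1e6
    nrow(call_enhancers(atlas, ann$models)$calls) / mb
  }, 0)
  expect_lte(mean(rates), 0.5)
})
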