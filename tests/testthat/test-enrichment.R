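test_that("pwm construction applies pseudocounts", {
  m <- pwm_from_counts(matrix(5, 4, 3))
  expect_true(all(abs(m$probs - 0.25) < 1e-12))
  sharp <- pwm_from_counts(matrix(c(97, 1, 1, 1), 4, 1))
  expect_equal(unname(sharp$probs["A", 1]), 98 / 104)
  expect_equal(sum(sharp$probs[, 1]), 1)
  expect_error(pwm_from_counts(matrix(1, 3, 2)), "4 rows")
})

test_that("scan_pwm scores match the hand-summed log-odds oracle", {
  probs <- matrix(0.1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs["A", ] <- 0.7
  pwm <- structure(list(id = "pA", probs = probs,
                        background = rep(0.25, 4), pseudocount = 0),
                   class = "pwm")
  hits <- scan_pwm("AAAT", pwm, score_fraction = 0.5)
  fwd <- hits[strand == "+"]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$score, 3 * log2(0.7 / 0.25) + log2(0.1 / 0.25),
               tolerance = 1e-9)

  # consensus scores the maximum at score_fraction = 1
  h2 <- scan_pwm("AAAA", pwm, score_fraction = 1)
  expect_equal(h2[strand == "+", score], 4 * log2(0.7 / 0.25),
               tolerance = 1e-9)

  # sequence shorter than the motif -> empty
  expect_equal(nrow(scan_pwm("AA", pwm)), 0)
})

test_that("reverse-complement symmetry is exact", {
  set.seed(13)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  for (i in 1:10) {
    L <- sample(4:9, 1)
    counts <- matrix(rpois(4 * L, 5) + 1, 4)
    pwm <- pwm_from_counts(counts, "x")
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    h1 <- scan_pwm(s, pwm, score_fraction = 0.01)
    h2 <- scan_pwm(rc(s), pwm, score_fraction = 0.01)
    expect_equal(sort(h1[strand == "+", score]),
                 sort(h2[strand == "-", score]), tolerance = 1e-9)
  }
  # planting the reverse complement of the consensus yields a - strand hit
  pwm <- pwm_from_counts(consensus_pwm_counts(
    data.table(id = "m", consensus = "TGACTCAG"))$m, "m")
  hit <- scan_pwm(rc("TGACTCAG"), pwm, score_fraction = 0.99)
  expect_equal(hit$strand, "-")
})

test_that("N bases contribute zero to the score", {
  probs <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs["A", ] <- 0.7; probs[c("C", "G", "T"), ] <- 0.1
  pwm <- structure(list(id = "p", probs = probs, background = rep(0.25, 4),
                        pseudocount = 0), class = "pwm")
  hN <- scan_pwm("AN", pwm, score_fraction = 0.1)
  expect_equal(hN[strand == "+", score], log2(0.7 / 0.25), tolerance = 1e-9)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  bg <- paste0("x", 1:20)
  fg <- bg[1:10]
  term <- list(t5 = bg[c(1:4, 11)])          # K = 5, k = 4
  res <- hypergeom_enrich(fg, bg, term)
  expect_equal(res$p, 28028 / 184756, tolerance = 1e-12)
  expect_equal(res[, .(k, n, K, N)], data.table(k = 4L, n = 10L, K = 5L,
                                                N = 20L))
  # K = N: certain event
  resN <- hypergeom_enrich(fg, bg, list(all = bg))
  expect_equal(resN$p, 1)
  expect_error(hypergeom_enrich(character(), bg, term), "empty")
  expect_error(hypergeom_enrich(c(fg, "zzz"), bg, term), "subset")
})

test_that("BH correction follows the step-up formula", {
  bg <- paste0("b", 1:100)
  # craft four terms with chosen p-values is fiddly; test p.adjust contract
  # through the invariant q >= p and the stated flat-q example directly
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(14)
  fg <- sample(bg, 30)
  terms <- lapply(1:6, function(i) sample(bg, sample(10:60, 1)))
  names(terms) <- paste0("t", 1:6)
  res <- hypergeom_enrich(fg, bg, terms)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$k <= pmin(res$n, res$K)))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(diff(res$q) >= -1e-15))   # monotone in p-rank
})

test_that("motif planted in every member window ranks first", {
  set.seed(15)
  seqlen <- 20000L
  genome <- paste(sample(c("A", "C", "G", "T"), seqlen, TRUE), collapse = "")
  motif <- "TTTCGCGC"
  members <- sprintf("TC%06d", 1:5)
  others <- sprintf("TC%06d", 6:20)
  summits <- seq(500, by = 900, length.out = 20)
  for (s in summits[1:5]) substr(genome, s - 50, s - 43) <- motif
  clusters <- data.table(cluster_id = c(members, others), chrom = "chrS",
                         start = summits - 5L, end = summits + 5L,
                         strand = "+", summit = as.integer(summits),
                         total_count = 10, annotation_class = "promoter",
                         gene_id = sprintf("G%d", 1:20),
                         distance_to_5p = 0L)
  atlas <- make_atlas(clusters, matrix(10, 20, 3,
                                       dimnames = list(NULL, paste0("s", 1:3))),
                      setNames(rep(1e6, 3), paste0("s", 1:3)))
  lib <- data.table(id = c("planted", "absent"),
                    consensus = c(motif, "AGATAAGG"))
  pwms <- lapply(consensus_pwm_counts(lib), pwm_from_counts)
  names(pwms) <- lib$id
  res <- motif_enrich(members, atlas, Biostrings::DNAStringSet(c(chrS = genome)),
                      pwms)
  expect_equal(res$term[1], "planted")
  expect_equal(res[term == "planted", k], 5L)
  expect_lt(res[term == "planted", q], 0.05)
})

test_that("overlap enrichment handles degenerate peak geometries", {
  clusters <- data.table(cluster_id = sprintf("TC%06d", 1:10), chrom = "chr1",
                         start = (1:10) * 5000L, end = (1:10) * 5000L + 10L,
                         strand = "+", summit = (1:10) * 5000L,
                         total_count = 1, annotation_class = "promoter",
                         gene_id = sprintf("G%d", 1:10), distance_to_5p = 0L)
  atlas <- make_atlas(clusters, matrix(1, 10, 3,
                                       dimnames = list(NULL, paste0("s", 1:3))))
  fg <- clusters$cluster_id[1:4]
  whole <- list(everywhere = data.table(chrom = "chr1", start = 0L,
                                        end = 100000L))
  expect_equal(overlap_enrich(fg, atlas, whole)$p, 1)
  exact <- list(fgonly = data.table(chrom = "chr1",
                                    start = (1:4) * 5000L - 300L,
                                    end = (1:4) * 5000L + 301L))
  res <- overlap_enrich(fg, atlas, exact)
  expect_equal(res$k, 4L); expect_equal(res$K, 4L)
  expect_equal(res$p, oracle_hyper_upper(4, 10, 4, 4), tolerance = 1e-12)
})

test_that("planted module motifs are the top enrichment on synthetic data", {
  w <- default_world(with_sequence = TRUE)
  cfg <- w$cfg
  pwms <- lapply(consensus_pwm_counts(cfg$motif_library), pwm_from_counts)
  names(pwms) <- cfg$motif_library$id
  hits <- motif_hit_table(w$filtered, w$ann$sequence, pwms)
  map <- setNames(w$matches$cluster_id, w$matches$tss_id)
  tm <- w$sim$truth$module_membership
  for (m in paste0("module", seq_len(cfg$n_modules))) {
    ids <- na.omit(map[names(tm)[tm == m]])
    res <- motif_enrich(ids, w$filtered, hits = hits)
    want <- cfg$motif_library$id[((as.integer(sub("module", "", m)) - 1) %%
                                    nrow(cfg$motif_library)) + 1]
    expect_equal(res$term[1], want)
    expect_lt(res$q[1], 0.05)
  }
})
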