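# Synthetic CAGE world: a toy genome with non-overlapping gene models,
# planted cell-type-specific coexpression modules, alternate promoters,
# promoter-proximal motif instances, balanced bidirectional enhancers and
# sporadic background tags -- everything needed to exercise the pipeline
# end-to-end with known ground truth.

#' Default planted motif library
#'
#' Eight distinct 8-bp consensus strings loosely styled on well-known
#' myeloid-relevant motif families (AP-1, NF-kB, E-box, GATA, ETS, RUNT,
#' POU).  None is the reverse complement of another.
#' @export
default_motif_library <- function() {
  data.table(id = paste0("MOTIF", 1:8),
             consensus = c("TGACTCAG", "GGGATTCC", "CACGTGAT", "TTTCGCGC",
                           "AGATAAGG", "CCGGAAGT", "TGTGGTTT", "ATGCAAAT"))
}

#' Simulation configuration
#'
#' The stated world of the synthetic generator.  Defaults describe 5 cell
#' types with 3 replicates each (15 libraries), 200 genes on a 5 x 1 Mb
#' genome, 8 cell-type-specific coexpression modules, a quarter of genes
#' with an alternate promoter regulated by a different module, 30 balanced
#' bidirectional enhancers, and negative-binomial tag counts around
#' library sizes of 1-4 million tags.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of non-overlapping gene models.
#' @param n_cell_types,replicates_per_type sample structure.
#' @param n_modules cell-type-specific coexpression modules; modules
#'   beyond `n_cell_types` are active in two adjacent cell types.
#' @param alt_promoter_fraction fraction of genes given a second,
#'   differently-regulated TSS (>= 600 bp from the first).
#' @param n_enhancers planted intergenic bidirectional enhancers.
#' @param enhancer_balance expected directionality D of planted enhancers
#'   (0 = perfectly balanced forward/reverse emission).
#' @param motif_library data.table `id, consensus`.
#' @param planted_motif_rate probability a module TSS carries its module's
#'   motif 50 bp upstream of the summit.
#' @param library_size_range min/max total tags per sample.
#' @param dispersion negative-binomial dispersion (NB size = 1 /
#'   dispersion); 0 gives Poisson counts.
#' @param baseline_tpm,active_tpm off/on expression levels (tags per
#'   million).
#' @param noise_tss_rate per-bp density of unplanted single-sample
#'   background tag positions.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5L, chrom_length = 1e6L,
                       n_genes = 200L, n_cell_types = 5L,
                       replicates_per_type = 3L, n_modules = 8L,
                       alt_promoter_fraction = 0.25, n_enhancers = 30L,
                       enhancer_balance = 0,
                       motif_library = default_motif_library(),
                       planted_motif_rate = 0.9,
                       library_size_range = c(1e6, 4e6),
                       dispersion = 0.1, baseline_tpm = 0.2,
                       active_tpm = 50, noise_tss_rate = 5e-5,
                       seed = 42L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              replicates_per_type = as.integer(replicates_per_type),
              n_modules = as.integer(n_modules),
              alt_promoter_fraction = alt_promoter_fraction,
              n_enhancers = as.integer(n_enhancers),
              enhancer_balance = enhancer_balance,
              motif_library = as.data.table(motif_library),
              planted_motif_rate = planted_motif_rate,
              library_size_range = as.numeric(library_size_range),
              dispersion = dispersion, baseline_tpm = baseline_tpm,
              active_tpm = active_tpm, noise_tss_rate = noise_tss_rate,
              seed = as.integer(seed))
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "n_cell_types",
              "replicates_per_type", "n_modules")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$n_enhancers < 0) stop("n_enhancers must be >= 0")
  for (f in c("alt_promoter_fraction", "planted_motif_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (abs(cfg$enhancer_balance) > 1)
    stop("enhancer_balance must be in [-1, 1]")
  if (length(cfg$library_size_range) != 2 ||
      cfg$library_size_range[1] > cfg$library_size_range[2] ||
      cfg$library_size_range[1] <= 0)
    stop("library_size_range must be positive (min, max) with min <= max")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$baseline_tpm < 0 || cfg$active_tpm <= 0)
    stop("expression levels must be non-negative (active > 0)")
  if (cfg$noise_tss_rate < 0) stop("noise_tss_rate must be >= 0")
  if (!all(c("id", "consensus") %in% names(cfg$motif_library)))
    stop("motif_library needs id and consensus columns")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes on", x$n_chromosomes, "x",
      x$chrom_length, "bp;", x$n_cell_types, "cell types x",
      x$replicates_per_type, "replicates;", x$n_modules, "modules;",
      x$n_enhancers, "enhancers; seed", x$seed, "\n")
  invisible(x)
}

.module_types <- function(m, n_types) {
  # modules 1..n_types are single-type; later modules span two adjacent
  # types, giving every module a distinct activity pattern
  if (m <= n_types) return(m)
  a <- ((m - n_types - 1L) %% n_types) + 1L
  b <- (a %% n_types) + 1L
  c(a, b)
}

#' Generate the toy genome annotation
#'
#' Places non-overlapping gene bodies (2-6 kb) separated by intergenic
#' gaps of at least 2 kb on both strands, assigns gene roles (module
#' member, enhancer partner, constitutive background), adds alternate
#' promoters (second transcripts with 5' ends 600-1500 bp downstream),
#' reserves intergenic enhancer sites with >= 800 bp clearance from any
#' gene, and (optionally) draws a random genome sequence with the module
#' motif consensus planted 50 bp upstream of module TSS summits.
#'
#' @param config a [sim_config()].
#' @param sequence if FALSE, skip genome sequence / motif planting (much
#'   faster when only coordinates and counts are needed).
#' @return a `cage_annotation`: list with `config`, `genes`, `transcripts`
#'   (gene_models-compatible), `tss` (planted gene TSS table),
#'   `enhancers`, `motif_placements`, `sequence` (DNAStringSet or NULL).
#' @export
generate_annotation <- function(config, sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  clen <- config$chrom_length
  chroms <- paste0("chr", seq_len(nchr))
  per_chr <- diff(floor(seq(0, config$n_genes, length.out = nchr + 1)))

  genes <- vector("list", config$n_genes)
  gi <- 0L
  for (ci in seq_len(nchr)) {
    pos <- 0L
    for (k in seq_len(per_chr[ci])) {
      gap <- 2000L + as.integer(floor(runif(1) * 3000))
      body <- 2000L + as.integer(floor(runif(1) * 4000))
      start <- pos + gap
      end <- start + body
      if (end + 2000L > clen) {
        stop("genome too small to place ", config$n_genes,
             " genes without overlap: chromosome length is ", clen,
             " bp but up to ", ceiling(config$n_genes / nchr),
             " genes per chromosome need about ",
             ceiling(config$n_genes / nchr) * 9000 + 2000, " bp")
      }
      gi <- gi + 1L
      genes[[gi]] <- data.table(gene_id = sprintf("G%03d", gi),
                                chrom = chroms[ci], start = start,
                                end = end,
                                strand = if (runif(1) < 0.5) "+" else "-")
      pos <- end
    }
  }
  genes <- rbindlist(genes)

  # roles: module members, enhancer partners, constitutive background
  n_background <- max(0L, as.integer(round(0.05 * config$n_genes)))
  n_partner <- min(config$n_enhancers,
                   config$n_genes - n_background - config$n_modules)
  n_partner <- max(n_partner, 0L)
  n_module_genes <- config$n_genes - n_background - n_partner
  if (n_module_genes < config$n_modules)
    stop("too few genes to populate ", config$n_modules, " modules")
  shuffled <- sample(genes$gene_id)
  role <- setNames(rep("module", config$n_genes), shuffled)
  if (n_partner > 0)
    role[shuffled[seq(n_module_genes + 1, n_module_genes + n_partner)]] <-
      "partner"
  if (n_background > 0)
    role[shuffled[seq(n_module_genes + n_partner + 1, config$n_genes)]] <-
      "background"
  module_of <- setNames(rep(NA_integer_, config$n_genes), shuffled)
  module_of[shuffled[seq_len(n_module_genes)]] <-
    rep_len(seq_len(config$n_modules), n_module_genes)

  # transcripts + planted TSS table
  tss_rows <- list(); tx_rows <- list()
  tssn <- 0L
  n_alt <- as.integer(round(config$alt_promoter_fraction * config$n_genes))
  module_gene_ids <- shuffled[seq_len(n_module_genes)]
  alt_genes <- if (n_alt > 0 && n_module_genes > 0) {
    sample(module_gene_ids, min(n_alt, n_module_genes))
  } else character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    tssn <- tssn + 1L
    p1 <- if (g$strand == "+") g$start else g$end - 1L
    tx_rows[[length(tx_rows) + 1]] <-
      data.table(transcript_id = paste0(g$gene_id, ".1"),
                 gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                 end = g$end, strand = g$strand, tss = p1)
    tss_rows[[length(tss_rows) + 1]] <-
      data.table(tss_id = sprintf("TSS%04d", tssn), gene_id = g$gene_id,
                 transcript_id = paste0(g$gene_id, ".1"), chrom = g$chrom,
                 pos = p1, strand = g$strand, role = role[g$gene_id],
                 module = module_of[g$gene_id], is_alt = FALSE)
    if (g$gene_id %in% alt_genes) {
      off <- 600L + as.integer(floor(runif(1) * 900))
      tssn <- tssn + 1L
      if (g$strand == "+") {
        p2 <- g$start + off
        tx2 <- data.table(transcript_id = paste0(g$gene_id, ".2"),
                          gene_id = g$gene_id, chrom = g$chrom, start = p2,
                          end = g$end, strand = g$strand, tss = p2)
      } else {
        p2 <- g$end - 1L - off
        tx2 <- data.table(transcript_id = paste0(g$gene_id, ".2"),
                          gene_id = g$gene_id, chrom = g$chrom,
                          start = g$start, end = p2 + 1L, strand = g$strand,
                          tss = p2)
      }
      tx_rows[[length(tx_rows) + 1]] <- tx2
      # the alternate promoter is regulated by a module whose cell types
      # are disjoint from the primary module's (cell-type-partitioned
      # alternate promoter usage)
      m0 <- module_of[g$gene_id]
      t0 <- .module_types(m0, config$n_cell_types)
      alt_mod <- (m0 %% config$n_modules) + 1L
      for (step in seq_len(config$n_modules)) {
        cand <- ((m0 + step - 1L) %% config$n_modules) + 1L
        if (!length(intersect(.module_types(cand, config$n_cell_types),
                              t0))) { alt_mod <- cand; break }
      }
      tss_rows[[length(tss_rows) + 1]] <-
        data.table(tss_id = sprintf("TSS%04d", tssn), gene_id = g$gene_id,
                   transcript_id = paste0(g$gene_id, ".2"), chrom = g$chrom,
                   pos = p2, strand = g$strand, role = "module",
                   module = alt_mod, is_alt = TRUE)
    }
  }
  transcripts <- rbindlist(tx_rows)
  tss <- rbindlist(tss_rows)

  # enhancer sites in intergenic gaps, >= 800 bp from any gene
  clear <- 800L
  gaps <- rbindlist(lapply(chroms, function(ch) {
    gg <- genes[chrom == ch][order(start)]
    bounds <- c(0L, as.vector(rbind(gg$start, gg$end)), clen)
    n <- length(bounds) / 2
    data.table(chrom = ch, start = bounds[seq(1, 2 * n, 2)],
               end = bounds[seq(2, 2 * n, 2)])
  }))
  gaps <- gaps[end - start >= 2L * clear + 400L]
  if (config$n_enhancers > nrow(gaps))
    stop("genome too small: only ", nrow(gaps),
         " intergenic gaps can host enhancers, need ", config$n_enhancers)
  pick <- if (config$n_enhancers > 0) {
    gaps[sample(nrow(gaps), config$n_enhancers)]
  } else gaps[0]
  enh <- if (nrow(pick)) {
    centers <- pick$start + clear +
      as.integer(floor(runif(nrow(pick)) * (pick$end - pick$start -
                                              2L * clear)))
    data.table(enhancer_id = sprintf("E%03d", seq_len(nrow(pick))),
               chrom = pick$chrom, center = centers,
               rev_pos = centers - 90L, fwd_pos = centers + 90L,
               cell_type = ((seq_len(nrow(pick)) - 1L) %%
                              config$n_cell_types) + 1L,
               partner_gene = NA_character_)
  } else {
    data.table(enhancer_id = character(), chrom = character(),
               center = integer(), rev_pos = integer(),
               fwd_pos = integer(), cell_type = integer(),
               partner_gene = character())
  }
  setorder(enh, chrom, center)
  if (nrow(enh)) enh[, enhancer_id := sprintf("E%03d", .I)]

  # pair each enhancer with the nearest unused partner-pool gene on the
  # same chromosome; the pair shares one cell type, giving the enhancer a
  # coexpressed target for linking tests
  partner_pool <- names(role)[role == "partner"]
  ptss <- tss[gene_id %in% partner_pool & !is_alt]
  used <- character()
  partner_type <- setNames(rep(NA_integer_, length(partner_pool)),
                           partner_pool)
  if (nrow(enh)) {
    for (i in seq_len(nrow(enh))) {
      cand <- ptss[chrom == enh$chrom[i] & !(gene_id %in% used)]
      if (!nrow(cand)) next
      j <- which.min(abs(cand$pos - enh$center[i]))
      enh[i, partner_gene := cand$gene_id[j]]
      partner_type[cand$gene_id[j]] <- enh$cell_type[i]
      used <- c(used, cand$gene_id[j])
    }
  }
  leftover <- setdiff(partner_pool, used)
  if (length(leftover)) {
    partner_type[leftover] <- ((seq_along(leftover) - 1L) %%
                                 config$n_cell_types) + 1L
  }

  # cell types active per TSS
  tss[, cell_types := vapply(seq_len(.N), function(i) {
    if (role[i] == "background") {
      paste(seq_len(config$n_cell_types), collapse = ",")
    } else if (role[i] == "partner") {
      as.character(partner_type[gene_id[i]])
    } else {
      paste(.module_types(module[i], config$n_cell_types), collapse = ",")
    }
  }, "")]

  # motif placements: module TSSs carry their module's motif upstream
  lib <- config$motif_library
  placements <- list()
  midx <- which(tss$role == "module")
  for (i in midx) {
    if (runif(1) >= config$planted_motif_rate) next
    mid <- lib$id[((tss$module[i] - 1L) %% nrow(lib)) + 1L]
    at <- tss$pos[i] - 50L
    len <- nchar(lib$consensus[lib$id == mid])
    if (at < 0 || at + len > clen) next
    placements[[length(placements) + 1]] <-
      data.table(tss_id = tss$tss_id[i], motif_id = mid,
                 chrom = tss$chrom[i], pos = at)
  }
  placements <- if (length(placements)) rbindlist(placements) else
    data.table(tss_id = character(), motif_id = character(),
               chrom = character(), pos = integer())

  seqs <- NULL
  if (sequence) {
    seqs <- lapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
            collapse = "")
    })
    names(seqs) <- chroms
    if (nrow(placements)) {
      cons <- setNames(lib$consensus, lib$id)
      for (i in seq_len(nrow(placements))) {
        ch <- placements$chrom[i]
        s <- cons[placements$motif_id[i]]
        substr(seqs[[ch]], placements$pos[i] + 1L,
               placements$pos[i] + nchar(s)) <- s
      }
    }
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }

  structure(list(config = config, genes = genes[], transcripts = transcripts,
                 models = gene_models(genes, transcripts),
                 tss = tss[], enhancers = enh[],
                 motif_placements = placements, sequence = seqs),
            class = "cage_annotation")
}

#' @export
print.cage_annotation <- function(x, ...) {
  cat("cage_annotation:", nrow(x$genes), "genes,", nrow(x$tss),
      "planted TSSs,", nrow(x$enhancers), "enhancers",
      if (is.null(x$sequence)) "(no sequence)" else "(with sequence)", "\n")
  invisible(x)
}

.nb_counts <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
  else rpois(n, mu)
}

#' Generate per-sample CTSS tracks and truth tables
#'
#' Counts per planted TSS and sample are negative binomial around
#' `tpm * library_size / 1e6`, with the on level (`active_tpm`) applying
#' only in the TSS's active cell types and `baseline_tpm` elsewhere.
#' Tags spread over a 1-20 bp window downstream of the summit with
#' geometric decay, so tag clustering is non-trivial.  Planted enhancers
#' emit a divergent pair of clusters 180 bp apart whose forward/reverse
#' expected split follows `enhancer_balance`, only in their active cell
#' type.  Background noise adds sporadic single-sample tag positions.
#'
#' @param config a [sim_config()].
#' @param annotation result of [generate_annotation()].
#' @return list with `tracks` (named list of CTSS data.tables), `sheet`
#'   (sample sheet), `library_sizes`, and `truth` (module membership,
#'   gene-TSS map, motif placements, enhancer loci, per-sample expected
#'   expressed-TSS counts, per-type signature genes).
#' @export
generate_ctss <- function(config, annotation) {
  stopifnot(inherits(annotation, "cage_annotation"))
  set.seed(config$seed + 1L)
  types <- paste0("CT", seq_len(config$n_cell_types))
  sheet <- CJ(cell_type = types, replicate = seq_len(config$replicates_per_type),
              sorted = FALSE)
  setorder(sheet, cell_type, replicate)
  sheet[, sample_id := sprintf("%s_r%d", cell_type, replicate)]
  sheet[, stage_order := match(cell_type, types)]
  setcolorder(sheet, c("sample_id", "cell_type", "replicate", "stage_order"))
  nsamp <- nrow(sheet)
  lib <- setNames(round(runif(nsamp, config$library_size_range[1],
                              config$library_size_range[2])),
                  sheet$sample_id)
  # nominal sequencing depth: planted TPM levels are defined against this
  # total; the emitted tracks hold only the planted/noise fraction of it
  sheet[, library_size := lib]
  type_idx <- match(sheet$cell_type, types)

  # emitters: planted gene TSSs plus the two divergent sides of each
  # enhancer
  tssdt <- annotation$tss
  emit <- rbind(
    tssdt[, .(id = tss_id, chrom, pos, strand, cell_types,
              tpm = config$active_tpm, kind = "tss", max_w = 20L)],
    if (nrow(annotation$enhancers)) {
      e <- annotation$enhancers
      b <- config$enhancer_balance
      rbind(data.table(id = paste0(e$enhancer_id, "_fwd"), chrom = e$chrom,
                       pos = e$fwd_pos, strand = "+",
                       cell_types = as.character(e$cell_type),
                       tpm = config$active_tpm * (1 + b) / 2, kind = "enh",
                       max_w = 10L),
            data.table(id = paste0(e$enhancer_id, "_rev"), chrom = e$chrom,
                       pos = e$rev_pos, strand = "-",
                       cell_types = as.character(e$cell_type),
                       tpm = config$active_tpm * (1 - b) / 2, kind = "enh",
                       max_w = 10L))
    })
  active_sets <- lapply(strsplit(emit$cell_types, ","), as.integer)

  # per-emitter, per-sample mean TPM, then NB counts
  active <- t(vapply(active_sets, function(as_) type_idx %in% as_,
                     logical(nsamp)))
  on_level <- outer(emit$tpm, rep(1, nsamp))
  mean_tpm <- ifelse(active, on_level, config$baseline_tpm)
  mu <- sweep(mean_tpm, 2, lib / 1e6, "*")
  counts <- matrix(.nb_counts(length(mu), as.vector(mu), config$dispersion),
                   nrow = nrow(emit))

  # positional spread with geometric decay from the summit, oriented
  # downstream of the 5' end
  rows <- vector("list", nrow(emit) * nsamp)
  ri <- 0L
  widths <- 1L + as.integer(floor(runif(nrow(emit)) * emit$max_w))
  for (i in seq_len(nrow(emit))) {
    w <- widths[i]
    probs <- 0.55 ^ (0:(w - 1)); probs <- probs / sum(probs)
    offs <- if (emit$strand[i] == "+") emit$pos[i] + 0:(w - 1) else
      emit$pos[i] - 0:(w - 1)
    ok <- offs >= 0 & offs < config$chrom_length
    for (s in seq_len(nsamp)) {
      n <- counts[i, s]
      if (n == 0) next
      parts <- if (w == 1) n else as.vector(rmultinom(1, n, probs))
      nz <- parts > 0 & ok
      if (!any(nz)) next
      ri <- ri + 1L
      rows[[ri]] <- data.table(sample = s, chrom = emit$chrom[i],
                               pos = offs[nz], strand = emit$strand[i],
                               count = parts[nz])
    }
  }
  tags <- rbindlist(rows[seq_len(ri)])

  # background noise: sporadic positions, each hit in a single sample
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  noise <- rbindlist(lapply(chroms, function(ch) {
    nn <- rpois(1, config$chrom_length * config$noise_tss_rate)
    if (nn == 0) return(NULL)
    data.table(sample = sample.int(nsamp, nn, replace = TRUE), chrom = ch,
               pos = sample.int(config$chrom_length, nn) - 1L,
               strand = sample(c("+", "-"), nn, replace = TRUE),
               count = 1L + rpois(nn, 0.3))
  }))
  if (nrow(noise)) tags <- rbind(tags, noise)

  tracks <- lapply(seq_len(nsamp), function(s) {
    dt <- tags[sample == s,
               .(count = sum(count)), by = .(chrom, pos, strand)]
    out <- data.table(chrom = dt$chrom, start = dt$pos, end = dt$pos + 1L,
                      name = ".", count = as.integer(dt$count),
                      strand = dt$strand)
    setorder(out, chrom, start, strand)
    out
  })
  names(tracks) <- sheet$sample_id

  # ground truth for recovery tests
  module_membership <- setNames(paste0("module", tssdt[role == "module", module]),
                                tssdt[role == "module", tss_id])
  gene_tss_map <- split(tssdt$tss_id, tssdt$gene_id)
  type_per_tss <- strsplit(tssdt$cell_types, ",")
  per_gene_types <- tapply(seq_len(nrow(tssdt)), tssdt$gene_id, function(ii)
    unique(unlist(type_per_tss[ii])))
  gene_role <- tapply(tssdt$role, tssdt$gene_id, function(r) r[1])
  signature_truth <- lapply(seq_along(types), function(t) {
    names(per_gene_types)[vapply(per_gene_types, function(v)
      identical(v, as.character(t)), TRUE) &
        gene_role[names(per_gene_types)] != "background"]
  })
  names(signature_truth) <- types
  expected_expressed <- vapply(seq_len(nsamp), function(s) {
    sum(vapply(seq_along(active_sets), function(i)
      (type_idx[s] %in% active_sets[[i]]) && emit$tpm[i] >= 10, TRUE))
  }, 0L)
  names(expected_expressed) <- sheet$sample_id
  enh <- copy(annotation$enhancers)
  if (nrow(enh)) {
    enh[, `:=`(cell_type = types[cell_type],
               directionality = config$enhancer_balance)]
  }
  truth <- list(module_membership = module_membership,
                gene_tss_map = gene_tss_map,
                motif_placements = annotation$motif_placements,
                tss = tssdt,
                enhancer_loci = enh[],
                signature_truth = signature_truth,
                expected_expressed = expected_expressed,
                cell_types = types)
  list(tracks = tracks, sheet = sheet[], library_sizes = lib, truth = truth)
}

#' Run the full simulation and write all files
#'
#' Writes `genome.fa`, `genes.gtf`, `samples.tsv`, `motifs.jaspar`,
#' `truth.json` and one `ctss/<sample>.ctss.bed` per sample.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param sequence write the genome FASTA (default TRUE).
#' @return (invisibly) list with `annotation`, `sim` (tracks/sheet/truth)
#'   and the written `paths`.
#' @export
simulate_cage <- function(config, out_dir, sequence = TRUE) {
  annotation <- generate_annotation(config, sequence = sequence)
  sim <- generate_ctss(config, annotation)
  dir.create(file.path(out_dir, "ctss"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(gtf = file.path(out_dir, "genes.gtf"),
                sheet = file.path(out_dir, "samples.tsv"),
                truth = file.path(out_dir, "truth.json"),
                motifs = file.path(out_dir, "motifs.jaspar"))
  write_gtf(annotation$models, paths$gtf)
  write_sample_sheet(sim$sheet, paths$sheet)
  truth <- sim$truth
  truth$gene_tss_map <- lapply(truth$gene_tss_map, as.list)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  pwms <- consensus_pwm_counts(config$motif_library)
  write_pwm(pwms, paths$motifs)
  if (sequence) {
    paths$fasta <- file.path(out_dir, "genome.fa")
    write_fasta(annotation$sequence, paths$fasta)
  }
  paths$ctss <- vapply(names(sim$tracks), function(s) {
    p <- file.path(out_dir, "ctss", paste0(s, ".ctss.bed"))
    write_ctss(sim$tracks[[s]], p)
    p
  }, "")
  invisible(list(annotation = annotation, sim = sim, paths = paths))
}

#' JASPAR-style count matrices for a consensus motif library
#'
#' Consensus base gets count 97, the other bases 1 per column, so that a
#' pseudocount of 1 yields 98/104 for the consensus base.
#' @param motif_library data.table `id, consensus`.
#' @return named list of 4 x L count matrices.
#' @export
consensus_pwm_counts <- function(motif_library) {
  out <- lapply(seq_len(nrow(motif_library)), function(i) {
    s <- strsplit(motif_library$consensus[i], "")[[1]]
    m <- matrix(1, 4, length(s), dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(s, rownames(m)), seq_along(s))] <- 97
    m
  })
  names(out) <- motif_library$id
  out
}

#' Match planted TSSs to atlas clusters
#'
#' For each planted TSS, finds the same-chromosome, same-strand atlas
#' cluster whose summit is nearest, within `tol` bp.
#' @param atlas a `tss_atlas`.
#' @param truth_tss data.table with `tss_id` (or `id`), `chrom`, `pos`,
#'   `strand`.
#' @param tol summit tolerance in bp (default 20).
#' @return data.table `tss_id, cluster_id, dist` (`NA` when unmatched).
#' @export
match_planted_tss <- function(atlas, truth_tss, tol = 20L) {
  truth_tss <- as.data.table(truth_tss)
  if (!"tss_id" %in% names(truth_tss))
    setnames(truth_tss, "id", "tss_id")
  cl <- atlas$clusters
  rbindlist(lapply(seq_len(nrow(truth_tss)), function(i) {
    tt <- truth_tss[i]
    cand <- cl[chrom == tt$chrom & strand == tt$strand &
                 abs(summit - tt$pos) <= tol]
    if (!nrow(cand)) {
      data.table(tss_id = tt$tss_id, cluster_id = NA_character_,
                 dist = NA_integer_)
    } else {
      j <- which.min(abs(cand$summit - tt$pos))
      data.table(tss_id = tt$tss_id, cluster_id = cand$cluster_id[j],
                 dist = abs(cand$summit[j] - tt$pos))
    }
  }))
}

#' Simulate a stage-ordered expression matrix for trajectory clustering
#'
#' Emulates a maturation series (default 5 stages: hematopoietic
#' progenitor, common myeloid progenitor, promyelocyte, marrow neutrophil,
#' blood neutrophil) with three planted dynamic shape families -- monotone
#' ramp, mid pulse and late switch-off -- plus flat genes.  Values are on
#' the log2(TPM + 1) scale: `baseline + gene offset + amplitude * shape +
#' Gaussian noise`.
#'
#' @param n_per_family dynamic genes per shape family (default 60).
#' @param n_flat non-dynamic genes (default 60).
#' @param n_stages ordered stages (default 5).
#' @param reps_per_stage samples per stage (default 3).
#' @param amplitude dynamic range in log2 units (default 4).
#' @param noise_sd per-sample Gaussian noise (default 0.25).
#' @param baseline expression floor in log2 units (default 2).
#' @param seed RNG seed.
#' @return list with `matrix` (genes x samples, log2tpm), `sheet`
#'   (sample sheet with `stage_order`), `truth` (gene -> family) and
#'   `stage_profiles` (true stage-mean matrix).
#' @export
simulate_stage_matrix <- function(n_per_family = 60L, n_flat = 60L,
                                  n_stages = 5L, reps_per_stage = 3L,
                                  amplitude = 4, noise_sd = 0.25,
                                  baseline = 2, seed = 1L) {
  stopifnot(n_stages >= 3)
  set.seed(seed)
  S <- n_stages
  shapes <- list(
    ramp = seq(0, 1, length.out = S),
    pulse = { mid <- (S + 1) / 2
              1 - abs(seq_len(S) - mid) / (mid - 1) },
    switch_off = c(rep(1, ceiling(0.6 * S)), rep(0, S - ceiling(0.6 * S))))
  stage_names <- if (S == 5) {
    c("HPC", "CMP", "promyelocyte", "neutrophil_marrow", "neutrophil_blood")
  } else paste0("stage", seq_len(S))
  sheet <- CJ(stage_order = seq_len(S), replicate = seq_len(reps_per_stage),
              sorted = TRUE)
  sheet[, cell_type := stage_names[stage_order]]
  sheet[, sample_id := sprintf("%s_r%d", cell_type, replicate)]
  setcolorder(sheet, c("sample_id", "cell_type", "replicate", "stage_order"))

  fams <- c(rep(names(shapes), each = n_per_family), rep("flat", n_flat))
  n_genes <- length(fams)
  ids <- sprintf("TG%04d", seq_len(n_genes))
  prof <- t(vapply(seq_len(n_genes), function(i) {
    base <- baseline + runif(1)
    if (fams[i] == "flat") rep(base, S) else
      base + amplitude * runif(1, 0.75, 1.25) * shapes[[fams[i]]]
  }, numeric(S)))
  rownames(prof) <- ids
  colnames(prof) <- stage_names
  mat <- prof[, sheet$stage_order] +
    matrix(stats::rnorm(n_genes * nrow(sheet), sd = noise_sd),
           n_genes, nrow(sheet))
  mat[mat < 0] <- 0
  colnames(mat) <- sheet$sample_id
  attr(mat, "units") <- "log2tpm"
  list(matrix = mat, sheet = sheet[], truth = setNames(fams, ids),
       stage_profiles = prof)
}
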