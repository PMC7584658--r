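#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of tumor samples with planted structural variants and
#' promoter-substitution effects. Array segment means follow the purity
#' mixture model `log2((purity * CN + (1 - purity) * 2) / 2)` with additive
#' Gaussian amplitude noise (log2 units) and a floor that stands in for the
#' dynamic range of the array; segment boundaries are jittered uniformly
#' within one probe spacing to emulate the probe grid. Expression is
#' log-normal per gene; samples affected by a planted promoter substitution
#' have the 3' partner multiplied by the planted fold effect, and the donor
#' gene's baseline is set `max(2, fold)`-fold above the 3' partner's so the
#' planted mechanism (a stronger promoter driving induction) is coherent.
#'
#' @param seed integer RNG seed; a fixed seed reproduces the cohort exactly.
#' @param cancer_types character vector of cancer-type labels.
#' @param n_samples samples per cancer type (recycled).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param cen_halfwidth half-width of the centromere interval, centered on
#'   the chromosome midpoint (bp).
#' @param probe_spacing probe grid spacing in bp; boundary jitter is uniform
#'   in +/- one spacing.
#' @param purity tumor cell fraction in (0, 1]; scalar or per-sample vector
#'   (recycled over all samples).
#' @param noise_sd Gaussian amplitude noise, log2 units.
#' @param sv_per_sample planted background SVs per sample.
#' @param sv_size_range min/max planted SV size (bp).
#' @param tdup_frac fraction of background SVs that are tandem duplications.
#' @param nested_hom_frac fraction of planted deletions that carry a nested
#'   homozygous core (copy number 1 -> 0).
#' @param n_ps_pairs number of planted promoter-substitution gene pairs.
#' @param ps_n_affected affected samples per planted pair.
#' @param ps_fold linear induction fold of the 3' partner in affected
#'   samples (1 = no effect).
#' @param gene_width_range,gene_gap_range gene body width and intergenic gap
#'   ranges (bp) used when laying out the gene model.
#' @param biotype_probs probabilities for coding / lincRNA / other biotypes.
#' @param expr_mu_range range of per-gene baseline means, log2 scale.
#' @param expr_sd per-sample expression noise, log2 units.
#' @param amp_floor minimum emitted segment mean, log2 (caps the -Inf of a
#'   homozygous deletion in a pure sample).
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cancer_types = c("CT01", "CT02"),
                       n_samples = 25L,
                       chrom_lengths = c("1" = 6e7, "2" = 6e7, "3" = 6e7),
                       cen_halfwidth = 1.5e6,
                       probe_spacing = 3000,
                       purity = 0.7,
                       noise_sd = 0.05,
                       sv_per_sample = 6L,
                       sv_size_range = c(5e4, 2e6),
                       tdup_frac = 0.5,
                       nested_hom_frac = 0,
                       n_ps_pairs = 2L,
                       ps_n_affected = 4L,
                       ps_fold = 8,
                       gene_width_range = c(2e4, 1.5e5),
                       gene_gap_range = c(5e4, 3e5),
                       biotype_probs = c(coding = 0.85, lincRNA = 0.05,
                                         other = 0.10),
                       expr_mu_range = c(3, 9),
                       expr_sd = 0.5,
                       amp_floor = -8) {
  cfg <- list(seed = as.integer(seed), cancer_types = cancer_types,
              n_samples = rep_len(as.integer(n_samples), length(cancer_types)),
              chrom_lengths = chrom_lengths, cen_halfwidth = cen_halfwidth,
              probe_spacing = probe_spacing, purity = purity,
              noise_sd = noise_sd, sv_per_sample = as.integer(sv_per_sample),
              sv_size_range = sv_size_range, tdup_frac = tdup_frac,
              nested_hom_frac = nested_hom_frac,
              n_ps_pairs = as.integer(n_ps_pairs),
              ps_n_affected = as.integer(ps_n_affected), ps_fold = ps_fold,
              gene_width_range = gene_width_range,
              gene_gap_range = gene_gap_range,
              biotype_probs = biotype_probs,
              expr_mu_range = expr_mu_range, expr_sd = expr_sd,
              amp_floor = amp_floor)
  class(cfg) <- "sim_config"
  stopifnot(all(cfg$purity > 0), all(cfg$purity <= 1), cfg$noise_sd >= 0,
            cfg$expr_sd >= 0, cfg$ps_fold > 0,
            cfg$sv_size_range[1] <= cfg$sv_size_range[2],
            is.null(names(cfg$chrom_lengths)) == FALSE)
  if (cfg$n_ps_pairs > 0 && cfg$ps_n_affected > min(cfg$n_samples)) {
    stop("ps_n_affected cannot exceed the samples available per cancer type")
  }
  cfg
}

#' Expected segment mean under the purity mixture model
#'
#' `log2((purity * cn + (1 - purity) * 2) / 2)`, floored. At purity 1 a
#' single-copy loss gives exactly -1 and a single-copy gain log2(3/2); lower
#' purity pulls every amplitude toward 0.
#'
#' @param cn integer tumor copy number (ploidy-2 baseline).
#' @param purity tumor cell fraction in (0, 1].
#' @param floor lower cap, log2.
#' @return expected log2 segment mean.
#' @export
mixture_seg_mean <- function(cn, purity, floor = -8) {
  pmax(floor, log2((purity * cn + (1 - purity) * 2) / 2))
}

# lay out non-overlapping genes along one chromosome, avoiding the
# telomere/centromere exclusion neighbourhoods
layout_genes_chrom <- function(chrom, len, cen_start, cen_end, cfg, id_offset) {
  tel_margin <- 3e6
  cen_lo <- cen_start - 2.5e6
  cen_hi <- cen_end + 2.5e6
  pos <- tel_margin
  rows <- list()
  k <- 0L
  repeat {
    gap <- stats::runif(1, cfg$gene_gap_range[1], cfg$gene_gap_range[2])
    gstart <- round(pos + gap)
    gwidth <- round(stats::runif(1, cfg$gene_width_range[1],
                                 cfg$gene_width_range[2]))
    gend <- gstart + gwidth
    if (gstart < cen_hi && gend > cen_lo) {
      pos <- cen_hi
      next
    }
    if (gend > len - tel_margin) break
    k <- k + 1L
    rows[[k]] <- data.frame(
      gene_id = sprintf("SIMG%05d", id_offset + k),
      chrom = chrom, start = gstart, end = gend,
      strand = sample(c("+", "-"), 1),
      biotype = sample(names(cfg$biotype_probs), 1,
                       prob = cfg$biotype_probs),
      stringsAsFactors = FALSE
    )
    pos <- gend
  }
  do.call(rbind, rows)
}

# uniform breakpoint jitter within one probe spacing
jitter_bp <- function(bp, spacing) {
  bp + round(stats::runif(length(bp), -spacing, spacing))
}

#' Simulate a complete synthetic cohort with a truth ledger
#'
#' Generates, deterministically from `config$seed`: a genome reference, a
#' GENCODE-like gene model, per-sample planted deletions and tandem
#' duplications (copy number 2 -> 1, optionally nested 1 -> 0, and 2 -> 3),
#' the resulting SEG-style segment table under the purity/noise model, an
#' expression matrix with planted 3'-partner induction, sample labels and
#' the truth tables grounding every recovery test. Planted
#' promoter-substitution pairs are deletions bridging two adjacent
#' same-strand coding genes, so the DNA and RNA layers are mutually
#' consistent.
#'
#' @param config a [sim_config()].
#' @return a list of class `ps_cohort`: `config`, `genome`, `genes`
#'   (with `gene_name` and `tss`), `segments`, `expr`, `labels`, `purity`,
#'   `truth_svs` (`sample`, `cancer_type`, `chrom`, `bp1`, `bp2`, `sv_type`,
#'   `cn`, `origin`), `truth_ps` (`pair_key`, `gene5`, `gene3`,
#'   `cancer_type`, `fold`, `samples`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)

  ## genome reference
  chroms <- names(cfg$chrom_lengths)
  lens <- unname(cfg$chrom_lengths)
  mid <- floor(lens / 2)
  genome <- data.frame(chrom = chroms, length = lens,
                       cen_start = mid - cfg$cen_halfwidth,
                       cen_end = mid + cfg$cen_halfwidth,
                       stringsAsFactors = FALSE)

  ## gene model
  gene_parts <- list()
  off <- 0L
  for (i in seq_along(chroms)) {
    g <- layout_genes_chrom(chroms[i], lens[i], genome$cen_start[i],
                            genome$cen_end[i], cfg, off)
    off <- off + nrow(g)
    gene_parts[[i]] <- g
  }
  genes <- do.call(rbind, gene_parts)
  genes$gene_name <- genes$gene_id
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  rownames(genes) <- NULL

  ## samples
  samples <- unlist(lapply(seq_along(cfg$cancer_types), function(i) {
    sprintf("%s_S%02d", cfg$cancer_types[i], seq_len(cfg$n_samples[i]))
  }))
  labels <- stats::setNames(rep(cfg$cancer_types, cfg$n_samples), samples)
  purity <- stats::setNames(rep_len(cfg$purity, length(samples)), samples)

  ## planted promoter-substitution pairs: deletions bridging two adjacent
  ## same-strand coding genes
  truth_ps <- NULL
  ps_sv <- NULL
  if (cfg$n_ps_pairs > 0) {
    cand <- list()
    for (ch in chroms) {
      gc <- genes[genes$chrom == ch & genes$biotype == "coding", ]
      gc <- gc[order(gc$start), ]
      if (nrow(gc) < 2) next
      for (k in seq_len(nrow(gc) - 1)) {
        if (gc$strand[k] == gc$strand[k + 1]) {
          cand[[length(cand) + 1]] <- gc[k:(k + 1), ]
        }
      }
    }
    if (length(cand) < cfg$n_ps_pairs) {
      stop("gene layout offers too few adjacent same-strand coding pairs")
    }
    picked <- integer(0)
    used_genes <- character(0)
    for (idx in sample(seq_along(cand))) {
      ids <- cand[[idx]]$gene_id
      if (!any(ids %in% used_genes)) {
        picked <- c(picked, idx)
        used_genes <- c(used_genes, ids)
      }
      if (length(picked) == cfg$n_ps_pairs) break
    }
    if (length(picked) < cfg$n_ps_pairs) {
      stop("could not select disjoint planted gene pairs")
    }
    ps_rows <- list()
    sv_rows <- list()
    for (j in seq_along(picked)) {
      pr <- cand[[picked[j]]]
      a <- pr[1, ]; b <- pr[2, ]  # a upstream of b in coordinates
      ct <- cfg$cancer_types[(j - 1) %% length(cfg$cancer_types) + 1]
      aff <- sample(samples[labels == ct], cfg$ps_n_affected)
      bp1 <- round(a$start + 0.5 * (a$end - a$start))
      bp2 <- round(b$start + 0.5 * (b$end - b$start))
      g5 <- if (a$strand == "+") a else b
      g3 <- if (a$strand == "+") b else a
      ps_rows[[j]] <- data.frame(
        pair_key = paste(g5$gene_id, g3$gene_id, sep = "|"),
        gene5 = g5$gene_id, gene3 = g3$gene_id, cancer_type = ct,
        fold = cfg$ps_fold, samples = paste(aff, collapse = ","),
        stringsAsFactors = FALSE
      )
      sv_rows[[j]] <- data.frame(
        sample = aff, cancer_type = ct, chrom = a$chrom,
        bp1 = bp1, bp2 = bp2, sv_type = "DEL", cn = 1,
        origin = "PS", stringsAsFactors = FALSE
      )
    }
    truth_ps <- do.call(rbind, ps_rows)
    ps_sv <- do.call(rbind, sv_rows)
  }

  ## background SVs, rejection-sampled into arm regions with margins
  margin <- cfg$probe_spacing * 2 + 2e6  # exclusion zone + jitter safety
  min_sep <- 2e4
  arms <- list()
  for (i in seq_along(chroms)) {
    arms[[chroms[i]]] <- rbind(
      c(margin + 1e5, genome$cen_start[i] - margin - 1e5),
      c(genome$cen_end[i] + margin + 1e5, lens[i] - margin - 1e5)
    )
  }
  occupied <- list()  # per sample|chrom: matrix of intervals
  occ_key <- function(s, ch) paste(s, ch, sep = "\r")
  add_occ <- function(s, ch, b1, b2) {
    k <- occ_key(s, ch)
    occupied[[k]] <<- rbind(occupied[[k]], c(b1, b2))
  }
  free <- function(s, ch, b1, b2) {
    k <- occ_key(s, ch)
    occ <- occupied[[k]]
    if (is.null(occ)) return(TRUE)
    all(b1 > occ[, 2] + min_sep | b2 < occ[, 1] - min_sep)
  }
  if (!is.null(ps_sv)) {
    for (r in seq_len(nrow(ps_sv))) {
      add_occ(ps_sv$sample[r], ps_sv$chrom[r], ps_sv$bp1[r], ps_sv$bp2[r])
    }
  }
  bg_rows <- list()
  for (s in samples) {
    for (k in seq_len(cfg$sv_per_sample)) {
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample(seq_along(chroms), 1, prob = lens)
        ch <- chroms[ci]
        size <- round(stats::runif(1, cfg$sv_size_range[1],
                                   cfg$sv_size_range[2]))
        arm <- arms[[ch]][sample(1:2, 1), ]
        if (arm[2] - arm[1] < size) next
        b1 <- round(stats::runif(1, arm[1], arm[2] - size))
        b2 <- b1 + size - 1
        if (!free(s, ch, b1, b2)) next
        is_tdup <- stats::runif(1) < cfg$tdup_frac
        nested <- !is_tdup && cfg$nested_hom_frac > 0 &&
          stats::runif(1) < cfg$nested_hom_frac
        add_occ(s, ch, b1, b2)
        bg_rows[[length(bg_rows) + 1]] <- data.frame(
          sample = s, cancer_type = unname(labels[s]), chrom = ch,
          bp1 = b1, bp2 = b2,
          sv_type = if (is_tdup) "TDUP" else "DEL",
          cn = if (is_tdup) 3 else 1,
          origin = if (nested) "BG_NESTED" else "BG",
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a background SV without overlap; ",
             "reduce sv_per_sample or sizes")
      }
    }
  }
  truth_svs <- rbind(ps_sv, do.call(rbind, bg_rows))
  truth_svs <- truth_svs[order(truth_svs$sample, chrom_key(truth_svs$chrom),
                               truth_svs$bp1), ]
  rownames(truth_svs) <- NULL

  ## nested homozygous cores become extra truth rows (callable as DEL)
  nest <- truth_svs[truth_svs$origin == "BG_NESTED", , drop = FALSE]
  if (nrow(nest) > 0) {
    core <- nest
    qspan <- (nest$bp2 - nest$bp1 + 1) %/% 4
    core$bp1 <- nest$bp1 + qspan
    core$bp2 <- nest$bp2 - qspan
    core$cn <- 0
    core$origin <- "BG_NESTED_CORE"
    truth_svs <- rbind(truth_svs, core)
    truth_svs <- truth_svs[order(truth_svs$sample,
                                 chrom_key(truth_svs$chrom), truth_svs$bp1), ]
    rownames(truth_svs) <- NULL
  }

  ## SEG profile per sample-chromosome
  seg_rows <- list()
  for (s in samples) {
    pur <- purity[[s]]
    for (i in seq_along(chroms)) {
      ch <- chroms[i]
      ev <- truth_svs[truth_svs$sample == s & truth_svs$chrom == ch &
                        truth_svs$origin != "BG_NESTED_CORE", , drop = FALSE]
      cores <- truth_svs[truth_svs$sample == s & truth_svs$chrom == ch &
                           truth_svs$origin == "BG_NESTED_CORE", ,
                         drop = FALSE]
      pieces <- list()
      prev <- 1
      if (nrow(ev) > 0) {
        for (r in seq_len(nrow(ev))) {
          jb1 <- jitter_bp(ev$bp1[r], cfg$probe_spacing)
          jb2 <- jitter_bp(ev$bp2[r], cfg$probe_spacing)
          pieces[[length(pieces) + 1]] <- c(prev, jb1 - 1, 2)
          core <- cores[cores$bp1 > ev$bp1[r] & cores$bp2 < ev$bp2[r], ,
                        drop = FALSE]
          if (nrow(core) == 1) {
            ji1 <- jitter_bp(core$bp1[1], cfg$probe_spacing)
            ji2 <- jitter_bp(core$bp2[1], cfg$probe_spacing)
            pieces[[length(pieces) + 1]] <- c(jb1, ji1 - 1, ev$cn[r])
            pieces[[length(pieces) + 1]] <- c(ji1, ji2, 0)
            pieces[[length(pieces) + 1]] <- c(ji2 + 1, jb2, ev$cn[r])
          } else {
            pieces[[length(pieces) + 1]] <- c(jb1, jb2, ev$cn[r])
          }
          prev <- jb2 + 1
        }
      }
      pieces[[length(pieces) + 1]] <- c(prev, lens[i], 2)
      pm <- do.call(rbind, pieces)
      npieces <- nrow(pm)
      noise <- stats::rnorm(npieces, 0, cfg$noise_sd)
      m <- log2((pur * pm[, 3] + (1 - pur) * 2) / 2)
      seg_mean <- pmax(cfg$amp_floor, m + noise)
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        sample = s, cancer_type = unname(labels[s]), chrom = ch,
        start = pm[, 1], end = pm[, 2],
        num_probes = pmax(1, round((pm[, 2] - pm[, 1] + 1) /
                                     cfg$probe_spacing)),
        seg_mean = seg_mean, stringsAsFactors = FALSE
      )
    }
  }
  segments <- do.call(rbind, seg_rows)
  segments <- sort_segments(segments)
  rownames(segments) <- NULL

  ## expression: log-normal baseline, planted induction on the RNA layer
  mu <- stats::setNames(stats::runif(nrow(genes), cfg$expr_mu_range[1],
                                     cfg$expr_mu_range[2]), genes$gene_id)
  if (!is.null(truth_ps)) {
    for (j in seq_len(nrow(truth_ps))) {
      mu[truth_ps$gene5[j]] <- mu[truth_ps$gene3[j]] +
        max(1, log2(truth_ps$fold[j]))
    }
  }
  expr <- matrix(0, nrow = nrow(genes), ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    expr[, j] <- 2^(mu + stats::rnorm(nrow(genes), 0, cfg$expr_sd))
  }
  if (!is.null(truth_ps)) {
    for (j in seq_len(nrow(truth_ps))) {
      aff <- strsplit(truth_ps$samples[j], ",", fixed = TRUE)[[1]]
      expr[truth_ps$gene3[j], aff] <- expr[truth_ps$gene3[j], aff] *
        truth_ps$fold[j]
    }
  }

  structure(list(config = cfg, genome = genome,
                 genes = genes[, c("gene_id", "gene_name", "chrom", "start",
                                   "end", "strand", "biotype", "tss")],
                 segments = segments, expr = expr, labels = labels,
                 purity = purity, truth_svs = truth_svs,
                 truth_ps = truth_ps %||% data.frame()),
            class = "ps_cohort")
}

#' Simulate a null cohort (no expression induction)
#'
#' Identical to [simulate_cohort()] — same seed, same DNA layer, same
#' planted rearrangements — but every planted expression effect is set to
#' fold 1, so designated 3' partners are distributionally identical between
#' affected and unaffected samples. Used for false-discovery-rate control
#' checks.
#'
#' @param config a [sim_config()].
#' @return a `ps_cohort` list.
#' @export
null_cohort <- function(config = sim_config()) {
  config$ps_fold <- 1
  simulate_cohort(config)
}

#' Write a synthetic cohort to pipeline input files
#'
#' Emits exactly the formats the pipeline consumes: SEG segments, GTF gene
#' model, genome reference TSV, expression TSV, sample label TSV and the two
#' truth TSVs.
#'
#' @param cohort a `ps_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    seg = file.path(dir, "segments.seg"),
    gtf = file.path(dir, "genes.gtf"),
    genome = file.path(dir, "genome.tsv"),
    expr = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth_svs = file.path(dir, "truth_svs.tsv"),
    truth_ps = file.path(dir, "truth_ps.tsv")
  )
  write_seg(cohort$segments, paths[["seg"]])
  write_gtf(cohort$genes, paths[["gtf"]])
  write_genome_ref(cohort$genome, paths[["genome"]])
  expr_out <- data.frame(gene_id = rownames(cohort$expr), cohort$expr,
                         check.names = FALSE)
  utils::write.table(expr_out, paths[["expr"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cohort$labels),
               cancer_type = unname(cohort$labels)),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cohort$truth_svs, paths[["truth_svs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth_ps, paths[["truth_ps"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @export
print.ps_cohort <- function(x, ...) {
  cat("synthetic cohort:",
      length(x$labels), "samples,",
      nrow(x$genes), "genes,",
      nrow(x$segments), "segments,",
      nrow(x$truth_svs), "planted SVs,",
      nrow(x$truth_ps), "planted PS pairs\n")
  invisible(x)
}
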