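# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk except through tempfiles written here.

state_levels <- c("HOMDEL", "HEMIDEL", "NEUTRAL", "GAIN", "AMP")

# representative mid-bin amplitude for each state
state_amplitude <- c(HOMDEL = -2, HEMIDEL = -0.5, NEUTRAL = 0,
                     GAIN = 0.5, AMP = 1.5)

# classified segment table from a state sequence (contiguous 1 Mb tiles
# unless gaps are given, one per junction)
segs_from_states <- function(states, sample = "S1", chrom = "1",
                             width = 1e6, gaps = 0, cancer_type = "CT",
                             num_probes = 50) {
  n <- length(states)
  gaps <- rep_len(gaps, max(0, n - 1))
  start <- numeric(n); end <- numeric(n)
  pos <- 1
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + width - 1
    pos <- end[i] + 1 + if (i < n) gaps[i] else 0
  }
  df <- data.frame(sample = sample, cancer_type = cancer_type, chrom = chrom,
                   start = start, end = end, num_probes = num_probes,
                   seg_mean = unname(state_amplitude[states]),
                   stringsAsFactors = FALSE)
  df$state <- factor(states, levels = state_levels, ordered = TRUE)
  df
}

# two-gene toy chromosome used by the promoter-substitution geometry tests
toy_genes <- function(strand_a = "+", strand_b = "+",
                      biotype_a = "coding", biotype_b = "coding") {
  g <- data.frame(
    gene_id = c("GA", "GB"), gene_name = c("GA", "GB"), chrom = "1",
    start = c(300001, 700001), end = c(350000, 760000),
    strand = c(strand_a, strand_b), biotype = c(biotype_a, biotype_b),
    stringsAsFactors = FALSE
  )
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}

# run the DNA half of the pipeline on a synthetic cohort
call_pipeline_svs <- function(co, config = ps_config()) {
  segs <- classify_segments(co$segments, config)
  segs <- merge_segments(segs, config)
  segs <- filter_gap_adjacent(segs, config)
  filter_svs(call_svs(segs), co$genome, config)
}

# recall / precision / label coherence of calls against the planted truth,
# breakpoints matched within one probe spacing
recovery_metrics <- function(co, svs) {
  tol <- co$config$probe_spacing
  truth <- co$truth_svs
  prec <- match_svs(svs, truth, tol = tol)
  rec <- match_svs(truth, svs, tol = tol)
  list(recall = rec$summary$frac_matched,
       precision = prec$summary$frac_matched,
       coherence = prec$summary$frac_coherent,
       n_truth = nrow(truth), n_calls = nrow(svs))
}

# exhaustive promoter-substitution geometry sweep on the two-gene toy
# chromosome: every SV type x strand combination x ordered breakpoint pair.
# Returns agreement counts of detect_ps against the junction oracle.
ps_geometry_sweep <- function(window = 2e5) {
  positions <- c(50000, 180001, 325000, 340010, 420000, 560000,
                 720500, 745000, 820001, 1400000)
  cfg <- ps_config(upstream_window = window)
  n_cases <- 0L
  n_agree <- 0L
  mismatches <- list()
  for (sa in c("+", "-")) for (sb in c("+", "-")) {
    genes <- toy_genes(sa, sb)
    for (sv_type in c("DEL", "TDUP")) {
      for (i in seq_along(positions)) for (j in seq_along(positions)) {
        if (i >= j) next
        bp1 <- positions[i]; bp2 <- positions[j]
        a1 <- annotate_breakpoints(
          data.frame(chrom = "1", position = bp1), genes)
        a2 <- annotate_breakpoints(
          data.frame(chrom = "1", position = bp2), genes)
        got <- detect_ps(sv_type, bp1, bp2, a1, a2, cfg)
        want <- oracle_ps(sv_type, bp1, bp2, genes, window)
        same <- if (is.null(got) && is.null(want)) TRUE
        else if (is.null(got) || is.null(want)) FALSE
        else got$category == want$category &&
          got$gene5 == want$gene5 && got$gene3 == want$gene3
        n_cases <- n_cases + 1L
        if (same) n_agree <- n_agree + 1L
        else mismatches[[length(mismatches) + 1]] <-
            list(sa = sa, sb = sb, sv_type = sv_type, bp1 = bp1, bp2 = bp2,
                 got = got, want = want)
      }
    }
  }
  list(n_cases = n_cases, n_agree = n_agree, mismatches = mismatches)
}

# synthetic candidate screen: `n_null` recurrent stronger-promoter pairs
# with no effect plus (optionally) one planted pair whose 3' partner is
# induced `fold`-fold in its affected samples.  Exercises the real
# screen_recurrent() code path on constructed events and expression.
build_screen_cohort <- function(n_null = 20, planted_fold = 8,
                                n_affected_planted = 4, n_samples = 105,
                                mu3 = 5, expr_sd = 0.5) {
  ct <- "CT"
  samples <- sprintf("S%03d", seq_len(n_samples))
  labels <- stats::setNames(rep(ct, n_samples), samples)
  n_pairs <- n_null + as.integer(planted_fold > 0)
  genes <- c(sprintf("g5_%02d", seq_len(n_pairs)),
             sprintf("g3_%02d", seq_len(n_pairs)))
  mu <- stats::setNames(c(rep(mu3 + 1.5, n_pairs), rep(mu3, n_pairs)), genes)
  expr <- 2^(matrix(stats::rnorm(length(genes) * n_samples, 0, expr_sd),
                    nrow = length(genes),
                    dimnames = list(genes, samples)) + mu)
  ev_rows <- list()
  for (k in seq_len(n_pairs)) {
    n_aff <- if (planted_fold > 0 && k == 1) n_affected_planted
    else sample(2:4, 1)
    aff <- sample(samples, n_aff)
    g5 <- sprintf("g5_%02d", k); g3 <- sprintf("g3_%02d", k)
    if (planted_fold > 0 && k == 1) {
      expr[g3, aff] <- expr[g3, aff] * planted_fold
      # a planted induced pair also has its mechanistically stronger donor
      expr[g5, ] <- expr[g5, ] * 2^(log2(planted_fold) - 1.5)
    }
    ev_rows[[k]] <- data.frame(
      sample = aff, cancer_type = ct, chrom = "1",
      bp1 = 1e6 * k, bp2 = 1e6 * k + 5e4, sv_type = "DEL",
      category = "FUSION", gene5 = g5, gene5_name = g5,
      gene3 = g3, gene3_name = g3, strand = "+", upstream_distance = 0,
      pair_key = paste(g5, g3, sep = "|"), stringsAsFactors = FALSE
    )
  }
  list(events = do.call(rbind, ev_rows), expr = expr, labels = labels,
       planted_pair = if (planted_fold > 0) "g5_01|g3_01" else NA_character_)
}
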