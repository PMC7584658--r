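test_that("the purity mixture formula reproduces its closed-form anchors", {
  # pure tumor, single-copy loss: exactly -1, classified hemizygous
  expect_equal(mixture_seg_mean(1, 1), -1)
  expect_equal(as.character(classify_state(mixture_seg_mean(1, 1))), "HEMIDEL")
  # 50% purity dilutes the loss towards 0
  expect_equal(mixture_seg_mean(1, 0.5), log2(0.75))
  # complete loss in a pure tumor hits the amplitude floor
  expect_equal(mixture_seg_mean(0, 1), -8)
  expect_equal(as.character(classify_state(mixture_seg_mean(0, 1))), "HOMDEL")
  # single-copy gain in a pure tumor
  expect_equal(mixture_seg_mean(3, 1), log2(1.5))
})

test_that("the mixture is monotone in copy number and in purity", {
  for (p in c(0.2, 0.5, 0.8, 1)) {
    m <- mixture_seg_mean(0:6, p)
    expect_false(is.unsorted(m, strictly = FALSE))
    expect_true(all(diff(mixture_seg_mean(1:6, p)) > 0))
  }
  pur <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(mixture_seg_mean(4, pur)) > 0))   # gains grow
  expect_true(all(diff(mixture_seg_mean(1, pur)) < 0))   # losses deepen
  expect_true(all(mixture_seg_mean(2, pur) == 0))        # neutral stays 0
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- sim_config(seed = 97, n_samples = 4, sv_per_sample = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth_svs, b$truth_svs)
  cfg2 <- cfg
  cfg2$seed <- 98L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(a$segments, c2$segments))
})

test_that("emitted segments are a contiguous tiling consistent with the truth", {
  co <- simulate_cohort(sim_config(seed = 101, n_samples = 4,
                                   sv_per_sample = 3))
  segs <- co$segments
  key <- paste(segs$sample, segs$chrom)
  for (k in unique(key)) {
    g <- segs[key == k, ]
    expect_equal(g$start[1], 1)
    expect_equal(g$end[nrow(g)],
                 unname(co$config$chrom_lengths[g$chrom[1]]))
    if (nrow(g) > 1) {
      expect_equal(g$start[-1], g$end[-nrow(g)] + 1)
    }
  }
  # planted SVs stay inside chromosome bounds and clear of excluded zones
  tr <- co$truth_svs
  len <- co$genome$length[match(tr$chrom, co$genome$chrom)]
  expect_true(all(tr$bp1 > 2e6 & tr$bp2 < len - 2e6))
  expect_true(all(tr$bp1 < tr$bp2))
  # expression covers every gene and sample
  expect_equal(dim(co$expr), c(nrow(co$genes), length(co$labels)))
  expect_true(all(is.finite(co$expr) & co$expr >= 0))
})

test_that("a noise-free pure cohort emits exact mixture amplitudes", {
  cfg <- sim_config(seed = 103, n_samples = 2, sv_per_sample = 2,
                    purity = 1, noise_sd = 0, n_ps_pairs = 0)
  co <- simulate_cohort(cfg)
  dels <- co$truth_svs[co$truth_svs$sv_type == "DEL", ]
  segs <- co$segments
  for (r in seq_len(nrow(dels))) {
    hit <- segs[segs$sample == dels$sample[r] &
                  segs$chrom == dels$chrom[r] &
                  segs$start >= dels$bp1[r] - cfg$probe_spacing &
                  segs$end <= dels$bp2[r] + cfg$probe_spacing, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$seg_mean, -1)
  }
})

test_that("the null cohort shares the DNA layer and removes only the RNA effect", {
  cfg <- sim_config(seed = 107, n_samples = 6, sv_per_sample = 2)
  co <- simulate_cohort(cfg)
  nu <- null_cohort(cfg)
  expect_identical(co$segments, nu$segments)
  expect_identical(co$truth_svs[, c("sample", "chrom", "bp1", "bp2", "sv_type")],
                   nu$truth_svs[, c("sample", "chrom", "bp1", "bp2", "sv_type")])
  expect_true(all(nu$truth_ps$fold == 1))
  # genes not involved in planted pairs have identical expression
  planted <- unique(c(co$truth_ps$gene5, co$truth_ps$gene3))
  other <- setdiff(rownames(co$expr), planted)
  expect_identical(co$expr[other, ], nu$expr[other, ])
  # the 3' partner differs exactly by the planted fold in affected samples
  for (j in seq_len(nrow(co$truth_ps))) {
    g3 <- co$truth_ps$gene3[j]
    aff <- strsplit(co$truth_ps$samples[j], ",")[[1]]
    unaff <- setdiff(colnames(co$expr), aff)
    expect_equal(co$expr[g3, aff], nu$expr[g3, aff] * co$truth_ps$fold[j])
    expect_equal(co$expr[g3, unaff], nu$expr[g3, unaff])
  }
})

test_that("written cohort files feed straight back into the readers", {
  co <- simulate_cohort(sim_config(seed = 109, n_samples = 5,
                                   sv_per_sample = 2))
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  segs <- read_seg(paths[["seg"]], labels = co$labels)
  expect_equal(nrow(segs), nrow(co$segments))
  expect_equal(sum(segs$seg_mean), sum(co$segments$seg_mean), tolerance = 1e-6)
  genes <- read_gtf(paths[["gtf"]])
  expect_equal(sort(genes$gene_id), sort(co$genes$gene_id))
  expect_equal(genes[order(genes$gene_id), c("start", "end", "strand", "biotype")],
               co$genes[order(co$genes$gene_id), c("start", "end", "strand", "biotype")],
               ignore_attr = TRUE)
  expect_equal(read_genome_ref(paths[["genome"]]), co$genome,
               ignore_attr = TRUE)
  expr <- read_expr(paths[["expr"]])
  expect_equal(expr, co$expr, tolerance = 1e-6)
  expect_equal(read_labels(paths[["labels"]]), co$labels)
})

test_that("planted promoter-substitution pairs are recovered end to end", {
  co <- simulate_cohort(sim_config(seed = 113))
  svs <- call_pipeline_svs(co)
  events <- call_ps(svs, co$genes)
  res <- screen_recurrent(events, co$expr, co$labels)
  for (j in seq_len(nrow(co$truth_ps))) {
    hit <- res[res$pair_key == co$truth_ps$pair_key[j] &
                 res$cancer_type == co$truth_ps$cancer_type[j], ]
    expect_equal(nrow(hit), 1)
    expect_true(hit$significant)
  }
  # and the null cohort yields no significant planted pair
  nu <- null_cohort(sim_config(seed = 113))
  res0 <- screen_recurrent(call_ps(call_pipeline_svs(nu), nu$genes),
                           nu$expr, nu$labels)
  hit0 <- res0[res0$pair_key %in% nu$truth_ps$pair_key, ]
  expect_false(any(hit0$significant))
})
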