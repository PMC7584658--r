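mk_expr <- function(values) {
  # values: named list gene -> numeric vector (same sample order)
  m <- do.call(rbind, values)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  m
}

test_that("promoter strength difference is the log2 gap of unaffected medians", {
  expr <- mk_expr(list(G5 = c(31, 31, 31, 100), G3 = c(7, 7, 7, 100)))
  labels <- stats::setNames(rep("CT", 4), colnames(expr))
  # median5 = 31, median3 = 7 over unaffected -> log2(32) - log2(8) = 2
  expect_equal(
    promoter_strength_diff("G5", "G3", "CT", expr, labels,
                           affected = "S04"),
    2
  )
  # equal medians -> 0
  expr2 <- mk_expr(list(G5 = c(5, 5, 5), G3 = c(5, 5, 5)))
  labels2 <- stats::setNames(rep("CT", 3), colnames(expr2))
  expect_equal(promoter_strength_diff("G5", "G3", "CT", expr2, labels2), 0)
  expect_error(
    promoter_strength_diff("G5", "NOPE", "CT", expr2, labels2),
    "NOPE"
  )
})

test_that("induction is measured per affected sample against the unaffected median", {
  expr <- mk_expr(list(G3 = c(7, 7, 7, 7, 63)))
  labels <- stats::setNames(rep("CT", 5), colnames(expr))
  ind <- induction_fc("G3", "S05", "CT", expr, labels)
  expect_equal(unname(ind), log2(64) - log2(8))  # = 3
  # affected equal to the median -> 0
  ind <- induction_fc("G3", "S01", "CT", expr, labels)
  expect_equal(unname(ind), 0)
  # zero baseline is handled by the pseudocount
  expr0 <- mk_expr(list(G3 = c(0, 0, 0, 7)))
  labels0 <- stats::setNames(rep("CT", 4), colnames(expr0))
  expect_equal(unname(induction_fc("G3", "S04", "CT", expr0, labels0)), 3)
})

test_that("the quadrant test matches hypergeometric enumeration and handles degeneracy", {
  mk_stats <- function(stronger, induced) {
    data.frame(promoter_diff = ifelse(stronger, 1, -1),
               mean_induction = ifelse(induced, 1, -1))
  }
  # perfectly balanced table: no association
  st <- mk_stats(rep(c(TRUE, FALSE), each = 10), rep(c(TRUE, FALSE), 10))
  ft <- fisher_strength_vs_induction(st)
  expect_equal(unname(as.vector(ft$table)), rep(5L, 4))
  expect_equal(ft$p_value, 1)
  # perfectly coupled 10/10: p = 2 / choose(20, 10), checked by enumeration
  st <- mk_stats(rep(c(TRUE, FALSE), each = 10),
                 rep(c(TRUE, FALSE), each = 10))
  ft <- fisher_strength_vs_induction(st)
  expect_equal(ft$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(ft$p_value, oracle_fisher(ft$table), tolerance = 1e-10)
  # empty margin: warn and return 1
  st <- mk_stats(rep(TRUE, 8), rep(c(TRUE, FALSE), 4))
  expect_warning(ft <- fisher_strength_vs_induction(st), "degenerate")
  expect_equal(ft$p_value, 1)
})

test_that("the recurrent-pair screen finds planted induction and respects its gates", {
  set.seed(71)
  sc <- build_screen_cohort(n_null = 6, planted_fold = 8)
  res <- screen_recurrent(sc$events, sc$expr, sc$labels)
  expect_true(sc$planted_pair %in% res$pair_key)
  hit <- res[res$pair_key == sc$planted_pair, ]
  expect_lte(hit$q_value, 0.1)
  expect_true(hit$significant)
  expect_gt(hit$mean_induction, 2)
  expect_gte(hit$promoter_diff, 1)
  # every candidate passed the recurrence and stronger-promoter gates
  expect_true(all(res$n_affected >= 2))
  expect_true(all(res$promoter_diff >= 1))

  # a pair whose affected samples look like everyone else is not significant
  null_row <- res[res$pair_key != sc$planted_pair, ]
  expect_true(all(!null_row$significant | null_row$q_value <= 0.1))

  # screen output is invariant to sample and gene ordering
  perm <- sample(ncol(sc$expr))
  res2 <- screen_recurrent(sc$events, sc$expr[rev(rownames(sc$expr)), perm],
                           sc$labels[perm])
  res2 <- res2[match(res$pair_key, res2$pair_key), ]
  expect_equal(res$p_value, res2$p_value)
})

test_that("degenerate screen candidates are retained with p = 1 and a flag", {
  expr <- mk_expr(list(G5 = rep(64, 8), G3 = rep(4, 8)))
  labels <- stats::setNames(rep("CT", 8), colnames(expr))
  events <- data.frame(
    sample = c("S01", "S02"), cancer_type = "CT", chrom = "1",
    bp1 = 1, bp2 = 2, sv_type = "DEL", category = "FUSION",
    gene5 = "G5", gene5_name = "G5", gene3 = "G3", gene3_name = "G3",
    strand = "+", upstream_distance = 0, pair_key = "G5|G3",
    stringsAsFactors = FALSE
  )
  res <- screen_recurrent(events, expr, labels)
  expect_equal(nrow(res), 1)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("the rank-sum case test matches exact enumeration", {
  expr <- mk_expr(list(G = c(1, 2, 3, 4, 5, 6)))
  labels <- stats::setNames(rep("CT", 6), colnames(expr))
  p <- wilcoxon_case("G", c("S01", "S02", "S03"), "CT", expr, labels)
  expect_equal(p, 0.1)
  expect_equal(p, oracle_wilcox(log2(c(1, 2, 3) + 1), log2(c(4, 5, 6) + 1)))
  # fully tied data
  exprt <- mk_expr(list(G = rep(5, 6)))
  expect_equal(wilcoxon_case("G", c("S01", "S02"), "CT", exprt, labels), 1)
  # a strong planted shift in a large group is detected
  set.seed(73)
  vals <- c(2^rnorm(5, 10, 0.5), 2^rnorm(100, 5, 0.5))
  exprs <- mk_expr(list(G = vals))
  labs <- stats::setNames(rep("CT", 105), colnames(exprs))
  expect_lt(wilcoxon_case("G", colnames(exprs)[1:5], "CT", exprs, labs),
            0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(79)
  for (rep in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # q is non-decreasing along sorted p
  p <- sort(runif(25))
  expect_false(is.unsorted(bh_fdr(p)))
})

test_that("expression and label readers round-trip pipeline files", {
  expr <- mk_expr(list(GA = c(1.5, 2), GB = c(0, 7)))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_expr(f)
  expect_equal(got, expr)
  lf <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tcancer_type", "S01\tPRAD", "S02\tOV"), lf)
  expect_equal(read_labels(lf), c(S01 = "PRAD", S02 = "OV"))
})
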