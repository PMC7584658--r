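#' Read a gene x sample expression matrix
#'
#' Tab-separated, genes in rows (first column gene ids), samples in columns,
#' linear non-negative normalized values. All downstream statistics work on
#' log2(x + 1).
#'
#' @param path path to the TSV matrix.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expr <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression matrix must contain finite non-negative values")
  }
  m
}

#' Read a sample-to-cancer-type label map
#'
#' Two-column TSV (sample, cancer_type) with header.
#'
#' @param path path to the TSV file.
#' @return named character vector: `labels[sample] == cancer_type`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file needs two columns: sample, cancer_type")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

log2p1 <- function(x) log2(x + 1)

ct_samples_of <- function(cancer_type, expr, labels) {
  s <- names(labels)[labels == cancer_type]
  intersect(colnames(expr), s)
}

#' Promoter-strength difference of a gene pair
#'
#' Promoter strength is proxied by a gene's median expression among the
#' *unaffected* samples of the cancer type; the difference is
#' `log2(median5' + 1) - log2(median3' + 1)`. A value of 1 therefore means
#' the donor promoter is 2-fold stronger.
#'
#' @param gene5,gene3 gene ids (rownames of `expr`).
#' @param cancer_type cancer-type label.
#' @param expr expression matrix ([read_expr()]).
#' @param labels sample label map ([read_labels()]).
#' @param affected character vector of affected sample ids, excluded from the
#'   medians.
#' @return log2 difference (scalar).
#' @export
promoter_strength_diff <- function(gene5, gene3, cancer_type, expr, labels,
                                   affected = character()) {
  for (g in c(gene5, gene3)) {
    if (!g %in% rownames(expr)) {
      stop("gene absent from expression matrix: ", g, call. = FALSE)
    }
  }
  unaff <- setdiff(ct_samples_of(cancer_type, expr, labels), affected)
  if (length(unaff) == 0) {
    stop("no unaffected samples for cancer type ", cancer_type, call. = FALSE)
  }
  log2p1(stats::median(expr[gene5, unaff])) -
    log2p1(stats::median(expr[gene3, unaff]))
}

#' Per-sample induction of the 3' partner
#'
#' For each affected sample, `log2(x + 1) - log2(median_unaffected + 1)`,
#' the unaffected median taken over samples of the same cancer type that do
#' not carry the event.
#'
#' @inheritParams promoter_strength_diff
#' @param gene3 gene id of the 3' partner.
#' @return named numeric vector, one log2 fold-change per affected sample.
#' @export
induction_fc <- function(gene3, affected, cancer_type, expr, labels) {
  if (!gene3 %in% rownames(expr)) {
    stop("gene absent from expression matrix: ", gene3, call. = FALSE)
  }
  affected <- intersect(affected, colnames(expr))
  unaff <- setdiff(ct_samples_of(cancer_type, expr, labels), affected)
  if (length(unaff) == 0) {
    stop("no unaffected samples for cancer type ", cancer_type, call. = FALSE)
  }
  base <- log2p1(stats::median(expr[gene3, unaff]))
  stats::setNames(log2p1(expr[gene3, affected]) - base, affected)
}

#' Per-pair, per-cancer-type expression statistics of PS events
#'
#' Groups events by (gene pair, cancer type) and computes the number of
#' distinct affected samples with expression data, the promoter-strength
#' difference and the mean 3'-partner induction. Pairs whose genes or
#' samples are missing from the expression matrix are excluded with a
#' reported count.
#'
#' @param events PS event data.frame ([call_ps()]).
#' @param expr expression matrix.
#' @param labels sample label map.
#' @return data.frame with `pair_key`, `cancer_type`, `gene5`, `gene3`,
#'   `n_affected`, `promoter_diff`, `mean_induction`.
#' @export
ps_event_stats <- function(events, expr, labels) {
  empty <- data.frame(pair_key = character(), cancer_type = character(),
                      gene5 = character(), gene3 = character(),
                      n_affected = integer(), promoter_diff = numeric(),
                      mean_induction = numeric(), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  grp <- unique(events[, c("pair_key", "cancer_type", "gene5", "gene3")])
  rows <- vector("list", nrow(grp))
  n_excl <- 0L
  for (i in seq_len(nrow(grp))) {
    pk <- grp$pair_key[i]; ct <- grp$cancer_type[i]
    g5 <- grp$gene5[i]; g3 <- grp$gene3[i]
    if (!(g5 %in% rownames(expr)) || !(g3 %in% rownames(expr))) {
      n_excl <- n_excl + 1L
      next
    }
    aff <- unique(events$sample[events$pair_key == pk &
                                  events$cancer_type == ct])
    aff <- intersect(aff, ct_samples_of(ct, expr, labels))
    unaff <- setdiff(ct_samples_of(ct, expr, labels), aff)
    if (length(aff) == 0 || length(unaff) == 0) {
      n_excl <- n_excl + 1L
      next
    }
    pd <- promoter_strength_diff(g5, g3, ct, expr, labels, affected = aff)
    ind <- induction_fc(g3, aff, ct, expr, labels)
    rows[[i]] <- data.frame(pair_key = pk, cancer_type = ct, gene5 = g5,
                            gene3 = g3, n_affected = length(aff),
                            promoter_diff = pd, mean_induction = mean(ind),
                            stringsAsFactors = FALSE)
  }
  if (n_excl > 0) {
    message(n_excl, " gene pair(s) excluded: gene or samples missing from expression data")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quadrant association between promoter strength and induction
#'
#' Dichotomizes each PS event at the configured cut points — "5' promoter
#' stronger" (`promoter_diff > fisher_strength_cut`) against "3' partner
#' induced" (`mean_induction > fisher_induction_cut`) — and tests the 2x2
#' table with a two-sided Fisher's exact test. A degenerate table (an empty
#' row or column) returns p = 1 with a warning.
#'
#' @param stats per-pair statistics from [ps_event_stats()] (needs
#'   `promoter_diff` and `mean_induction`).
#' @param config a [ps_config()].
#' @return list with `table` (2x2 counts), `odds_ratio`, `p_value`.
#' @export
fisher_strength_vs_induction <- function(stats, config = ps_config()) {
  stronger <- factor(stats$promoter_diff > config$fisher_strength_cut,
                     levels = c(TRUE, FALSE),
                     labels = c("stronger", "not_stronger"))
  induced <- factor(stats$mean_induction > config$fisher_induction_cut,
                    levels = c(TRUE, FALSE),
                    labels = c("induced", "not_induced"))
  tab <- table(stronger, induced)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (empty margin); p set to 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Screen recurrent stronger-promoter pairs for 3'-partner induction
#'
#' The candidate set holds every (gene pair, cancer type) with at least
#' `recurrence_min` distinct affected samples and a 5' promoter at least
#' `stronger_promoter_fold`-fold stronger than the 3' partner's. Each
#' candidate is tested with a two-sided Student's t-test (pooled variance;
#' Welch via `config$welch`) comparing log2(x+1) expression of the 3'
#' partner between affected and unaffected samples of that cancer type, and
#' p-values are Benjamini-Hochberg adjusted across the candidate set.
#' Candidates with an undefined test (fewer than two usable affected
#' samples, or zero variance in both groups) are retained with p = 1 and
#' flagged.
#'
#' @param events PS event data.frame ([call_ps()]).
#' @param expr expression matrix.
#' @param labels sample label map.
#' @param config a [ps_config()].
#' @return data.frame with `pair_key`, `cancer_type`, `gene5`, `gene3`,
#'   `n_affected`, `promoter_diff`, `mean_induction`, `p_value`, `q_value`,
#'   `significant` (q <= `fdr_level`), `degenerate`.
#' @export
screen_recurrent <- function(events, expr, labels, config = ps_config()) {
  st <- ps_event_stats(events, expr, labels)
  cand <- st[st$n_affected >= config$recurrence_min &
               st$promoter_diff >= log2(config$stronger_promoter_fold), ,
             drop = FALSE]
  if (nrow(cand) == 0) {
    cand$p_value <- numeric(0); cand$q_value <- numeric(0)
    cand$significant <- logical(0); cand$degenerate <- logical(0)
    return(cand)
  }
  p <- numeric(nrow(cand))
  degen <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ct <- cand$cancer_type[i]
    aff <- unique(events$sample[events$pair_key == cand$pair_key[i] &
                                  events$cancer_type == ct])
    aff <- intersect(aff, ct_samples_of(ct, expr, labels))
    unaff <- setdiff(ct_samples_of(ct, expr, labels), aff)
    x <- log2p1(expr[cand$gene3[i], aff])
    y <- log2p1(expr[cand$gene3[i], unaff])
    pv <- tryCatch(
      stats::t.test(x, y, var.equal = !config$welch,
                    alternative = "two.sided")$p.value,
      error = function(e) NA_real_
    )
    if (!is.finite(pv)) {
      p[i] <- 1
      degen[i] <- TRUE
    } else {
      p[i] <- pv
    }
  }
  cand$p_value <- p
  cand$q_value <- bh_fdr(p)
  cand$significant <- cand$q_value <= config$fdr_level
  cand$degenerate <- degen
  cand <- cand[order(cand$q_value, cand$p_value, cand$pair_key), ]
  rownames(cand) <- NULL
  cand
}

#' Wilcoxon rank-sum test for a single altered-vs-rest comparison
#'
#' Two-sided rank-sum test on log2(x+1) expression, comparing the given
#' altered samples of one cancer type with every other sample of that type.
#' The exact null distribution is used when both groups have at most 10
#' samples and no ties; otherwise the normal approximation with tie and
#' continuity correction. Fully tied data return p = 1.
#'
#' @param gene gene id.
#' @param affected character vector of altered sample ids.
#' @param cancer_type cancer-type label.
#' @param expr expression matrix.
#' @param labels sample label map.
#' @return two-sided p-value.
#' @export
wilcoxon_case <- function(gene, affected, cancer_type, expr, labels) {
  affected <- intersect(affected, colnames(expr))
  unaff <- setdiff(ct_samples_of(cancer_type, expr, labels), affected)
  if (length(affected) == 0 || length(unaff) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  x <- log2p1(expr[gene, affected])
  y <- log2p1(expr[gene, unaff])
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values of the same length.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
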