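# Which breakpoint side donates the promoter, per SV type and strand.
# A deletion joins ...(left of bp1)|(right of bp2)...; a tandem duplication
# joins ...(up to bp2)|(from bp1)....  On the plus strand transcription flows
# left-to-right across the junction, so the promoter donor sits on the left
# junction side (bp1 for DEL, bp2 for TDUP); on the minus strand the flow is
# right-to-left and the sides swap.
five_prime_side <- function(sv_type, strand) {
  if (sv_type == "DEL") {
    if (strand == "+") 1L else 2L
  } else {
    if (strand == "+") 2L else 1L
  }
}

#' Decide whether one SV creates a promoter substitution
#'
#' Two geometries qualify (coding genes only, both partners on the same
#' strand):
#' \describe{
#'   \item{FUSION}{both breakpoints fall within coding genes; the 5' partner
#'     is the gene whose TSS-containing portion is retained on the
#'     transcriptional 5' side of the junction, the other gene is the 3'
#'     partner;}
#'   \item{UPSTREAM}{exactly one breakpoint falls within a coding gene such
#'     that its 5' part, including the TSS, is retained at the junction; the
#'     other breakpoint is intergenic and annotated as upstream of a
#'     same-strand coding gene no further than `upstream_window` bp from its
#'     TSS — that gene becomes the 3' partner via transcriptional
#'     readthrough.}
#' }
#' Same-gene pairs (an SV internal to one gene), opposite-strand pairs and
#' every other geometry yield no event.
#'
#' @param sv_type "DEL" or "TDUP".
#' @param bp1,bp2 ordered breakpoints (`bp1 < bp2`).
#' @param ann1,ann2 one-row annotations of bp1 and bp2 from
#'   [annotate_breakpoints()].
#' @param config a [ps_config()].
#' @return `NULL`, or a list with `category`, `gene5`, `gene5_name`,
#'   `gene3`, `gene3_name`, `strand`, `upstream_distance`.
#' @export
detect_ps <- function(sv_type, bp1, bp2, ann1, ann2, config = ps_config()) {
  ann <- list(ann1, ann2)
  bp <- c(bp1, bp2)
  coding <- vapply(ann, function(a) identical(a$relation, "WITHIN_CODING"),
                   logical(1))

  event <- function(category, g5, g3, dist) {
    if (identical(g5$gene_id, g3$gene_id)) return(NULL)
    list(category = category,
         gene5 = g5$gene_id, gene5_name = g5$gene_name,
         gene3 = g3$gene_id, gene3_name = g3$gene_name,
         strand = g5$gene_strand, upstream_distance = dist)
  }
  # TSS-retention guard for the donor: its breakpoint must lie between the
  # TSS and the gene's 3' end in reading direction.  For a breakpoint inside
  # the gene body this always holds; it protects against degenerate
  # annotations only.
  tss_retained <- function(a, p) {
    if (a$gene_strand == "+") p >= a$gene_tss else p <= a$gene_tss
  }

  if (all(coding)) {
    if (ann1$gene_strand != ann2$gene_strand) return(NULL)
    i5 <- five_prime_side(sv_type, ann1$gene_strand)
    g5 <- ann[[i5]]
    g3 <- ann[[3L - i5]]
    if (!tss_retained(g5, bp[i5])) return(NULL)
    return(event("FUSION", g5, g3, 0))
  }

  if (sum(coding) == 1) {
    gi <- which(coding)
    g5 <- ann[[gi]]
    if (gi != five_prime_side(sv_type, g5$gene_strand)) return(NULL)
    other <- ann[[3L - gi]]
    if (!identical(other$relation, "UPSTREAM_OF")) return(NULL)
    if (!identical(other$gene_biotype, "coding")) return(NULL)
    if (!identical(other$gene_strand, g5$gene_strand)) return(NULL)
    if (other$distance > config$upstream_window) return(NULL)
    return(event("UPSTREAM", g5, other, other$distance))
  }

  NULL
}

#' Call promoter-substitution events for a table of SVs
#'
#' Annotates both breakpoints of every SV ([annotate_breakpoints()]) and
#' applies [detect_ps()] to each.
#'
#' @param svs filtered SV call data.frame ([filter_svs()] output).
#' @param genes gene model data.frame ([read_gtf()]).
#' @param config a [ps_config()].
#' @return data.frame of PS events: `sample`, `cancer_type`, `chrom`, `bp1`,
#'   `bp2`, `sv_type`, `category` ("FUSION"/"UPSTREAM"), `gene5`,
#'   `gene5_name`, `gene3`, `gene3_name`, `strand`, `upstream_distance`
#'   (0 for fusions), `pair_key`.
#' @export
call_ps <- function(svs, genes, config = ps_config()) {
  empty <- data.frame(sample = character(), cancer_type = character(),
                      chrom = character(), bp1 = numeric(), bp2 = numeric(),
                      sv_type = character(), category = character(),
                      gene5 = character(), gene5_name = character(),
                      gene3 = character(), gene3_name = character(),
                      strand = character(), upstream_distance = numeric(),
                      pair_key = character(), stringsAsFactors = FALSE)
  if (nrow(svs) == 0) return(empty)
  a1 <- annotate_breakpoints(data.frame(chrom = svs$chrom, position = svs$bp1),
                             genes)
  a2 <- annotate_breakpoints(data.frame(chrom = svs$chrom, position = svs$bp2),
                             genes)
  rows <- vector("list", nrow(svs))
  for (i in seq_len(nrow(svs))) {
    ev <- detect_ps(svs$sv_type[i], svs$bp1[i], svs$bp2[i],
                    a1[i, , drop = FALSE], a2[i, , drop = FALSE], config)
    if (is.null(ev)) next
    rows[[i]] <- data.frame(
      sample = svs$sample[i], cancer_type = svs$cancer_type[i],
      chrom = svs$chrom[i], bp1 = svs$bp1[i], bp2 = svs$bp2[i],
      sv_type = svs$sv_type[i], category = ev$category,
      gene5 = ev$gene5, gene5_name = ev$gene5_name,
      gene3 = ev$gene3, gene3_name = ev$gene3_name,
      strand = ev$strand, upstream_distance = ev$upstream_distance,
      pair_key = paste(ev$gene5, ev$gene3, sep = "|"),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate recurrence of promoter-substitution gene pairs
#'
#' Counts distinct affected samples per gene pair, within each cancer type
#' and overall. A sample carrying the same pair through several SVs counts
#' once. A pair is "recurrent" when its overall distinct-sample count reaches
#' `recurrence_min`.
#'
#' @param events PS event data.frame from [call_ps()].
#' @param config a [ps_config()].
#' @return list with `by_cancer` (pair x cancer-type rows: `pair_key`,
#'   `cancer_type`, `n_samples`) and `overall` (`pair_key`, `n_samples`,
#'   `n_cancer_types`, `recurrent`).
#' @export
build_recurrence <- function(events, config = ps_config()) {
  if (nrow(events) == 0) {
    return(list(
      by_cancer = data.frame(pair_key = character(), cancer_type = character(),
                             n_samples = integer(), stringsAsFactors = FALSE),
      overall = data.frame(pair_key = character(), n_samples = integer(),
                           n_cancer_types = integer(), recurrent = logical(),
                           stringsAsFactors = FALSE)
    ))
  }
  u <- unique(events[, c("pair_key", "cancer_type", "sample")])
  tab <- stats::aggregate(sample ~ pair_key + cancer_type, data = u, FUN = length)
  names(tab)[names(tab) == "sample"] <- "n_samples"
  tab <- tab[order(-tab$n_samples, tab$pair_key, tab$cancer_type), ]
  rownames(tab) <- NULL

  us <- unique(events[, c("pair_key", "sample")])
  n_all <- stats::aggregate(sample ~ pair_key, data = us, FUN = length)
  names(n_all)[2] <- "n_samples"
  uc <- unique(tab[, c("pair_key", "cancer_type")])
  n_ct <- stats::aggregate(cancer_type ~ pair_key, data = uc, FUN = length)
  names(n_ct)[2] <- "n_cancer_types"
  overall <- merge(n_all, n_ct, by = "pair_key")
  overall$recurrent <- overall$n_samples >= config$recurrence_min
  overall <- overall[order(-overall$n_samples, overall$pair_key), ]
  rownames(overall) <- NULL
  list(by_cancer = tab, overall = overall)
}
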