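#' Read a GENCODE-style gene model from GTF
#'
#' Keeps gene-level features only. Biotypes are collapsed to the three
#' classes the screen distinguishes: `protein_coding` becomes "coding",
#' `lincRNA` stays "lincRNA" and everything else becomes "other". The TSS is
#' the strand-dependent 5' end of the gene body (start on "+", end on "-").
#'
#' @param path path to a GTF file (GENCODE attribute dialect: `gene_id`,
#'   `gene_name`, `gene_type`/`gene_biotype`).
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, `tss`, sorted by chromosome and start.
#' @export
read_gtf <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene", , drop = FALSE]
  if (nrow(gr) == 0) stop("no gene features found in '", path, "'")
  if (is.null(gr$gene_id) || any(is.na(gr$gene_id))) {
    stop("GTF format error in '", path, "': gene feature without a gene_id attribute",
         call. = FALSE)
  }
  raw_type <- gr$gene_type %||% gr$gene_biotype
  if (is.null(raw_type)) {
    stop("GTF format error in '", path,
         "': gene features carry neither gene_type nor gene_biotype",
         call. = FALSE)
  }
  strand <- as.character(gr$strand)
  if (any(strand == "*")) {
    stop("GTF format error in '", path, "': gene feature without strand",
         call. = FALSE)
  }
  genes <- data.frame(
    gene_id = as.character(gr$gene_id),
    gene_name = as.character(gr$gene_name %||% gr$gene_id),
    chrom = norm_chrom(gr$seqnames),
    start = gr$start,
    end = gr$end,
    strand = strand,
    biotype = map_biotype(as.character(raw_type)),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order(chrom_key(genes$chrom), genes$start, genes$end), ]
  rownames(genes) <- NULL
  genes
}

map_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "coding"
  out[tolower(x) == "lincrna"] <- "lincRNA"
  out
}

#' Write a gene model as a GENCODE-style GTF
#'
#' Inverse of [read_gtf()] for the columns this package uses; chromosome
#' names are emitted with the conventional "chr" prefix.
#'
#' @param genes gene model data.frame ([read_gtf()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  type_out <- c(coding = "protein_coding", lincRNA = "lincRNA",
                other = "misc_RNA")[genes$biotype]
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                   genes$gene_id, genes$gene_name, type_out)
  lines <- sprintf("chr%s\tpromsub\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Annotate genomic positions with genes by priority
#'
#' Implements the three-tier priority used for SV breakpoints: an overlapping
#' coding gene beats an overlapping lincRNA, which beats the closest upstream
#' gene. "Upstream" is strand-aware: the position must lie 5' of the
#' candidate gene's TSS along that gene's own reading direction, and the
#' distance is measured from the position to the TSS. Ties among overlapping
#' genes are broken by the smallest gene span, then lexicographic `gene_id`;
#' ties in upstream distance by `gene_id`.
#'
#' @param bps data.frame with columns `chrom` and `position`.
#' @param genes gene model data.frame from [read_gtf()].
#' @return data.frame aligned with `bps`: `relation` (one of
#'   "WITHIN_CODING", "WITHIN_LINC", "UPSTREAM_OF", "NONE"), `gene_id`,
#'   `gene_name`, `gene_strand`, `gene_biotype`, `gene_tss`, `distance`
#'   (0 for overlaps).
#' @export
annotate_breakpoints <- function(bps, genes) {
  n <- nrow(bps)
  out <- data.frame(relation = rep("NONE", n),
                    gene_id = NA_character_, gene_name = NA_character_,
                    gene_strand = NA_character_, gene_biotype = NA_character_,
                    gene_tss = NA_real_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  by_chrom <- split(genes, genes$chrom)
  chroms <- norm_chrom(bps$chrom)
  for (i in seq_len(n)) {
    g <- by_chrom[[chroms[i]]]
    if (is.null(g) || nrow(g) == 0) next
    pos <- bps$position[i]
    ov <- g$start <= pos & pos <= g$end
    pick_overlap <- function(idx) {
      o <- idx[order(g$end[idx] - g$start[idx], g$gene_id[idx])][1]
      o
    }
    hit <- NULL
    cod <- which(ov & g$biotype == "coding")
    if (length(cod)) {
      hit <- pick_overlap(cod)
      out$relation[i] <- "WITHIN_CODING"
      out$distance[i] <- 0
    } else {
      lnc <- which(ov & g$biotype == "lincRNA")
      if (length(lnc)) {
        hit <- pick_overlap(lnc)
        out$relation[i] <- "WITHIN_LINC"
        out$distance[i] <- 0
      } else {
        up <- which((g$strand == "+" & pos < g$tss) |
                      (g$strand == "-" & pos > g$tss))
        if (length(up)) {
          d <- abs(g$tss[up] - pos)
          hit <- up[order(d, g$gene_id[up])][1]
          out$relation[i] <- "UPSTREAM_OF"
          out$distance[i] <- abs(g$tss[hit] - pos)
        }
      }
    }
    if (!is.null(hit)) {
      out$gene_id[i] <- g$gene_id[hit]
      out$gene_name[i] <- g$gene_name[hit]
      out$gene_strand[i] <- g$strand[hit]
      out$gene_biotype[i] <- g$biotype[hit]
      out$gene_tss[i] <- g$tss[hit]
    }
  }
  out
}
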