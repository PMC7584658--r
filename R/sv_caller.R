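#' Infer deletions and tandem duplications from classified segments
#'
#' Applies three rules to the per-sample, per-chromosome sequence of
#' copy-number states (input is expected merged and gap-filtered):
#' \describe{
#'   \item{HEMI_RUN}{a hemizygous-deletion segment whose neighbours, where
#'     present, are both not homozygous deletions, is a deletion (DEL)
#'     spanning the segment;}
#'   \item{HOM_IN_HEMI}{a homozygous-deletion segment whose neighbours both
#'     exist and are both hemizygous deletions is a deletion spanning the
#'     segment;}
#'   \item{GAIN_RUN}{a gained segment with no amplified neighbour is a tandem
#'     duplication (TDUP) spanning the segment.}
#' }
#' A missing neighbour (chromosome-terminal segment) satisfies "not HOMDEL"
#' and "not AMP" but cannot satisfy "is HEMIDEL". Breakpoints are the first
#' and last base of the event segment.
#'
#' @param segs classified segment data.frame with columns `sample`,
#'   `cancer_type`, `chrom`, `start`, `end`, `state`, sorted and
#'   non-overlapping per sample-chromosome.
#' @return data.frame of SV calls: `sample`, `cancer_type`, `chrom`, `bp1`,
#'   `bp2`, `sv_type` ("DEL"/"TDUP"), `rule`, `source_segments`.
#' @export
call_svs <- function(segs) {
  if (is.null(segs$state)) stop("segments must carry a 'state' column")
  empty <- data.frame(sample = character(), cancer_type = character(),
                      chrom = character(), bp1 = numeric(), bp2 = numeric(),
                      sv_type = character(), rule = character(),
                      source_segments = character(),
                      stringsAsFactors = FALSE)
  if (nrow(segs) == 0) return(empty)
  n <- nrow(segs)
  key <- paste(segs$sample, segs$chrom, sep = "\r")
  runs <- rle(key)
  if (anyDuplicated(runs$values) ||
      (n > 1 && any(diff(segs$start) <= 0 & key[-1] == key[-n]))) {
    stop("segments must be sorted by (sample, chromosome, start)",
         call. = FALSE)
  }
  first <- c(TRUE, key[-1] != key[-n])
  last <- c(first[-1], TRUE)
  s <- as.character(segs$state)
  left <- c(NA_character_, s[-n]); left[first] <- NA_character_
  right <- c(s[-1], NA_character_); right[last] <- NA_character_
  not_homdel <- function(x) is.na(x) | x != "HOMDEL"
  not_amp <- function(x) is.na(x) | x != "AMP"

  hemi <- s == "HEMIDEL" & not_homdel(left) & not_homdel(right)
  hom <- s == "HOMDEL" & !is.na(left) & !is.na(right) &
    left == "HEMIDEL" & right == "HEMIDEL"
  gain <- s == "GAIN" & not_amp(left) & not_amp(right)

  idx <- which(hemi | hom | gain)
  if (length(idx) == 0) return(empty)
  out <- data.frame(
    sample = segs$sample[idx],
    cancer_type = if (is.null(segs$cancer_type)) NA_character_ else
      segs$cancer_type[idx],
    chrom = segs$chrom[idx],
    bp1 = segs$start[idx],
    bp2 = segs$end[idx],
    sv_type = ifelse(gain[idx], "TDUP", "DEL"),
    rule = ifelse(gain[idx], "GAIN_RUN",
                  ifelse(hom[idx], "HOM_IN_HEMI", "HEMI_RUN")),
    source_segments = sprintf("%s:%s:%d-%d", segs$sample[idx],
                              segs$chrom[idx], as.integer(segs$start[idx]),
                              as.integer(segs$end[idx])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter SV calls by size and telomere/centromere proximity
#'
#' An SV is removed iff its span (`bp2 - bp1 + 1`) is smaller than
#' `sv_min_size`, or either breakpoint lies within `telocent_excl` bp of a
#' telomere (position 1 or the chromosome length) or of a centromere
#' boundary (a breakpoint inside the centromere interval has distance 0).
#' Row order is preserved; re-filtering is a no-op.
#'
#' @param svs SV call data.frame from [call_svs()].
#' @param genome genome reference from [read_genome_ref()].
#' @param config a [ps_config()].
#' @return filtered SV data.frame.
#' @export
filter_svs <- function(svs, genome, config = ps_config()) {
  if (nrow(svs) == 0) return(svs)
  check_genome_coverage(svs$chrom, genome)
  i <- match(svs$chrom, genome$chrom)
  len <- genome$length[i]
  cs <- genome$cen_start[i]
  ce <- genome$cen_end[i]
  excl <- function(bp) {
    d_tel <- pmin(bp - 1, len - bp)
    d_cen <- ifelse(bp >= cs & bp <= ce, 0,
                    pmin(abs(bp - cs), abs(bp - ce)))
    pmin(d_tel, d_cen) <= config$telocent_excl
  }
  keep <- (svs$bp2 - svs$bp1 + 1) >= config$sv_min_size &
    !excl(svs$bp1) & !excl(svs$bp2)
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cancer-type deletion / duplication counts
#'
#' @param svs SV call data.frame.
#' @return data.frame with `cancer_type`, `n_del`, `n_tdup` and
#'   `del_tdup_ratio` (`Inf` when a type has deletions but no duplications).
#' @export
summarize_by_cancer <- function(svs) {
  if (nrow(svs) == 0) {
    return(data.frame(cancer_type = character(), n_del = integer(),
                      n_tdup = integer(), del_tdup_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  ct <- factor(svs$cancer_type, levels = unique(svs$cancer_type))
  n_del <- tapply(svs$sv_type == "DEL", ct, sum)
  n_tdup <- tapply(svs$sv_type == "TDUP", ct, sum)
  out <- data.frame(cancer_type = levels(ct),
                    n_del = as.integer(n_del),
                    n_tdup = as.integer(n_tdup),
                    stringsAsFactors = FALSE)
  out$del_tdup_ratio <- ifelse(out$n_tdup == 0, Inf, out$n_del / out$n_tdup)
  rownames(out) <- NULL
  out
}

#' Write SV calls as TSV or minimal BEDPE
#'
#' @param svs SV call data.frame.
#' @param path output path.
#' @param format "tsv" (all columns) or "bedpe" (0-based half-open paired
#'   intervals, one per breakpoint).
#' @return `path`, invisibly.
#' @export
write_svs <- function(svs, path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bedpe <- data.frame(
      chrom1 = svs$chrom, start1 = svs$bp1 - 1, end1 = svs$bp1,
      chrom2 = svs$chrom, start2 = svs$bp2 - 1, end2 = svs$bp2,
      name = paste(svs$sample, svs$sv_type, sep = "_"),
      score = ".", strand1 = ".", strand2 = "."
    )
    utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
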