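#' Read a SEG file of segmented copy-number profiles
#'
#' Tolerant reader for tab-separated SEG files (the common SNP-array level-3
#' dialect): header required, column names matched case-insensitively across
#' the usual variants ("Sample"/"ID", "Segment_Mean"/"seg.mean",
#' "Num_Probes"/"num.mark", ...). Coordinates are 1-based inclusive.
#' Rows with a non-finite segment mean are dropped and their count reported;
#' chromosome names are normalized by stripping any "chr" prefix.
#'
#' @param path path to the SEG file.
#' @param labels optional named character vector mapping sample id to
#'   cancer-type label; unmapped samples get `NA`.
#' @return data.frame with columns `sample`, `cancer_type`, `chrom`, `start`,
#'   `end`, `num_probes`, `seg_mean`, sorted by (sample, chrom, start).
#' @examples
#' f <- tempfile(fileext = ".seg")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
#'              "S1\tchr1\t1\t1000\t10\t-0.5"), f)
#' read_seg(f)
#' @export
read_seg <- function(path, labels = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  nms <- names(raw)
  i_sample <- match_column(nms, c("sample", "id", "sampleid", "samplename"),
                           "sample", path)
  i_chrom <- match_column(nms, c("chromosome", "chrom", "chr"),
                          "chromosome", path)
  i_start <- match_column(nms, c("start", "locstart", "startposition",
                                 "chromstart"), "start", path)
  i_end <- match_column(nms, c("end", "locend", "endposition", "chromend"),
                        "end", path)
  i_mean <- match_column(nms, c("segmentmean", "segmean", "mean",
                                "log2ratio"), "segment mean", path)
  i_np <- match_column(nms, c("numprobes", "nummark", "nummarkers",
                              "numsnps", "probes"), "num_probes", path,
                       required = FALSE)

  df <- data.frame(
    sample = as.character(raw[[i_sample]]),
    chrom = norm_chrom(raw[[i_chrom]]),
    start = as.numeric(raw[[i_start]]),
    end = as.numeric(raw[[i_end]]),
    num_probes = if (is.na(i_np)) NA_real_ else as.numeric(raw[[i_np]]),
    seg_mean = suppressWarnings(as.numeric(raw[[i_mean]])),
    stringsAsFactors = FALSE
  )

  bad_coord <- which(!is.finite(df$start) | !is.finite(df$end) |
                       df$start > df$end)
  if (length(bad_coord)) {
    stop(sprintf("invalid segment coordinates (start > end or missing) at line %d of '%s'",
                 bad_coord[1] + 1L, path), call. = FALSE)
  }
  if (any(!nzchar(df$chrom))) {
    stop("empty chromosome name in '", path, "'", call. = FALSE)
  }

  drop <- !is.finite(df$seg_mean)
  if (any(drop)) {
    message(sum(drop), " segment(s) with non-finite seg_mean dropped from '",
            basename(path), "'")
    df <- df[!drop, , drop = FALSE]
  }

  df$cancer_type <- if (is.null(labels)) NA_character_ else
    unname(labels[df$sample])
  df <- df[, c("sample", "cancer_type", "chrom", "start", "end",
               "num_probes", "seg_mean")]
  df <- sort_segments(df)
  rownames(df) <- NULL
  df
}

#' Write segments in canonical SEG format
#'
#' @param segs segment data.frame as produced by [read_seg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  out <- data.frame(Sample = segs$sample, Chromosome = segs$chrom,
                    Start = segs$start, End = segs$end,
                    Num_Probes = segs$num_probes,
                    Segment_Mean = segs$seg_mean)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Copy-number state names
#'
#' The five discrete states, in increasing copy-number order.
#' @return character vector of the five state names.
#' @export
cn_states <- function() c("HOMDEL", "HEMIDEL", "NEUTRAL", "GAIN", "AMP")

#' Classify log2 segment means into five copy-number states
#'
#' With the default thresholds: HOMDEL iff x < -1; HEMIDEL iff -1 <= x <
#' -0.2; NEUTRAL iff -0.2 <= x < 0.3; GAIN iff 0.3 <= x < 0.7; AMP iff x >=
#' 0.7. Each bin is closed on the left and open on the right, so the five
#' bins partition the real line.
#'
#' @param seg_mean numeric vector of finite log2 ratios.
#' @param config a [ps_config()] holding the four cut points.
#' @return ordered factor with levels `cn_states()`.
#' @examples
#' classify_state(c(-1.5, -1, 0, 0.7))
#' @export
classify_state <- function(seg_mean, config = ps_config()) {
  if (any(!is.finite(seg_mean))) {
    stop("seg_mean must be finite for state classification", call. = FALSE)
  }
  breaks <- c(-Inf, config$homdel_max, config$hemidel_max,
              config$neutral_max, config$gain_max, Inf)
  cut(seg_mean, breaks = breaks, labels = cn_states(),
      right = FALSE, ordered_result = TRUE)
}

#' Attach copy-number states to a segment table
#'
#' @param segs segment data.frame (needs a `seg_mean` column).
#' @param config a [ps_config()].
#' @return `segs` with a `state` column appended.
#' @export
classify_segments <- function(segs, config = ps_config()) {
  segs$state <- classify_state(segs$seg_mean, config)
  segs
}

# apply `fun` per (sample, chromosome) group and rbind, preserving sort order
by_sample_chrom <- function(segs, fun) {
  if (nrow(segs) == 0) return(segs)
  segs <- sort_segments(segs)
  key <- paste(segs$sample, segs$chrom, sep = "\r")
  parts <- split(segs, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(parts, fun))
  rownames(out) <- NULL
  out
}

#' Merge nearby same-state segments
#'
#' Consecutive segments of one sample-chromosome that share a copy-number
#' state and are separated by a gap smaller than `merge_gap_max` are replaced
#' by a single segment spanning both; the merged amplitude is the
#' probe-count-weighted mean (unweighted when probe counts are absent).
#' Merging is transitive within a chain and idempotent.
#'
#' @param segs classified segment data.frame (must carry `state`).
#' @param config a [ps_config()].
#' @return merged segment data.frame, sorted.
#' @export
merge_segments <- function(segs, config = ps_config()) {
  if (is.null(segs$state)) stop("segments must be classified before merging")
  by_sample_chrom(segs, function(g) {
    n <- nrow(g)
    if (n > 1 && any(g$start[-1] <= g$end[-n])) {
      stop(sprintf("overlapping segments in sample %s chromosome %s",
                   g$sample[1], g$chrom[1]), call. = FALSE)
    }
    if (n == 1) return(g)
    gap <- g$start[-1] - g$end[-n] - 1
    brk <- c(TRUE, as.character(g$state[-1]) != as.character(g$state[-n]) |
               gap >= config$merge_gap_max)
    run <- cumsum(brk)
    merged <- lapply(split(seq_len(n), run), function(idx) {
      gi <- g[idx, , drop = FALSE]
      w <- gi$num_probes
      m <- if (all(is.finite(w))) {
        sum(gi$seg_mean * w) / sum(w)
      } else {
        mean(gi$seg_mean)
      }
      out <- gi[1, , drop = FALSE]
      out$end <- max(gi$end)
      out$num_probes <- if (all(is.finite(w))) sum(w) else NA_real_
      out$seg_mean <- m
      out
    })
    do.call(rbind, merged)
  })
}

#' Drop segments flanking large no-data gaps
#'
#' A no-data region is the interval between two consecutive segment records
#' of one sample-chromosome. Every segment immediately flanking a gap
#' strictly larger than `nodata_gap_min` is removed; a gap of exactly the
#' threshold is tolerated, and chromosome ends never count as no-data
#' regions.
#'
#' @param segs segment data.frame, sorted.
#' @param config a [ps_config()].
#' @return filtered segment data.frame (a subset of the input rows).
#' @export
filter_gap_adjacent <- function(segs, config = ps_config()) {
  by_sample_chrom(segs, function(g) {
    n <- nrow(g)
    if (n < 2) return(g)
    gap <- g$start[-1] - g$end[-n] - 1
    big <- gap > config$nodata_gap_min
    drop <- c(big, FALSE) | c(FALSE, big)
    g[!drop, , drop = FALSE]
  })
}

#' Read a genome reference table
#'
#' BED-like tab-separated file with header columns `chrom`, `length`,
#' `cen_start`, `cen_end` (1-based inclusive centromere interval). Telomeres
#' are implicitly position 1 and the chromosome length.
#'
#' @param path path to the reference TSV.
#' @return data.frame with one row per chromosome.
#' @export
read_genome_ref <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  nms <- names(raw)
  ref <- data.frame(
    chrom = norm_chrom(raw[[match_column(nms, c("chrom", "chromosome", "chr"),
                                         "chrom", path)]]),
    length = as.numeric(raw[[match_column(nms, c("length", "size", "chromlength"),
                                          "length", path)]]),
    cen_start = as.numeric(raw[[match_column(nms, c("censtart", "centromerestart"),
                                             "cen_start", path)]]),
    cen_end = as.numeric(raw[[match_column(nms, c("cenend", "centromereend"),
                                           "cen_end", path)]]),
    stringsAsFactors = FALSE
  )
  validate_genome_ref(ref)
  ref
}

validate_genome_ref <- function(ref) {
  stopifnot(is.data.frame(ref),
            all(c("chrom", "length", "cen_start", "cen_end") %in% names(ref)))
  if (anyDuplicated(ref$chrom)) stop("duplicated chromosome in genome reference")
  bad <- ref$cen_start < 1 | ref$cen_end > ref$length |
    ref$cen_start > ref$cen_end
  if (any(bad)) {
    stop("centromere interval outside [1, length] for chromosome ",
         ref$chrom[which(bad)[1]], call. = FALSE)
  }
  invisible(ref)
}

#' Write a genome reference table
#'
#' @param ref genome reference data.frame ([read_genome_ref()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_ref <- function(ref, path) {
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# every chromosome used by `chroms` must exist in the reference
check_genome_coverage <- function(chroms, genome) {
  missing <- setdiff(unique(chroms), genome$chrom)
  if (length(missing)) {
    stop("chromosome(s) absent from genome reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
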