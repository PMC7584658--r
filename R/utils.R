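`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix; all internal coordinates are keyed by the
#' bare chromosome name ("1", ..., "22", "X", "Y").
#'
#' @param x character vector of chromosome names.
#' @return character vector without "chr" prefix.
#' @export
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

# sortable key: autosomes numerically, then X/Y/others lexicographically
chrom_key <- function(x) {
  n <- suppressWarnings(as.integer(x))
  ifelse(is.na(n), paste0("Z_", x), sprintf("A_%09d", n))
}

sort_segments <- function(df) {
  df[order(df$sample, chrom_key(df$chrom), df$start, df$end), , drop = FALSE]
}

# canonical column-name form used by the tolerant TSV readers
canon_names <- function(x) gsub("[._ -]", "", tolower(x))

match_column <- function(nms, aliases, label, path, required = TRUE) {
  hit <- which(canon_names(nms) %in% aliases)
  if (length(hit) == 0) {
    if (required) {
      stop(sprintf("file '%s' is missing a mandatory column: %s", path, label),
           call. = FALSE)
    }
    return(NA_integer_)
  }
  hit[1]
}
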