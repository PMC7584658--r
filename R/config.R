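#' Pipeline configuration
#'
#' Collects every numeric threshold used by the screen. The defaults are the
#' values the method was designed with: the four log2-ratio cut points
#' defining the five copy-number states, the 100 kb merge and no-data
#' distances, the 15 kb minimum event size, the 2 Mb telomere/centromere
#' exclusion, the 200 kb upstream window for promoter juxtaposition, the
#' 2-fold stronger-promoter gate, recurrence at n >= 2 and FDR control at
#' 10%.
#'
#' @param homdel_max log2 ratio below which a segment is a homozygous
#'   deletion (default -1).
#' @param hemidel_max upper bound (exclusive) of the hemizygous-deletion bin
#'   (default -0.2).
#' @param neutral_max upper bound (exclusive) of the copy-neutral bin
#'   (default 0.3).
#' @param gain_max upper bound (exclusive) of the gain bin; at or above this
#'   a segment is an amplification (default 0.7).
#' @param merge_gap_max adjacent same-state segments separated by less than
#'   this many bp are merged (default 100,000).
#' @param nodata_gap_min segments flanking an inter-segment gap strictly
#'   larger than this are dropped as unreliable (default 100,000).
#' @param sv_min_size minimum SV span in bp (default 15,000).
#' @param telocent_excl breakpoints within this distance of a telomere or
#'   centromere boundary are excluded (default 2,000,000).
#' @param upstream_window maximum breakpoint-to-TSS distance for the
#'   promoter-to-upstream-region case, bp (default 200,000).
#' @param stronger_promoter_fold linear fold difference in median expression
#'   required to call the 5' promoter "stronger" in the screen (default 2).
#' @param recurrence_min minimum number of distinct affected samples for a
#'   gene pair to be screened (default 2).
#' @param fdr_level Benjamini-Hochberg significance level (default 0.10).
#' @param wgs_match_tol per-breakpoint tolerance when matching against WGS SV
#'   calls, bp (default 100,000).
#' @param fisher_strength_cut,fisher_induction_cut cut points (log2) used to
#'   dichotomize promoter-strength difference and induction in the quadrant
#'   association test (defaults 0).
#' @param welch use Welch's t-test instead of the pooled-variance Student's
#'   t-test in the screen (default FALSE).
#' @param match_strategy WGS matching strategy: breakpoint proximity
#'   (default) or reciprocal overlap.
#' @param recip_overlap_min minimum reciprocal overlap for the "overlap"
#'   strategy (default 0.5).
#'
#' @return a named list of class `ps_config`.
#' @examples
#' cfg <- ps_config()
#' cfg$sv_min_size
#' @export
ps_config <- function(homdel_max = -1,
                      hemidel_max = -0.2,
                      neutral_max = 0.3,
                      gain_max = 0.7,
                      merge_gap_max = 1e5,
                      nodata_gap_min = 1e5,
                      sv_min_size = 15000,
                      telocent_excl = 2e6,
                      upstream_window = 2e5,
                      stronger_promoter_fold = 2,
                      recurrence_min = 2,
                      fdr_level = 0.10,
                      wgs_match_tol = 1e5,
                      fisher_strength_cut = 0,
                      fisher_induction_cut = 0,
                      welch = FALSE,
                      match_strategy = c("breakpoint", "overlap"),
                      recip_overlap_min = 0.5) {
  cfg <- list(
    homdel_max = homdel_max, hemidel_max = hemidel_max,
    neutral_max = neutral_max, gain_max = gain_max,
    merge_gap_max = merge_gap_max, nodata_gap_min = nodata_gap_min,
    sv_min_size = sv_min_size, telocent_excl = telocent_excl,
    upstream_window = upstream_window,
    stronger_promoter_fold = stronger_promoter_fold,
    recurrence_min = recurrence_min, fdr_level = fdr_level,
    wgs_match_tol = wgs_match_tol,
    fisher_strength_cut = fisher_strength_cut,
    fisher_induction_cut = fisher_induction_cut,
    welch = isTRUE(welch),
    match_strategy = match.arg(match_strategy),
    recip_overlap_min = recip_overlap_min
  )
  class(cfg) <- "ps_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("homdel_max", "hemidel_max", "neutral_max", "gain_max")) {
    if (!num1(cfg[[f]])) stop("config field '", f, "' must be a finite number")
  }
  if (!(cfg$homdel_max < cfg$hemidel_max &&
        cfg$hemidel_max < cfg$neutral_max &&
        cfg$neutral_max < cfg$gain_max)) {
    stop("state thresholds must satisfy homdel_max < hemidel_max < neutral_max < gain_max")
  }
  for (f in c("merge_gap_max", "nodata_gap_min", "sv_min_size",
              "telocent_excl", "wgs_match_tol")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive number of bp")
    }
  }
  if (!num1(cfg$upstream_window) || cfg$upstream_window < 0) {
    stop("config field 'upstream_window' must be a non-negative number of bp")
  }
  if (!num1(cfg$stronger_promoter_fold) || cfg$stronger_promoter_fold <= 0) {
    stop("config field 'stronger_promoter_fold' must be a positive fold")
  }
  if (!num1(cfg$fdr_level) || cfg$fdr_level <= 0 || cfg$fdr_level > 1) {
    stop("config field 'fdr_level' must be a proportion in (0, 1]")
  }
  if (!num1(cfg$recurrence_min) || cfg$recurrence_min < 1) {
    stop("config field 'recurrence_min' must be >= 1")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys map one-to-one onto the arguments of [ps_config()]; absent keys keep
#' their defaults, unknown keys are an error.
#'
#' @param path path to a YAML key-value file.
#' @return a `ps_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(ps_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(ps_config, vals)
}

#' @export
print.ps_config <- function(x, ...) {
  cat("promoter-substitution pipeline configuration\n")
  for (f in setdiff(names(x), "match_strategy")) {
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  }
  cat(sprintf("  %-24s %s\n", "match_strategy", x$match_strategy))
  invisible(x)
}
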