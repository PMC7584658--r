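#' Match CNA-inferred SVs against WGS-derived SV calls
#'
#' With the default "breakpoint" strategy, a CNA SV matches a WGS SV of the
#' same sample and chromosome when both breakpoint offsets are at most
#' `wgs_match_tol` bp. Assignment is greedy one-to-one by smallest total
#' offset, ties resolved by WGS input order. The "overlap" strategy instead
#' requires reciprocal overlap of at least `recip_overlap_min` and assigns
#' greedily by largest reciprocal overlap.
#'
#' @param cna_svs data.frame of CNA-inferred SVs (`sample`, `chrom`, `bp1`,
#'   `bp2`, `sv_type`).
#' @param wgs_svs data.frame of WGS SVs (same columns; `sv_type` may also be
#'   named `type`).
#' @param config a [ps_config()].
#' @param tol per-breakpoint tolerance in bp; defaults to
#'   `config$wgs_match_tol`.
#' @return list with `matches` (one row per matched CNA SV: indices into both
#'   inputs, per-breakpoint offsets, `coherent` = same DEL/TDUP class) and
#'   `summary` (`n_cna`, `n_wgs`, `n_matched`, `frac_matched`,
#'   `frac_coherent`).
#' @export
match_svs <- function(cna_svs, wgs_svs, config = ps_config(),
                      tol = config$wgs_match_tol) {
  if (!is.null(wgs_svs$type) && is.null(wgs_svs$sv_type)) {
    wgs_svs$sv_type <- wgs_svs$type
  }
  matches <- data.frame(cna_idx = integer(), wgs_idx = integer(),
                        bp1_offset = numeric(), bp2_offset = numeric(),
                        coherent = logical(), stringsAsFactors = FALSE)
  n_cna <- nrow(cna_svs)
  n_wgs <- nrow(wgs_svs)
  if (n_cna > 0 && n_wgs > 0) {
    wkey <- paste(wgs_svs$sample, wgs_svs$chrom, sep = "\r")
    widx_by_key <- split(seq_len(n_wgs), wkey)
    cand <- vector("list", n_cna)
    for (i in seq_len(n_cna)) {
      j <- widx_by_key[[paste(cna_svs$sample[i], cna_svs$chrom[i], sep = "\r")]]
      if (is.null(j)) next
      d1 <- abs(cna_svs$bp1[i] - wgs_svs$bp1[j])
      d2 <- abs(cna_svs$bp2[i] - wgs_svs$bp2[j])
      if (config$match_strategy == "breakpoint") {
        ok <- d1 <= tol & d2 <= tol
        score <- d1 + d2  # smaller is better
      } else {
        inter <- pmin(cna_svs$bp2[i], wgs_svs$bp2[j]) -
          pmax(cna_svs$bp1[i], wgs_svs$bp1[j]) + 1
        ro <- pmin(inter / (cna_svs$bp2[i] - cna_svs$bp1[i] + 1),
                   inter / (wgs_svs$bp2[j] - wgs_svs$bp1[j] + 1))
        ok <- inter > 0 & ro >= config$recip_overlap_min
        score <- -ro  # larger overlap is better
      }
      if (!any(ok)) next
      cand[[i]] <- data.frame(cna_idx = i, wgs_idx = j[ok],
                              bp1_offset = d1[ok], bp2_offset = d2[ok],
                              score = score[ok])
    }
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand$score, cand$wgs_idx), , drop = FALSE]
      used_cna <- logical(n_cna)
      used_wgs <- logical(n_wgs)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        ci <- cand$cna_idx[k]; wi <- cand$wgs_idx[k]
        if (!used_cna[ci] && !used_wgs[wi]) {
          keep[k] <- TRUE
          used_cna[ci] <- TRUE
          used_wgs[wi] <- TRUE
        }
      }
      m <- cand[keep, , drop = FALSE]
      matches <- data.frame(
        cna_idx = m$cna_idx, wgs_idx = m$wgs_idx,
        bp1_offset = m$bp1_offset, bp2_offset = m$bp2_offset,
        coherent = cna_svs$sv_type[m$cna_idx] == wgs_svs$sv_type[m$wgs_idx],
        stringsAsFactors = FALSE
      )
      matches <- matches[order(matches$cna_idx), , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  n_matched <- nrow(matches)
  list(
    matches = matches,
    summary = list(
      n_cna = n_cna, n_wgs = n_wgs, n_matched = n_matched,
      frac_matched = if (n_cna == 0) NA_real_ else n_matched / n_cna,
      frac_coherent = if (n_matched == 0) NA_real_ else
        mean(matches$coherent)
    )
  )
}
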