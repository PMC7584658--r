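# Independent oracles used to cross-check the implementation.  Each is a
# literal, brute-force restatement of the corresponding rule, kept free of
# any code shared with the package internals.

# five-bin state classification as a chain of explicit inequalities
oracle_classify <- function(x, cfg = ps_config()) {
  vapply(x, function(v) {
    if (v < cfg$homdel_max) "HOMDEL"
    else if (v < cfg$hemidel_max) "HEMIDEL"
    else if (v < cfg$neutral_max) "NEUTRAL"
    else if (v < cfg$gain_max) "GAIN"
    else "AMP"
  }, character(1))
}

# one-pass literal evaluation of the three SV rules over a state sequence;
# returns a data.frame of (index, sv_type, rule)
oracle_call_svs <- function(states) {
  n <- length(states)
  rows <- list()
  for (i in seq_len(n)) {
    l <- if (i > 1) states[i - 1] else NA_character_
    r <- if (i < n) states[i + 1] else NA_character_
    s <- states[i]
    hit <- NULL
    if (s == "HEMIDEL" &&
        (is.na(l) || l != "HOMDEL") && (is.na(r) || r != "HOMDEL")) {
      hit <- c("DEL", "HEMI_RUN")
    } else if (s == "HOMDEL" && !is.na(l) && !is.na(r) &&
               l == "HEMIDEL" && r == "HEMIDEL") {
      hit <- c("DEL", "HOM_IN_HEMI")
    } else if (s == "GAIN" &&
               (is.na(l) || l != "AMP") && (is.na(r) || r != "AMP")) {
      hit <- c("TDUP", "GAIN_RUN")
    }
    if (!is.null(hit)) {
      rows[[length(rows) + 1]] <- data.frame(index = i, sv_type = hit[1],
                                             rule = hit[2],
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(index = integer(), sv_type = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# junction-construction oracle for promoter substitution.  A deletion joins
# ...(left of bp1) | (right of bp2)...; a tandem duplication joins
# ...(up to bp2) | (from bp1)....  We follow transcription across the
# junction on each strand and record the donor/acceptor it implies.
oracle_ps <- function(sv_type, bp1, bp2, genes, window) {
  lbp <- if (sv_type == "DEL") bp1 else bp2  # breakpoint ending the left piece
  rbp <- if (sv_type == "DEL") bp2 else bp1  # breakpoint starting the right piece
  coding <- genes[genes$biotype == "coding", , drop = FALSE]
  at <- function(p) coding[coding$start <= p & p <= coding$end, , drop = FALSE]
  gl <- at(lbp)
  gr <- at(rbp)
  stopifnot(nrow(gl) <= 1, nrow(gr) <= 1)

  plus_flow <- function() {
    if (nrow(gl) == 0 || gl$strand != "+") return(NULL)
    donor <- gl
    if (nrow(gr) > 0) {           # other breakpoint genic: fusion or nothing
      if (gr$strand != "+" || gr$gene_id == donor$gene_id) return(NULL)
      return(list(category = "FUSION", gene5 = donor$gene_id,
                  gene3 = gr$gene_id))
    }
    # readthrough: first plus-strand coding TSS downstream of the junction
    cand <- coding[coding$strand == "+" & coding$start > rbp, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    g3 <- cand[which.min(cand$start), ]
    d <- g3$start - rbp
    if (d > window || g3$gene_id == donor$gene_id) return(NULL)
    list(category = "UPSTREAM", gene5 = donor$gene_id, gene3 = g3$gene_id)
  }
  minus_flow <- function() {
    if (nrow(gr) == 0 || gr$strand != "-") return(NULL)
    donor <- gr
    if (nrow(gl) > 0) {
      if (gl$strand != "-" || gl$gene_id == donor$gene_id) return(NULL)
      return(list(category = "FUSION", gene5 = donor$gene_id,
                  gene3 = gl$gene_id))
    }
    cand <- coding[coding$strand == "-" & coding$end < lbp, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    g3 <- cand[which.max(cand$end), ]
    d <- lbp - g3$end
    if (d > window || g3$gene_id == donor$gene_id) return(NULL)
    list(category = "UPSTREAM", gene5 = donor$gene_id, gene3 = g3$gene_id)
  }
  plus_flow() %||% minus_flow()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher p by direct hypergeometric enumeration over the
# margin-conditioned support
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# two-sided exact rank-sum p by enumeration of all group assignments
oracle_wilcox <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(i) sum(r[i]))
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up computed by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
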