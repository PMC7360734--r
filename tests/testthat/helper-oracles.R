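# Independent brute-force oracles used to check the optimized implementations.
# All oracles work on plain data.frames with 1-based closed coordinates
# (chrom, start, end) and deliberately use nothing from the package's own
# overlap/scan machinery.

# all-pairs overlap counter: (n queries hitting any subject, n subjects hit)
oracle_count_overlaps <- function(q, s) {
  hit_q <- logical(nrow(q))
  hit_s <- logical(nrow(s))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j] &&
          q$start[i] <= s$end[j] && s$start[j] <= q$end[i]) {
        hit_q[i] <- TRUE
        hit_s[j] <- TRUE
      }
    }
  }
  c(n_query_hit = sum(hit_q), n_elements_hit = sum(hit_s))
}

# gap between nearest ends; 0 on overlap or adjacency (1-based closed)
oracle_distance <- function(s1, e1, s2, e2) {
  if (s1 <= e2 && s2 <= e1) return(0)
  if (s1 > e2) s1 - e2 - 1 else s2 - e1 - 1
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration: sum of
# all table probabilities not exceeding that of the observed table
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# literal count-the-tails two-tailed add-one empirical p
oracle_empirical_p <- function(observed, null_values) {
  n <- length(null_values)
  min(1, 2 * min((1 + sum(null_values >= observed)) / (n + 1),
                 (1 + sum(null_values <= observed)) / (n + 1)))
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1]]])), collapse = "")
}

# naive per-window PWM log2-odds scores on the forward strand; NA where the
# window holds a non-ACGT base
oracle_pwm_scores <- function(seq, pwm, pseudo = 1e-4) {
  m <- pwm$matrix
  m[m <= 0] <- pseudo
  sm <- log2(m / pwm$background)
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(sm)
  nw <- length(bases) - L + 1
  out <- rep(NA_real_, max(nw, 0))
  for (i in seq_len(nw)) {
    w <- match(bases[i:(i + L - 1)], rownames(sm))
    if (anyNA(w)) next
    out[i] <- sum(sm[cbind(w, seq_len(L))])
  }
  out
}

# naive Hamming guide matcher: does any guide match either strand of the
# sequence with at most k mismatches? ambiguous bases always mismatch
oracle_guide_hits <- function(guides, seq, k) {
  s <- strsplit(toupper(seq), "")[[1]]
  for (g in guides) {
    for (pat in c(g, oracle_revcomp(g))) {
      p <- strsplit(pat, "")[[1]]
      L <- length(p)
      if (L > length(s)) next
      for (off in 0:(length(s) - L)) {
        mm <- sum(s[off + seq_len(L)] != p |
                    !s[off + seq_len(L)] %in% names(ORACLE_COMP))
        if (mm <= k) return(TRUE)
      }
    }
  }
  FALSE
}

# random small interval set on a toy genome (1-based closed data.frame)
random_intervals_df <- function(n, chroms = c(chrA = 1000, chrB = 800),
                                max_len = 60) {
  chrom <- sample(names(chroms), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chroms[[chrom[i]]] - len[i] + 1L, 1L), integer(1))
  data.frame(chrom = chrom, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
}
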