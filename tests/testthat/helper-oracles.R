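# Independent oracles used to check the package implementations. These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the functions they validate.

# Step-up BH by the definitional formula: adj_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Exact P(|A intersect B| >= observed) for two uniform without-replacement
# draws of sizes s1, s2 from a universe of size m, by full enumeration of
# all subset pairs (feasible for m <= 8).
exact_overlap_p2 <- function(m, s1, s2, observed) {
  subs1 <- utils::combn(m, s1, simplify = FALSE)
  subs2 <- utils::combn(m, s2, simplify = FALSE)
  hits <- 0L
  total <- 0L
  for (a in subs1) {
    for (b in subs2) {
      total <- total + 1L
      if (length(intersect(a, b)) >= observed) hits <- hits + 1L
    }
  }
  hits / total
}

# One-sided hypergeometric upper tail P(X >= k) by direct summation of the
# pmf written with log-binomial coefficients.
hyper_tail_oracle <- function(k, K, M, n) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  i <- i[(n - i) <= (M - K)]
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(M - K, n - i) - lchoose(M, n)))
}

# Brute-force fragment x gene overlap: all-pairs interval arithmetic on
# 0-based half-open fragments vs 1-based inclusive gene bodies.
frag_gene_overlap_oracle <- function(fragments, genes) {
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    for (j in seq_len(nrow(genes))) {
      if (fragments$chrom[i] != genes$chrom[j]) next
      g0_start <- genes$start[j] - 1L  # 0-based half-open gene body
      g0_end <- genes$end[j]
      if (max(fragments$start[i], g0_start) < min(fragments$end[i], g0_end)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fragments$chrom[i], frag_id = fragments$frag_id[i],
          gene_id = genes$gene_id[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), frag_id = integer(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$frag_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
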