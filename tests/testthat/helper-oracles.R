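# Independent brute-force oracles used to validate the implementation paths.

# hypergeometric upper tail by explicit log-space summation
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up by direct enumeration
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  adj
}

# exhaustive evaluation of all cut points of a descending sort;
# returns the same structure as split_bright_dim
oracle_gap_split <- function(values, log = FALSE) {
  v <- if (log) base::log(values) else values
  n <- length(v)
  ord <- order(v, decreasing = TRUE)
  s <- v[ord]
  gap_at <- vapply(seq_len(n - 1L), function(c) s[c] - s[c + 1L], numeric(1))
  best <- which(gap_at == max(gap_at))
  if (max(gap_at) == 0 || length(best) > 1L)
    return(list(accepted = FALSE, labels = NULL))
  labels <- character(n)
  labels[ord[seq_len(best)]] <- "bright"
  labels[ord[(best + 1L):n]] <- "dim"
  list(accepted = TRUE, labels = labels)
}

# exhaustive per-slice maximum over the full field (profile oracle for a
# stack containing a single object under the ROI)
oracle_slicewise_max <- function(stack) {
  apply(stack, 3, max)
}

# load the published reference list of inversely regulated genes
reference_inverse_table <- function() {
  path <- system.file("extdata", "gec_inverse_genes.tsv", package = "gecpop")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
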