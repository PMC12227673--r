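# Independent oracles used to check the package's implementations.  These
# deliberately use brute force (exhaustive enumeration) rather than the
# package's own algorithms.

# Exact label distribution by enumerating all 2^m presence patterns of the
# m codebook tags.  Feasible for m <= ~15.
oracle_label_probs <- function(cb, lambda) {
  sigs <- cb$tags$signature
  m <- length(sigs)
  stopifnot(m <= 15L, length(lambda) == m)
  p <- -expm1(-lambda)
  null_label <- strrep("0", cb$channels)
  acc <- numeric(0)
  for (mask in 0:(2L^m - 1L)) {
    members <- which(bitwAnd(mask, 2L^(seq_len(m) - 1L)) != 0L)
    prob <- prod(c(p[members], 1 - p[setdiff(seq_len(m), members)]))
    lab <- if (length(members) == 0L) null_label else
      signature_union(sigs[members])
    acc[lab] <- (if (is.na(acc[lab])) 0 else acc[lab]) + prob
  }
  acc[sort(names(acc), method = "radix")]
}

# Random small codebook: C channels, up to n_tags signatures drawn from the
# full 1..C-site enumeration.
random_codebook <- function(channels, n_tags) {
  full <- enumerate_codebook(channels, 2, channels)
  keep <- sort(sample(nrow(full$tags), min(n_tags, nrow(full$tags))))
  codebook(full$tags$signature[keep])
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to the two groups (no ties assumed).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  idx <- utils::combn(length(pooled), n1)
  w_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
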