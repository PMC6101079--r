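# Independent brute-force references used to check the package implementation.

# Naive O(N^2) BH adjustment: q(i) = min over ranks j >= i of N * p_(j) / j,
# capped at 1, mapped back to input order.
naive_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(n * ps[i:n] / (i:n)))
  }, numeric(1))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Naive BH step-up acceptance count.
naive_accept_count <- function(p, alpha) {
  n <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(n) * alpha / n)
  if (length(ok)) max(ok) else 0L
}

# Brute-force bin-tail p-value: count decoy scores in the score's bin or any
# higher bin, directly from the raw scores (no histogram reuse).
brute_pvalue <- function(decoy_scores, score, bin_width, lo = 0, hi = 1) {
  idx <- function(s) {
    min(floor((s - lo) / bin_width) + 1, ceiling((hi - lo) / bin_width))
  }
  k_hat <- idx(score)
  ks <- vapply(decoy_scores, idx, numeric(1))
  sum(ks >= k_hat) / length(decoy_scores)
}

# Small score-table fixture.
toy_scores <- function(target = c(0.9, 0.5), decoy = c(0.1, 0.2)) {
  tibble::tibble(
    accession = c(
      paste0("T", seq_along(target), recycle0 = TRUE),
      paste0("DECOY_T", seq_along(decoy), recycle0 = TRUE)
    ),
    score = c(target, decoy),
    decoy = rep(c(FALSE, TRUE), c(length(target), length(decoy)))
  )
}

# Per-bin generating coefficients whose CDFs are monotone for any feature in
# [0, 1]: intercepts follow the logit of an increasing base CDF whose spacing
# (>= 4/K) exceeds the per-bin slope variation (2/K), so eta_k is increasing
# in k for every r in [0, 1].
monotone_beta <- function(K) {
  k <- seq_len(K - 1)
  cbind(qlogis(k / K), -3 + 2 * k / K)
}
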