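#' 10-bin protein-score histogram of a sample
#'
#' Bins the target (non-decoy) protein scores of a sample into `n_bins`
#' equal-width bins on a fixed shared domain and normalizes the counts to
#' probabilities. The same half-open bin convention as [build_null()] is
#' used. All samples share the domain `[lo, hi]` so that histograms of
#' different samples are directly comparable in [kl_divergence()].
#'
#' @param scores A score tibble (columns `accession`, `score`, `decoy`).
#' @param n_bins Number of bins; default 10.
#' @param lo,hi Shared domain; default `[0, 1]`.
#' @return A `score_histogram` object: list with `probs` (length `n_bins`,
#'   sums to 1), `lo`, `hi`, `n` (number of scores used).
#' @export
score_histogram <- function(scores, n_bins = 10, lo = 0, hi = 1) {
  check_scores(scores)
  stopifnot(n_bins >= 2)
  targets <- scores$score[!scores$decoy]
  if (length(targets) == 0L) {
    stop("sample has no target (non-decoy) entries", call. = FALSE)
  }
  w <- (hi - lo) / n_bins
  k <- bin_index(targets, bin_width = w, lo = lo, hi = hi)
  counts <- tabulate(k, nbins = n_bins)
  structure(
    list(probs = counts / length(targets), lo = lo, hi = hi,
         n = length(targets)),
    class = "score_histogram"
  )
}

#' @export
print.score_histogram <- function(x, ...) {
  cat("<score_histogram> ", length(x$probs), " bins on [", x$lo, ", ", x$hi,
    "], n = ", x$n, "\n",
    sep = ""
  )
  print(round(x$probs, 4))
  invisible(x)
}

#' Kullback-Leibler divergence between two score histograms
#'
#' `D(P || Q) = sum_k P_k log(P_k / Q_k)`, the non-symmetric similarity
#' measure between a sample's score histogram and the reference sample's.
#' Because empty bins make the ratio undefined, a pseudo-probability `eps`
#' is added to every bin of both histograms, which are then renormalized;
#' with identical inputs the smoothed histograms coincide and D is exactly 0.
#'
#' @param P,Q `score_histogram` objects (or bare probability vectors) with
#'   identical bin structure. D measures P against Q (Q as reference).
#' @param eps Smoothing pseudo-probability; default 1e-9.
#' @param base Logarithm base; default natural log (D in nats). Only relative
#'   comparisons matter downstream, so the base is a convention.
#' @return Non-negative scalar; 0 iff the smoothed histograms are equal.
#' @examples
#' a <- list(probs = c(0.5, 0.5))
#' b <- list(probs = c(0.25, 0.75))
#' kl_divergence(a, b)
#' @export
kl_divergence <- function(P, Q, eps = 1e-9, base = exp(1)) {
  p <- if (is.list(P)) P$probs else P
  q <- if (is.list(Q)) Q$probs else Q
  if (length(p) != length(q)) {
    stop("histograms have different numbers of bins", call. = FALSE)
  }
  if (is.list(P) && is.list(Q) &&
    !is.null(P$lo) && !is.null(Q$lo) &&
    (P$lo != Q$lo || P$hi != Q$hi)) {
    stop("histograms are defined on different domains", call. = FALSE)
  }
  stopifnot(eps > 0)
  ps <- (p + eps) / sum(p + eps)
  qs <- (q + eps) / sum(q + eps)
  sum(ps * (log(ps / qs) / log(base)))
}

#' Extract the per-sample feature vector
#'
#' The current feature set has a single entry (J = 1): the KL divergence of
#' the sample's 10-bin protein-score histogram to the reference sample's
#' histogram. Decoy entries are excluded — the feature describes the sample's
#' identification result, not its decoys.
#'
#' @param scores A score tibble for the sample.
#' @param reference A score tibble for the reference sample, or a
#'   precomputed `score_histogram`.
#' @param n_bins Number of histogram bins; default 10.
#' @inheritParams kl_divergence
#' @return A one-row tibble with column `r_1` (KL divergence, nats).
#' @export
extract_feature <- function(scores, reference, n_bins = 10, eps = 1e-9) {
  h_s <- score_histogram(scores, n_bins = n_bins)
  h_r <- if (inherits(reference, "score_histogram")) {
    reference
  } else {
    score_histogram(reference, n_bins = n_bins)
  }
  if (length(h_r$probs) != n_bins) {
    stop("reference histogram has ", length(h_r$probs),
      " bins; expected ", n_bins,
      call. = FALSE
    )
  }
  tibble(r_1 = kl_divergence(h_s, h_r, eps = eps))
}
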