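#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH: with sorted p-values p_(1) <= ... <= p_(N), the
#' adjusted value of rank i is `min_{j >= i} N * p_(j) / j`, capped at 1 and
#' mapped back to the input order; tied p-values share one adjusted value.
#' Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  check_pvector(p)
  p.adjust(p, method = "BH")
}

check_pvector <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Accepted set at a target FDR level
#'
#' BH step-up acceptance: the largest `i` with `p_(i) <= i * alpha / N`
#' determines the cutoff; the `i` smallest p-values are accepted. Ties at the
#' cutoff are all accepted (the sort is stable on input order, and equal
#' p-values share a rank decision because the step-up rule looks at the
#' largest qualifying rank).
#'
#' @param p Numeric vector of p-values.
#' @param alpha Target FDR level in (0, 1].
#' @return A list with `count` (number accepted) and `accepted` (integer
#'   indices into `p`, in input order).
#' @export
accept_at <- function(p, alpha) {
  check_pvector(p)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p)
  ord <- order(p)  # stable: ties keep input order
  ps <- p[ord]
  ok <- which(ps <= seq_len(n) * alpha / n)
  count <- if (length(ok)) max(ok) else 0L
  list(count = count, accepted = sort(ord[seq_len(count)]))
}

#' Estimated FDR as a function of identification count
#'
#' For each n in 1..N the estimated FDR of accepting the n smallest p-values
#' is the BH q-value of the n-th smallest p — the paper's FDR-versus-number-
#' of-identifications relationship. The per-protein q-values (input order)
#' are kept alongside.
#'
#' @param p Numeric vector of p-values.
#' @return An `fdr_curve` object: list with `points` (tibble `n_accepted`,
#'   `fdr`) and `qvalues` (numeric, input order).
#' @export
fdr_curve <- function(p) {
  check_pvector(p)
  q <- bh_adjust(p)
  structure(
    list(
      points = tibble(n_accepted = seq_along(p), fdr = sort(q)),
      qvalues = q
    ),
    class = "fdr_curve"
  )
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat("<fdr_curve> ", nrow(x$points), " proteins; estimated FDR range [",
    format(min(x$points$fdr), digits = 4), ", ",
    format(max(x$points$fdr), digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}

#' End-to-end FDR estimation for one sample
#'
#' Computes bin-based p-values of the target proteins against a null
#' distribution, BH q-values, and the accepted flag at level `alpha`.
#'
#' @param scores A score tibble (columns `accession`, `score`, `decoy`).
#' @param null A `perm_null` object.
#' @param alpha Target FDR level. Default 0.01.
#' @inheritParams pvalue
#' @return A tibble with columns `accession`, `score`, `pvalue`, `qvalue`,
#'   `accepted` (logical), in input order of the target entries.
#' @examples
#' nd <- build_null(runif(2000, 0, 0.6), bin_width = 0.003)
#' scores <- tibble::tibble(
#'   accession = paste0("P", 1:4),
#'   score = c(0.99, 0.95, 0.40, 0.10),
#'   decoy = FALSE
#' )
#' estimate_fdr(scores, nd, alpha = 0.05)
#' @export
estimate_fdr <- function(scores, null, alpha = 0.01, conservative = FALSE) {
  pv <- pvalues(scores, null, conservative = conservative)
  acc <- accept_at(pv$pvalue, alpha)
  accepted <- rep(FALSE, nrow(pv))
  accepted[acc$accepted] <- TRUE
  dplyr::mutate(pv,
    qvalue = bh_adjust(.data$pvalue),
    accepted = accepted
  )
}
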