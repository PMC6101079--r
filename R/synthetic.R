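#' Simulate a labelled protein identification sample
#'
#' Generates a synthetic score table emulating a ProteinProphet-style
#' protein identification result with known ground truth. True-positive
#' proteins draw scores from a Beta distribution concentrated near 1
#' (default Beta(8, 1)); false-positive target proteins and all decoy
#' proteins draw from a shared low-score Beta distribution (default
#' Beta(1, 8)) — encoding the target-decoy assumption that decoy scores
#' model false-positive scores. Each of the `n_repeats` permutation repeats
#' contributes `n_true + n_false` decoy scores, mirroring the 1:1
#' target-decoy database searched per repeat.
#'
#' @param n_true,n_false Numbers of true- and false-positive target
#'   proteins. Defaults 300 / 700.
#' @param n_repeats Number of permutation repeats; default 20.
#' @param true_shape,false_shape Length-2 Beta shape parameters for the
#'   true and false score distributions.
#' @param seed Integer seed; the simulation is reproducible under it.
#' @return A `synthetic_sample`: list with `scores` (score tibble of the
#'   targets, plus a `label` column `"true_positive"`/`"false_positive"`),
#'   `decoy_repeats` (list of `n_repeats` decoy score tibbles) and `config`.
#' @examples
#' sim <- simulate_sample(n_true = 30, n_false = 70, n_repeats = 5, seed = 1)
#' head(sim$scores)
#' @export
simulate_sample <- function(n_true = 300, n_false = 700, n_repeats = 20,
                            true_shape = c(8, 1), false_shape = c(1, 8),
                            seed = 1) {
  stopifnot(
    n_true >= 0, n_false >= 0, n_true + n_false >= 1, n_repeats >= 1,
    length(true_shape) == 2, length(false_shape) == 2,
    all(true_shape > 0), all(false_shape > 0)
  )
  set.seed(seed)
  n <- n_true + n_false
  scores <- tibble(
    accession = sprintf("SYN%05d", seq_len(n)),
    score = c(
      rbeta(n_true, true_shape[1], true_shape[2]),
      rbeta(n_false, false_shape[1], false_shape[2])
    ),
    decoy = FALSE,
    label = rep(c("true_positive", "false_positive"), c(n_true, n_false))
  )
  decoy_repeats <- purrr::map(seq_len(n_repeats), function(r) {
    tibble(
      accession = sprintf("DECOY_R%02d_%05d", r, seq_len(n)),
      score = rbeta(n, false_shape[1], false_shape[2]),
      decoy = TRUE
    )
  })
  structure(
    list(
      scores = scores,
      decoy_repeats = decoy_repeats,
      config = list(
        n_true = n_true, n_false = n_false, n_repeats = n_repeats,
        true_shape = true_shape, false_shape = false_shape, seed = seed
      )
    ),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("<synthetic_sample> ", x$config$n_true, " true + ", x$config$n_false,
    " false targets, ", x$config$n_repeats, " decoy repeats (seed ",
    x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a family of null distributions with known coefficients
#'
#' Test harness for the null-inference model: for sample i and bin k < K the
#' cumulative probability is `plogis(beta[k,1] + beta[k,2] * r_i + e)` with
#' `e ~ N(0, noise_sd)`; the last bin is 1. Each cumulative sequence is made
#' monotone (running maximum) and differenced into a density, from which a
#' `perm_null` with a nominal count mass is built. With `noise_sd = 0` and
#' generating coefficients whose CDFs are already monotone over the feature
#' range, [fit_coefficient_table()] recovers `beta` exactly.
#'
#' @param feature_values Numeric vector of per-sample feature values
#'   (length I).
#' @param beta (K-1) x 2 matrix of per-bin (intercept, slope) pairs.
#' @param K Number of bins.
#' @param noise_sd Standard deviation of logit-scale noise; default 0.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param bin_width,lo,hi Bin geometry; defaults give width `(hi - lo) / K`.
#' @param nominal_m Count mass of each generated null; default 1e6.
#' @return A list with `nulls` (list of `perm_null`) and `features` (tibble
#'   `sample_id`, `r_1`).
#' @export
simulate_null_family <- function(feature_values, beta, K,
                                 noise_sd = 0, seed = 1,
                                 lo = 0, hi = 1, bin_width = (hi - lo) / K,
                                 nominal_m = 1e6) {
  beta <- as.matrix(beta)
  stopifnot(
    nrow(beta) == K - 1L, ncol(beta) == 2L, noise_sd >= 0,
    length(feature_values) >= 1L
  )
  if (noise_sd > 0) set.seed(seed)
  nulls <- purrr::map(feature_values, function(r) {
    eta <- beta[, 1L] + beta[, 2L] * r
    if (noise_sd > 0) eta <- eta + stats::rnorm(K - 1L, sd = noise_sd)
    cum <- c(plogis(eta), 1)
    cum <- cummax(cum) # enforce a valid CDF
    cum <- pmin(cum, 1)
    density <- diff(c(0, cum))
    if (any(density < 0)) {
      stop("degenerate parameters: non-monotonizable cumulative sequence",
        call. = FALSE
      )
    }
    new_perm_null(density * nominal_m, bin_width = bin_width, lo = lo, hi = hi)
  })
  list(
    nulls = nulls,
    features = tibble(
      sample_id = sprintf("sim%02d", seq_along(feature_values)),
      r_1 = feature_values
    )
  )
}

#' Realized (true) FDR of an accepted protein set
#'
#' On labelled data, the fraction of accepted proteins that are false
#' positives (not in the ground-truth set). An empty accepted set has true
#' FDR 0 by convention.
#'
#' @param accepted Character vector of accepted accessions.
#' @param labels Named character vector or a tibble with columns `accession`
#'   and `label` mapping accessions to `"true_positive"`/`"false_positive"`.
#' @return Scalar in \[0, 1\].
#' @export
true_fdr <- function(accepted, labels) {
  if (length(accepted) == 0L) {
    return(0)
  }
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$accession)
  }
  if (!all(accepted %in% names(labels))) {
    stop("accepted accession(s) without a label: ",
      accepted[!accepted %in% names(labels)][1L],
      call. = FALSE
    )
  }
  mean(labels[accepted] == "false_positive")
}

#' Estimated-versus-true FDR calibration of one synthetic sample
#'
#' Runs the whole pipeline on a labelled synthetic sample — pool the decoy
#' repeats, build the null, compute p-values, apply the BH procedure at each
#' `alpha` — and compares the estimated FDR of the accepted set with the
#' realized true FDR. The estimated FDR at an acceptance count n is the BH
#' q-value of the n-th smallest p-value (0 when nothing is accepted).
#'
#' @param sample A `synthetic_sample` from [simulate_sample()].
#' @param alphas Numeric vector of target FDR levels.
#' @param bin_width Null bin width; default 0.003.
#' @return A tibble with columns `alpha`, `n_accepted`, `estimated_fdr`,
#'   `true_fdr`, `abs_difference`.
#' @export
calibration_report <- function(sample, alphas = c(0.01, 0.05, 0.1),
                               bin_width = 0.003) {
  stopifnot(inherits(sample, "synthetic_sample"))
  nd <- build_null(pool_decoy_scores(sample$decoy_repeats),
    bin_width = bin_width
  )
  pv <- pvalues(sample$scores, nd)
  curve <- fdr_curve(pv$pvalue)
  purrr::map_dfr(alphas, function(a) {
    acc <- accept_at(pv$pvalue, a)
    est <- if (acc$count > 0) curve$points$fdr[acc$count] else 0
    tf <- true_fdr(pv$accession[acc$accepted], sample$scores)
    tibble(
      alpha = a, n_accepted = acc$count,
      estimated_fdr = est, true_fdr = tf,
      abs_difference = abs(est - tf)
    )
  })
}
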