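#' Cumulative null probability of a bin
#'
#' `Pr(x <= upper edge of bin k) = sum(counts[1:k]) / M`. By construction the
#' last bin has cumulative probability 1, which is why the inference model
#' never fits the last bin.
#'
#' @param null A `perm_null` object.
#' @param k Bin index (vectorised), in `1..K`.
#' @return Cumulative probability in \[0, 1\].
#' @export
cum_prob <- function(null, k) {
  stopifnot(inherits(null, "perm_null"))
  if (null$M <= 0) stop("null distribution has M = 0", call. = FALSE)
  if (any(k < 1L | k > null$K)) {
    stop("bin index out of range 1..", null$K, call. = FALSE)
  }
  null$cum[k]
}

clip_unit <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Fit one bin of the logistic null-inference model
#'
#' Per-bin least squares on the logit scale: coefficients minimize
#' `sum_i L(logit(Pr_i) - b0 - sum_j b_j r_{i,j})` over the I training
#' samples. This is a linear model in the logit of the cumulative null
#' probability, not binomial maximum likelihood. Cumulative probabilities of
#' exactly 0 or 1 (empty leading bins, the forced last bin) are clipped into
#' `[clip_eps, 1 - clip_eps]` before the logit so the target stays finite.
#'
#' @param r Numeric vector (J = 1) or I x J matrix of per-sample features.
#' @param pr Numeric vector of cumulative null probabilities, one per sample.
#' @param loss `"l2"` (squared error, the default) or `"huber"` (robust,
#'   via [MASS::rlm()]).
#' @param clip_eps Clipping epsilon in (0, 0.5); default 1e-6.
#' @return Named numeric vector `c(intercept, feature_1, ..., feature_J)`.
#' @examples
#' fit_bin(c(0, 1), c(0.2, 0.5))
#' @export
fit_bin <- function(r, pr, loss = c("l2", "huber"), clip_eps = 1e-6) {
  loss <- match.arg(loss)
  r <- as.matrix(r)
  J <- ncol(r)
  I <- nrow(r)
  stopifnot(clip_eps > 0, clip_eps < 0.5)
  if (length(pr) != I) stop("length(pr) must equal nrow(r)", call. = FALSE)
  if (I < J + 1L) {
    stop("underdetermined fit: ", I, " samples for ", J + 1L,
      " coefficients",
      call. = FALSE
    )
  }
  y <- qlogis(clip_unit(pr, clip_eps))
  X <- cbind(1, r)
  if (qr(X)$rank < ncol(X)) {
    if (diff(range(y)) == 0) {
      # constant response: slope 0, intercept the common logit
      return(setNames(
        c(y[1L], rep(0, J)),
        c("intercept", paste0("feature_", seq_len(J)))
      ))
    }
    stop("rank-deficient design: features do not vary but Pr does",
      call. = FALSE
    )
  }
  beta <- switch(loss,
    l2 = stats::lm.fit(X, y)$coefficients,
    huber = coef(MASS::rlm(X, y, psi = MASS::psi.huber, maxit = 100))
  )
  setNames(
    as.numeric(beta),
    c("intercept", paste0("feature_", seq_len(J)))
  )
}

#' Fit the full per-bin coefficient table
#'
#' Runs [fit_bin()] for bins 1..K-1 of a family of null distributions that
#' share the same bin geometry; the last bin is skipped because its
#' cumulative probability is 1 for every sample. The result mirrors the
#' coefficient table stored in a feature database: one row per bin, an
#' intercept and one coefficient per feature.
#'
#' @param nulls List of `perm_null` objects with identical (K, bin_width,
#'   domain), one per training sample.
#' @param features Tibble (columns `r_1`, ..., `r_J`), numeric vector (J = 1)
#'   or I x J matrix of per-sample features, rows aligned with `nulls`.
#' @inheritParams fit_bin
#' @return A `coef_table`: tibble with columns `bin`, `intercept`,
#'   `feature_1`, ..., `feature_J` (K - 1 rows) carrying the bin geometry,
#'   loss name and clipping epsilon as attributes.
#' @export
fit_coefficient_table <- function(nulls, features, loss = c("l2", "huber"),
                                  clip_eps = 1e-6) {
  loss <- match.arg(loss)
  stopifnot(is.list(nulls), length(nulls) >= 1L)
  purrr::walk(nulls, function(nd) stopifnot(inherits(nd, "perm_null")))
  ref <- nulls[[1L]]
  same <- purrr::every(nulls, function(nd) {
    nd$K == ref$K && nd$bin_width == ref$bin_width &&
      nd$lo == ref$lo && nd$hi == ref$hi
  })
  if (!same) {
    stop("null distributions have mismatched bin structure", call. = FALSE)
  }
  r <- features_as_matrix(features)
  if (nrow(r) != length(nulls)) {
    stop("features and nulls have different lengths", call. = FALSE)
  }
  K <- ref$K
  cum <- do.call(rbind, purrr::map(nulls, "cum")) # I x K
  rows <- purrr::map(seq_len(K - 1L), function(k) {
    fit_bin(r, cum[, k], loss = loss, clip_eps = clip_eps)
  })
  tab <- dplyr::bind_cols(
    tibble(bin = seq_len(K - 1L)),
    as_tibble(do.call(rbind, rows))
  )
  structure(tab,
    class = c("coef_table", class(tab)),
    K = K, J = ncol(r), bin_width = ref$bin_width,
    lo = ref$lo, hi = ref$hi, loss = loss, clip_eps = clip_eps
  )
}

features_as_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- grep("^r_[0-9]+$", names(features), value = TRUE)
    if (length(cols) == 0L) {
      stop("feature table needs columns r_1 .. r_J", call. = FALSE)
    }
    as.matrix(features[, cols, drop = FALSE])
  } else {
    as.matrix(features)
  }
}

#' Predicted cumulative null probability for a new sample
#'
#' Evaluates the logistic link on the fitted coefficients at the new sample's
#' feature vector: `1 / (1 + exp(-(b0 + sum_j b_j r0_j)))`. The linear term
#' is clamped to avoid overflow, so the result is strictly inside (0, 1).
#'
#' @param coeffs A `coef_table`, or a single coefficient row (numeric vector
#'   `c(intercept, feature_1, ...)`).
#' @param r0 Feature vector of the new sample (length J), or a one-row
#'   feature tibble.
#' @param bin Optional bin index; with a `coef_table`, restricts the result
#'   to that bin. Default: all fitted bins.
#' @return Numeric vector of predicted cumulative probabilities.
#' @export
predict_cum_prob <- function(coeffs, r0, bin = NULL) {
  r0 <- as.numeric(features_as_matrix(if (is.data.frame(r0)) r0 else t(r0)))
  if (inherits(coeffs, "coef_table")) {
    J <- attr(coeffs, "J")
    if (length(r0) != J) {
      stop("feature vector has length ", length(r0), "; expected ", J,
        call. = FALSE
      )
    }
    B <- as.matrix(coeffs[, c("intercept", paste0("feature_", seq_len(J)))])
    eta <- as.numeric(B %*% c(1, r0))
    if (!is.null(bin)) eta <- eta[bin]
  } else {
    beta <- as.numeric(coeffs)
    if (length(beta) != length(r0) + 1L) {
      stop("coefficient row and feature vector have incompatible lengths",
        call. = FALSE
      )
    }
    eta <- sum(beta * c(1, r0))
  }
  # +/-36 keeps plogis strictly inside (0, 1) in double precision
  plogis(pmin(pmax(eta, -36), 36))
}

#' Infer the null distribution of a new sample
#'
#' Predicts the cumulative null probability of every fitted bin at the new
#' sample's feature vector, forces the last bin to 1, and differences the
#' cumulative sequence into a density (with `Pr(bin 0) = 0`). Because the
#' per-bin fits are independent, the predicted cumulative sequence need not
#' be monotone; it is repaired by isotonic regression (the L2-closest
#' non-decreasing sequence) before differencing, so the returned density is
#' non-negative and sums to 1.
#'
#' @param coeffs A `coef_table` from [fit_coefficient_table()].
#' @param r0 Feature vector (length J) or one-row feature tibble.
#' @param nominal_m Nominal decoy count used to synthesize the `counts`
#'   field so the inferred null plugs into [pvalue()]; default 1e6.
#' @return A `perm_null` object with fractional counts summing to
#'   `nominal_m`.
#' @export
infer_null <- function(coeffs, r0, nominal_m = 1e6) {
  stopifnot(inherits(coeffs, "coef_table"))
  K <- attr(coeffs, "K")
  cum <- c(predict_cum_prob(coeffs, r0), 1)
  cum <- isoreg(seq_len(K), cum)$yf
  cum <- clip_unit(cum, 0) # guard tiny numeric excursions
  cum[K] <- 1
  density <- diff(c(0, cum))
  new_perm_null(density * nominal_m,
    bin_width = attr(coeffs, "bin_width"),
    lo = attr(coeffs, "lo"), hi = attr(coeffs, "hi")
  )
}

#' Write / read a coefficient table as TSV + JSON sidecar
#'
#' The TSV mirrors the printed coefficient table (columns `bin`, `intercept`,
#' `feature_1` ...); the sidecar `<path>.meta.json` stores the bin geometry,
#' loss and clipping epsilon needed to reconstruct the `coef_table`.
#'
#' @param coeffs A `coef_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a `coef_table` (reader).
#' @export
write_coef_table <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coef_table"))
  write.table(as.data.frame(coeffs), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    coef_table_meta(coeffs),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

coef_table_meta <- function(coeffs) {
  list(
    K = attr(coeffs, "K"), J = attr(coeffs, "J"),
    bin_width = attr(coeffs, "bin_width"),
    lo = attr(coeffs, "lo"), hi = attr(coeffs, "hi"),
    loss = attr(coeffs, "loss"), clip_eps = attr(coeffs, "clip_eps")
  )
}

coef_table_from_parts <- function(tab, meta) {
  tab <- as_tibble(tab)
  structure(tab,
    class = c("coef_table", class(tab)),
    K = as.integer(meta$K), J = as.integer(meta$J),
    bin_width = meta$bin_width, lo = meta$lo, hi = meta$hi,
    loss = meta$loss, clip_eps = meta$clip_eps
  )
}

#' @rdname write_coef_table
#' @export
read_coef_table <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop("coefficient table or its .meta.json sidecar missing: ", path,
      call. = FALSE
    )
  }
  tab <- read.delim(path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  coef_table_from_parts(tab, meta)
}
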