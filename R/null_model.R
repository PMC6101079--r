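#' Read / write a protein score table
#'
#' Score tables are TSV files with header `accession<TAB>score<TAB>decoy`
#' (decoy coded 0/1), one row per inferred protein. The score is the protein
#' probability in \[0, 1\] reported by protein-inference software (e.g. a
#' ProteinProphet probability) and is used as the test statistic. If the
#' `decoy` column is absent it is derived from the accession prefix via
#' [is_decoy()].
#'
#' @param path TSV file path.
#' @param decoy_prefix Fallback accession prefix when the file has no `decoy`
#'   column.
#' @return A tibble with columns `accession` (character), `score` (double in
#'   \[0,1\]) and `decoy` (logical).
#' @export
read_scores <- function(path, decoy_prefix = "DECOY_") {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  df <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("accession", "score") %in% names(df))) {
    stop("score table needs columns accession and score: ", path,
      call. = FALSE
    )
  }
  if (is.null(df[["decoy"]])) {
    df$decoy <- is_decoy(df$accession, decoy_prefix)
  } else {
    df$decoy <- as.logical(df$decoy)
  }
  check_scores(df)
  df[, c("accession", "score", "decoy")]
}

#' @rdname read_scores
#' @param scores A score tibble.
#' @export
write_scores <- function(scores, path) {
  check_scores(scores)
  out <- data.frame(
    accession = scores$accession,
    score = scores$score,
    decoy = as.integer(scores$decoy)
  )
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

check_scores <- function(scores) {
  stopifnot(is.data.frame(scores))
  missing <- setdiff(c("accession", "score", "decoy"), names(scores))
  if (length(missing)) {
    stop("score table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(scores$score)) ||
    any(scores$score < 0) || any(scores$score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  invisible(scores)
}

#' Pool decoy scores across permutation repeats
#'
#' Concatenates the decoy (false-positive) scores of several score tables —
#' typically one table per shuffling repeat of the same sample. The pooled
#' vector of length `M` feeds [build_null()].
#'
#' @param repeats A score tibble or a list of score tibbles.
#' @return Numeric vector of decoy scores.
#' @export
pool_decoy_scores <- function(repeats) {
  if (is.data.frame(repeats)) repeats <- list(repeats)
  scores <- purrr::map(repeats, function(df) {
    check_scores(df)
    df$score[df$decoy]
  })
  out <- unlist(scores, use.names = FALSE)
  if (length(out) == 0L) {
    stop("empty null: no decoy scores in any repeat", call. = FALSE)
  }
  out
}

#' Bin index of a score
#'
#' Bins are half-open `[left, right)` of width `bin_width` starting at `lo`;
#' the final bin is right-closed so every score in `[lo, hi]` belongs to
#' exactly one bin, and it may be narrower than `bin_width` when
#' `(hi - lo) / bin_width` is not integral (e.g. 334 bins of width 0.003 on
#' the unit interval).
#'
#' @param score Numeric vector of scores in `[lo, hi]`.
#' @param null A `perm_null` object from [build_null()], or `NULL` if the bin
#'   geometry is given explicitly.
#' @param bin_width,lo,hi Bin geometry used when `null` is `NULL`.
#' @return Integer vector of bin indices in `1..K`.
#' @export
bin_index <- function(score, null = NULL, bin_width = 0.003, lo = 0, hi = 1) {
  if (!is.null(null)) {
    stopifnot(inherits(null, "perm_null"))
    bin_width <- null$bin_width
    lo <- null$lo
    hi <- null$hi
  }
  if (any(score < lo | score > hi)) {
    stop("score outside [", lo, ", ", hi, "]", call. = FALSE)
  }
  k_max <- as.integer(ceiling((hi - lo) / bin_width))
  pmin(as.integer(floor((score - lo) / bin_width)) + 1L, k_max)
}

#' Build the binned empirical null distribution
#'
#' Partitions `[lo, hi]` into `K = ceiling((hi - lo) / bin_width)` bins and
#' counts the pooled decoy scores per bin. The points (bin centre, count / M)
#' describe the empirical null probability density of false-positive protein
#' scores; the cumulative vector supports both p-values and the per-bin
#' logistic inference model.
#'
#' The domain defaults to the unit interval of protein probabilities rather
#' than the observed score range, so bin geometry is identical across
#' samples; at the default width 0.003 this yields K = 334 bins with a
#' truncated last bin.
#'
#' @param decoy_scores Numeric vector of pooled decoy scores (see
#'   [pool_decoy_scores()]).
#' @param bin_width Bin width; default 0.003.
#' @param lo,hi Domain bounds; default `[0, 1]`.
#' @return A `perm_null` object: list with elements `lo`, `hi`, `bin_width`,
#'   `K`, `counts` (length-`K`), `M`, `mids`, `density` and `cum`.
#' @examples
#' nd <- build_null(c(0.1, 0.2, 0.6, 0.9), bin_width = 0.25)
#' nd$counts
#' @export
build_null <- function(decoy_scores, bin_width = 0.003, lo = 0, hi = 1) {
  if (length(decoy_scores) == 0L) {
    stop("empty null: no decoy scores", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > hi - lo) {
    stop("bin_width must lie in (0, hi - lo]", call. = FALSE)
  }
  if (any(decoy_scores < lo | decoy_scores > hi)) {
    stop("decoy scores outside [", lo, ", ", hi, "]", call. = FALSE)
  }
  K <- as.integer(ceiling((hi - lo) / bin_width))
  k <- bin_index(decoy_scores, bin_width = bin_width, lo = lo, hi = hi)
  counts <- tabulate(k, nbins = K)
  new_perm_null(counts, bin_width = bin_width, lo = lo, hi = hi)
}

## constructor shared by build_null and infer_null; counts may be fractional
## for inferred nulls (a nominal M spread over the density)
new_perm_null <- function(counts, bin_width, lo, hi) {
  K <- length(counts)
  breaks <- c(lo + seq_len(K - 1L) * bin_width, hi)
  lefts <- lo + (seq_len(K) - 1L) * bin_width
  M <- sum(counts)
  structure(
    list(
      lo = lo, hi = hi, bin_width = bin_width, K = as.integer(K),
      counts = counts, M = M,
      mids = (lefts + breaks) / 2,
      density = counts / M,
      cum = cumsum(counts) / M
    ),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(
    "<perm_null> ", x$K, " bins of width ", format(x$bin_width),
    " on [", x$lo, ", ", x$hi, "], M = ", format(x$M), " decoy scores\n",
    sep = ""
  )
  invisible(x)
}

#' Bin-based p-value of a protein score
#'
#' The p-value of a score falling in bin `k_hat` is the null mass in that bin
#' and all higher bins, `sum(counts[k_hat:K]) / M` — a right-tail empirical
#' p-value that is a step function, constant within bins and non-increasing
#' in the score. Scores above all decoy scores receive p = 0 under the
#' literal rule; set `conservative = TRUE` to replace each tail count `c`
#' with `(c + 1) / (M + 1)` and so floor p-values away from zero.
#'
#' @param null A `perm_null` object.
#' @param score Numeric vector of scores in the null's domain.
#' @param conservative Apply the `(c + 1) / (M + 1)` correction. Default
#'   `FALSE` (literal tail mass).
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
pvalue <- function(null, score, conservative = FALSE) {
  stopifnot(inherits(null, "perm_null"))
  if (null$M <= 0) stop("null distribution has M = 0", call. = FALSE)
  k <- bin_index(score, null)
  tail_counts <- rev(cumsum(rev(null$counts)))[k]
  if (conservative) (tail_counts + 1) / (null$M + 1) else tail_counts / null$M
}

#' P-values for every target protein of a sample
#'
#' Applies [pvalue()] to each non-decoy row of a score table, preserving the
#' input order. Decoy entries are dropped: the N of the downstream BH
#' procedure counts target proteins only.
#'
#' @param scores A score tibble (columns `accession`, `score`, `decoy`).
#' @inheritParams pvalue
#' @return A tibble with columns `accession`, `score`, `pvalue`.
#' @export
pvalues <- function(scores, null, conservative = FALSE) {
  check_scores(scores)
  targets <- scores[!scores$decoy, , drop = FALSE]
  if (nrow(targets) == 0L) {
    stop("sample has no target (non-decoy) entries", call. = FALSE)
  }
  tibble(
    accession = targets$accession,
    score = targets$score,
    pvalue = pvalue(null, targets$score, conservative = conservative)
  )
}

#' Serialize a null distribution to JSON
#'
#' Writes the bin geometry and counts; [read_null_json()] reconstructs the
#' `perm_null` losslessly (density and cumulative vectors are recomputed).
#'
#' @param null A `perm_null` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_null_json <- function(null, path) {
  stopifnot(inherits(null, "perm_null"))
  jsonlite::write_json(
    list(
      lo = null$lo, hi = null$hi, bin_width = null$bin_width,
      K = null$K, M = null$M, counts = null$counts
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_null_json
#' @export
read_null_json <- function(path) {
  if (!file.exists(path)) stop("null JSON not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("lo", "hi", "bin_width", "counts")
  if (!all(needed %in% names(x))) {
    stop("null JSON lacks field(s): ",
      paste(setdiff(needed, names(x)), collapse = ", "),
      call. = FALSE
    )
  }
  new_perm_null(x$counts, bin_width = x$bin_width, lo = x$lo, hi = x$hi)
}
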