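#' Tidy a binned null distribution
#'
#' One row per bin: the bin index, its centre, count, density value and
#' cumulative probability.
#'
#' @param x A `perm_null`.
#' @param ... Unused.
#' @return A tibble with columns `bin`, `mid`, `count`, `density`, `cum`.
#' @method tidy perm_null
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(
    bin = seq_len(x$K), mid = x$mids, count = x$counts,
    density = x$density, cum = x$cum
  )
}

#' @rdname tidy.perm_null
#' @method glance perm_null
#' @export
glance.perm_null <- function(x, ...) {
  tibble(
    K = x$K, bin_width = x$bin_width, lo = x$lo, hi = x$hi, M = x$M,
    mean_score = sum(x$mids * x$density)
  )
}

#' Tidy an FDR curve
#'
#' @param x An `fdr_curve`.
#' @param ... Unused.
#' @return The `points` tibble (`n_accepted`, `fdr`).
#' @method tidy fdr_curve
#' @export
tidy.fdr_curve <- function(x, ...) x$points

#' @rdname tidy.fdr_curve
#' @method glance fdr_curve
#' @export
glance.fdr_curve <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$points),
    n_at_fdr_01 = sum(x$points$fdr <= 0.01),
    n_at_fdr_05 = sum(x$points$fdr <= 0.05),
    min_fdr = min(x$points$fdr)
  )
}

#' Tidy a fitted coefficient table
#'
#' @param x A `coef_table`.
#' @param ... Unused.
#' @return A tibble with one row per fitted bin (`bin`, `intercept`,
#'   `feature_1`, ...).
#' @method tidy coef_table
#' @export
tidy.coef_table <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.coef_table
#' @method glance coef_table
#' @export
glance.coef_table <- function(x, ...) {
  tibble(
    K = attr(x, "K"), J = attr(x, "J"),
    bin_width = attr(x, "bin_width"),
    loss = attr(x, "loss"), clip_eps = attr(x, "clip_eps")
  )
}

#' Plot a null distribution
#'
#' Bin-centre density of the empirical (or inferred) null.
#'
#' @param object A `perm_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_null
#' @export
autoplot.perm_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey35") +
    ggplot2::labs(
      x = "protein score", y = "null density",
      title = sprintf("Null distribution (K = %d, M = %s)",
        object$K, format(object$M, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an FDR curve
#'
#' Estimated FDR against the number of accepted proteins.
#'
#' @param object An `fdr_curve`.
#' @param alphas Horizontal reference levels to draw; default 0.01 and 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdr_curve
#' @export
autoplot.fdr_curve <- function(object, alphas = c(0.01, 0.05), ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$n_accepted, y = .data$fdr)
  ) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = alphas, linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "number of accepted proteins", y = "estimated FDR"
    ) +
    ggplot2::theme_minimal()
}

#' Compare two null distributions
#'
#' Overlays the densities of two nulls with the same bin geometry — e.g. a
#' permutation-built null against the null inferred for the same sample.
#'
#' @param a,b `perm_null` objects sharing (K, bin_width, domain).
#' @param labels Length-2 legend labels.
#' @return A ggplot object.
#' @export
plot_null_comparison <- function(a, b, labels = c("permutation", "inferred")) {
  stopifnot(inherits(a, "perm_null"), inherits(b, "perm_null"), a$K == b$K)
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy(a), which = labels[1]),
    dplyr::mutate(tidy(b), which = labels[2])
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$mid, y = .data$density, colour = .data$which)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "protein score", y = "null density", colour = NULL) +
    ggplot2::theme_minimal()
}
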