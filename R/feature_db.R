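#' Create a feature database
#'
#' A feature database bundles everything needed for off-line protein-level
#' FDR estimation: the stored null distributions of previously analysed
#' samples, a feature table (one KL-divergence feature per sample against a
#' designated reference sample), and the per-bin logistic coefficient table.
#' A new sample is either matched to a stored sample by feature similarity
#' (its null is reused) or, failing that, its null is inferred from the
#' coefficient table — no new permutation run in either case.
#'
#' The reference sample's 10-bin score histogram is stored inside the
#' database, so feature extraction for new samples never needs the
#' reference's raw scores again.
#'
#' @param reference_scores Score tibble of the reference sample.
#' @param reference_id Sample id of the reference. Default `"reference"`.
#' @param protein_db_path Optional path of the FASTA protein database the
#'   identifications came from (metadata only).
#' @param bin_width,lo,hi Null-distribution bin geometry. Defaults 0.003 on
#'   `[0, 1]`.
#' @param n_feature_bins Histogram bins for the KL feature; default 10.
#' @param match_tol J = 1 similarity tolerance: a new sample reuses a stored
#'   null when the absolute feature difference is at most this. Default 0.05.
#' @param cor_threshold J >= 2 similarity threshold on the Pearson
#'   correlation of feature vectors. Default 0.9.
#' @param kl_eps,clip_eps Smoothing and logit-clipping epsilons.
#' @return A `feature_db` object.
#' @export
feature_db <- function(reference_scores, reference_id = "reference",
                       protein_db_path = NULL,
                       bin_width = 0.003, lo = 0, hi = 1,
                       n_feature_bins = 10, match_tol = 0.05,
                       cor_threshold = 0.9, kl_eps = 1e-9,
                       clip_eps = 1e-6) {
  ref_hist <- score_histogram(reference_scores,
    n_bins = n_feature_bins, lo = lo, hi = hi
  )
  structure(
    list(
      protein_db_path = protein_db_path,
      reference_sample_id = reference_id,
      reference_hist = ref_hist,
      stored_nulls = list(),
      feature_table = tibble(sample_id = character(), r_1 = double()),
      coefficients = NULL,
      coefficients_stale = FALSE,
      config = list(
        bin_width = bin_width, lo = lo, hi = hi,
        n_feature_bins = n_feature_bins, match_tol = match_tol,
        cor_threshold = cor_threshold, kl_eps = kl_eps,
        clip_eps = clip_eps
      ),
      version = 1L
    ),
    class = "feature_db"
  )
}

#' @export
print.feature_db <- function(x, ...) {
  cat("<feature_db> ", nrow(x$feature_table), " stored sample(s), reference '",
    x$reference_sample_id, "', coefficients ",
    if (is.null(x$coefficients)) {
      "absent"
    } else if (isTRUE(x$coefficients_stale)) {
      "stale"
    } else {
      "fitted"
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' Add a sample's null distribution and features to a feature database
#'
#' Appends the sample to the feature table and null store. The coefficient
#' table is marked stale until [refit_db()] is called.
#'
#' @param db A `feature_db`.
#' @param sample_id Unused sample identifier.
#' @param features One-row feature tibble (from [extract_feature()]) or a
#'   numeric feature vector.
#' @param null The sample's `perm_null`, with the database's bin geometry.
#' @return The updated `feature_db`.
#' @export
add_sample <- function(db, sample_id, features, null) {
  stopifnot(inherits(db, "feature_db"), inherits(null, "perm_null"))
  if (sample_id %in% db$feature_table$sample_id) {
    stop("sample_id already stored: ", sample_id, call. = FALSE)
  }
  K <- as.integer(ceiling((db$config$hi - db$config$lo) / db$config$bin_width))
  if (null$K != K || null$bin_width != db$config$bin_width ||
    null$lo != db$config$lo || null$hi != db$config$hi) {
    stop("null bin structure does not match the database (K = ", K, ")",
      call. = FALSE
    )
  }
  r <- as.numeric(features_as_matrix(
    if (is.data.frame(features)) features else t(features)
  ))
  db$feature_table <- dplyr::bind_rows(
    db$feature_table,
    dplyr::bind_cols(
      tibble(sample_id = sample_id),
      as_tibble(setNames(as.list(r), paste0("r_", seq_along(r))))
    )
  )
  db$stored_nulls[[sample_id]] <- null
  db$coefficients_stale <- TRUE
  db
}

#' Refit the coefficient table of a feature database
#'
#' Runs [fit_coefficient_table()] on all stored nulls and features.
#'
#' @param db A `feature_db` with at least two stored samples.
#' @param loss `"l2"` or `"huber"`.
#' @return The updated `feature_db` with fresh coefficients.
#' @export
refit_db <- function(db, loss = c("l2", "huber")) {
  stopifnot(inherits(db, "feature_db"))
  loss <- match.arg(loss)
  ids <- db$feature_table$sample_id
  if (length(ids) < 2L) {
    stop("need at least two stored samples to fit coefficients",
      call. = FALSE
    )
  }
  db$coefficients <- fit_coefficient_table(
    db$stored_nulls[ids], db$feature_table,
    loss = loss, clip_eps = db$config$clip_eps
  )
  db$coefficients_stale <- FALSE
  db
}

#' Match a new sample's features against the stored samples
#'
#' With a single feature (the current implementation) similarity is the
#' absolute feature difference: the nearest stored sample is returned if it
#' lies within `match_tol`. With J >= 2 features similarity is the Pearson
#' correlation of feature vectors, and the best match must exceed
#' `cor_threshold`.
#'
#' @param db A `feature_db` with at least one stored sample.
#' @param r0 Feature vector or one-row feature tibble of the new sample.
#' @return The matched `sample_id`, or `NA_character_` if none is similar
#'   enough.
#' @export
match_sample <- function(db, r0) {
  stopifnot(inherits(db, "feature_db"))
  if (nrow(db$feature_table) == 0L) {
    stop("feature database has no stored samples", call. = FALSE)
  }
  r0 <- as.numeric(features_as_matrix(
    if (is.data.frame(r0)) r0 else t(r0)
  ))
  R <- features_as_matrix(db$feature_table)
  if (length(r0) != ncol(R)) {
    stop("feature vector has length ", length(r0), "; expected ", ncol(R),
      call. = FALSE
    )
  }
  if (length(r0) == 1L) {
    d <- abs(R[, 1L] - r0)
    i <- which.min(d)
    if (d[i] <= db$config$match_tol) db$feature_table$sample_id[i]
    else NA_character_
  } else {
    cors <- apply(R, 1L, function(ri) cor(ri, r0))
    i <- which.max(cors)
    if (cors[i] > db$config$cor_threshold) db$feature_table$sample_id[i]
    else NA_character_
  }
}

#' Resolve the null distribution of a new sample
#'
#' The off-line decision workflow: extract the sample's KL feature against
#' the database's reference histogram; if a stored sample is similar enough
#' (see [match_sample()]) reuse its stored null, otherwise infer a null from
#' the coefficient table. The database is never modified.
#'
#' @param db A complete `feature_db` (stored samples; fitted coefficients if
#'   inference may be needed).
#' @param scores Score tibble of the new sample.
#' @return A list with `null` (a `perm_null`), `provenance`
#'   (`"matched:<id>"` or `"inferred"`), and `feature` (the extracted
#'   feature value).
#' @export
resolve_null <- function(db, scores) {
  stopifnot(inherits(db, "feature_db"))
  r0 <- extract_feature(scores, db$reference_hist,
    n_bins = db$config$n_feature_bins, eps = db$config$kl_eps
  )
  hit <- match_sample(db, r0)
  if (!is.na(hit)) {
    return(list(
      null = db$stored_nulls[[hit]],
      provenance = paste0("matched:", hit),
      feature = r0$r_1
    ))
  }
  if (is.null(db$coefficients)) {
    stop("no similar stored sample and no coefficient table; run refit_db()",
      call. = FALSE
    )
  }
  if (isTRUE(db$coefficients_stale)) {
    warning("coefficient table is stale; refit_db() to include new samples",
      call. = FALSE
    )
  }
  list(
    null = infer_null(db$coefficients, r0),
    provenance = "inferred",
    feature = r0$r_1
  )
}

#' Save / load a feature database as a single JSON document
#'
#' The whole database — reference histogram, stored nulls, feature table,
#' coefficient table and configuration — round-trips through one
#' human-diffable JSON file with a schema version field.
#'
#' @param db A `feature_db`.
#' @param path JSON file path.
#' @return `path`, invisibly (save); a `feature_db` (load).
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  doc <- list(
    format = "permfdr-feature-db",
    version = db$version,
    protein_db_path = db$protein_db_path,
    reference_sample_id = db$reference_sample_id,
    reference_hist = db$reference_hist[c("probs", "lo", "hi", "n")],
    stored_nulls = purrr::map(db$stored_nulls, function(nd) {
      list(
        lo = nd$lo, hi = nd$hi, bin_width = nd$bin_width,
        counts = nd$counts
      )
    }),
    feature_table = db$feature_table,
    coefficients = if (!is.null(db$coefficients)) {
      list(
        table = as.data.frame(db$coefficients),
        meta = coef_table_meta(db$coefficients)
      )
    },
    coefficients_stale = db$coefficients_stale,
    config = db$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  if (!file.exists(path)) {
    stop("feature database not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "permfdr-feature-db")) {
    stop("not a permfdr feature database: ", path, call. = FALSE)
  }
  if (!identical(as.integer(doc$version), 1L)) {
    stop("unsupported feature database version: ", doc$version, call. = FALSE)
  }
  for (comp in c("reference_hist", "feature_table", "config")) {
    if (is.null(doc[[comp]])) {
      stop("feature database missing component: ", comp, call. = FALSE)
    }
  }
  db <- feature_db_skeleton(doc)
  nulls <- doc$stored_nulls
  db$stored_nulls <- purrr::map(nulls, function(nd) {
    new_perm_null(nd$counts,
      bin_width = nd$bin_width, lo = nd$lo, hi = nd$hi
    )
  })
  ft <- as_tibble(doc$feature_table)
  if (ncol(ft) == 0L) { # an empty table serializes as []
    ft <- tibble(sample_id = character(), r_1 = double())
  }
  if (nrow(ft) > 0 && !all(ft$sample_id %in% names(db$stored_nulls))) {
    stop("feature table lists sample(s) without a stored null", call. = FALSE)
  }
  db$feature_table <- ft
  if (!is.null(doc$coefficients) && length(doc$coefficients)) {
    db$coefficients <- coef_table_from_parts(
      doc$coefficients$table, doc$coefficients$meta
    )
  }
  Ks <- purrr::map_int(db$stored_nulls, "K")
  if (length(Ks) && length(unique(Ks)) > 1L) {
    stop("stored nulls disagree on K: ",
      paste(unique(Ks), collapse = ", "),
      call. = FALSE
    )
  }
  db
}

feature_db_skeleton <- function(doc) {
  structure(
    list(
      protein_db_path = doc$protein_db_path,
      reference_sample_id = doc$reference_sample_id,
      reference_hist = structure(
        list(
          probs = doc$reference_hist$probs,
          lo = doc$reference_hist$lo, hi = doc$reference_hist$hi,
          n = doc$reference_hist$n
        ),
        class = "score_histogram"
      ),
      stored_nulls = list(),
      feature_table = tibble(sample_id = character(), r_1 = double()),
      coefficients = NULL,
      coefficients_stale = isTRUE(doc$coefficients_stale),
      config = doc$config,
      version = 1L
    ),
    class = "feature_db"
  )
}
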