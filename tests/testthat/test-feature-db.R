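# Build a small but complete feature database from a family of related
# synthetic samples whose score mixtures vary smoothly, so nulls, features
# and coefficients are all non-trivial.
make_db <- function(n_store = 4, seed = 101, bin_width = 0.01) {
  set.seed(seed)
  # full-support reference keeps the KL feature scale moderate (no
  # eps-dominated empty reference bins)
  ref <- toy_scores(target = runif(1000))
  db <- feature_db(ref, bin_width = bin_width)
  mix <- seq(0.2, 0.8, length.out = n_store)
  for (i in seq_len(n_store)) {
    sc <- toy_scores(
      target = c(
        rbeta(round(2000 * mix[i]), 6, 2),
        rbeta(round(2000 * (1 - mix[i])), 1, 8)
      )
    )
    nd <- build_null(rbeta(3000, 1, 6 + 2 * i), bin_width = bin_width)
    db <- add_sample(
      db, paste0("s", i), extract_feature(sc, db$reference_hist), nd
    )
  }
  refit_db(db)
}

test_that("add_sample appends components, validates structure, and marks
           coefficients stale", {
  set.seed(53)
  db <- feature_db(toy_scores(target = runif(100)), bin_width = 0.01)
  nd <- build_null(runif(500), bin_width = 0.01)
  db <- add_sample(db, "a", tibble::tibble(r_1 = 0.1), nd)
  expect_equal(db$feature_table$sample_id, "a")
  expect_error(
    add_sample(db, "a", tibble::tibble(r_1 = 0.2), nd),
    "already stored"
  )
  wrong_k <- build_null(runif(500), bin_width = 0.05)
  expect_error(
    add_sample(db, "b", tibble::tibble(r_1 = 0.2), wrong_k),
    "bin structure"
  )
  db <- add_sample(db, "b", tibble::tibble(r_1 = 0.9), nd)
  expect_true(db$coefficients_stale)
  db <- refit_db(db)
  expect_false(db$coefficients_stale)
  expect_equal(nrow(db$coefficients), nd$K - 1)
})

test_that("match_sample does nearest-neighbour matching under the J = 1
           tolerance", {
  db <- make_db()
  r <- db$feature_table$r_1
  expect_equal(match_sample(db, r[2]), "s2") # exact feature match
  expect_equal(match_sample(db, tibble::tibble(r_1 = r[1] + 0.01)), "s1")
  expect_true(is.na(match_sample(db, max(r) + 1)))
  empty <- feature_db(toy_scores(target = runif(50)))
  expect_error(match_sample(empty, 0.1), "no stored samples")
})

test_that("match_sample uses Pearson correlation for J >= 2", {
  db <- feature_db(toy_scores(target = runif(100)), bin_width = 0.25)
  nd <- build_null(runif(100), bin_width = 0.25)
  db <- add_sample(db, "a", c(1, 2, 3), nd)
  db <- add_sample(db, "b", c(3, 2, 1), nd)
  expect_equal(match_sample(db, c(2, 4, 6)), "a") # perfectly correlated
  expect_true(is.na(match_sample(db, c(1, -2, 1)))) # correlated with neither
})

test_that("resolve_null reuses the stored null for a replicate and infers
           one for a novel sample", {
  db <- make_db()
  set.seed(59)
  # a replicate of stored sample s2: same generating mixture
  mix <- seq(0.2, 0.8, length.out = 4)[2]
  rep2 <- toy_scores(
    target = c(
      rbeta(round(2000 * mix), 6, 2),
      rbeta(round(2000 * (1 - mix)), 1, 8)
    )
  )
  res <- resolve_null(db, rep2)
  expect_match(res$provenance, "^matched:")
  matched_id <- sub("^matched:", "", res$provenance)
  expect_identical(res$null, db$stored_nulls[[matched_id]])
  # a clearly novel sample far from every stored feature
  novel <- toy_scores(target = rbeta(400, 8, 1))
  r_novel <- extract_feature(novel, db$reference_hist)$r_1
  expect_gt(min(abs(r_novel - db$feature_table$r_1)), db$config$match_tol)
  res2 <- resolve_null(db, novel)
  expect_equal(res2$provenance, "inferred")
  expect_equal(sum(res2$null$density), 1)
  expect_true(all(res2$null$density >= 0))
  # deterministic given db + sample
  expect_equal(resolve_null(db, novel), res2)
})

test_that("resolve_null then pvalues then fdr_curve runs end-to-end", {
  db <- make_db()
  set.seed(61)
  novel <- toy_scores(target = c(rbeta(100, 8, 1), rbeta(100, 1, 8)))
  res <- resolve_null(db, novel)
  pv <- pvalues(novel, res$null)
  crv <- fdr_curve(pv$pvalue)
  expect_equal(nrow(crv$points), 200)
  expect_true(all(crv$points$fdr >= 0 & crv$points$fdr <= 1))
  expect_gt(sum(crv$points$fdr <= 0.05), 0) # high scorers are acceptable
})

test_that("feature database JSON round trip is lossless and validated", {
  db <- make_db(n_store = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_db(db, path)
  db2 <- load_db(path)
  expect_equal(db2$feature_table, db$feature_table)
  expect_equal(db2$stored_nulls, db$stored_nulls)
  expect_equal(tidy(db2$coefficients), tidy(db$coefficients))
  expect_equal(db2$reference_hist, db$reference_hist)
  expect_equal(db2$config, db$config)
  # resolution behaves identically after the round trip
  set.seed(67)
  novel <- toy_scores(target = rbeta(200, 8, 1))
  expect_equal(
    resolve_null(db2, novel)$null$density,
    resolve_null(db, novel)$null$density
  )
  expect_error(load_db(file.path(tempdir(), "no.json")), "not found")
  # corrupt documents are rejected with the component named
  bad <- jsonlite::read_json(path)
  bad$feature_table <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(load_db(path2), "feature_table")
  notdb <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), notdb, auto_unbox = TRUE)
  expect_error(load_db(notdb), "not a permfdr")
})
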