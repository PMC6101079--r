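test_that("cum_prob is the running bin mass with last bin at 1", {
  nd <- build_null(c(0.1, 0.2, 0.6, 0.9), bin_width = 0.25)
  expect_equal(cum_prob(nd, 1), 0.5)
  expect_equal(cum_prob(nd, 2), 0.5)
  expect_equal(cum_prob(nd, nd$K), 1)
  expect_error(cum_prob(nd, 0), "out of range")
  expect_error(cum_prob(nd, 5), "out of range")
})

test_that("fit_bin solves the logit-scale least squares exactly", {
  # two points, one feature: exact 2x2 solve
  b <- fit_bin(c(0, 1), c(0.2, 0.5))
  expect_equal(unname(b["intercept"]), qlogis(0.2))
  expect_equal(unname(b["feature_1"]), qlogis(0.5) - qlogis(0.2))
  # constant Pr: zero slope, intercept at the common logit
  b2 <- fit_bin(c(0, 0.5, 1), rep(0.3, 3))
  expect_equal(unname(b2), c(qlogis(0.3), 0))
  # Pr = 1 clipped before the logit
  b3 <- fit_bin(c(0, 1), c(0.5, 1), clip_eps = 1e-6)
  expect_equal(unname(b3["feature_1"]), qlogis(1 - 1e-6) - qlogis(0.5))
  # degenerate design
  expect_error(fit_bin(c(1, 1, 1), c(0.2, 0.3, 0.4)), "rank-deficient")
  b4 <- fit_bin(c(1, 1, 1), rep(0.4, 3)) # constant response is fine
  expect_equal(unname(b4), c(qlogis(0.4), 0))
  expect_error(fit_bin(c(0, 1), c(0.2, 0.5, 0.7)), "length")
  expect_error(fit_bin(1, 0.5), "underdetermined")
})

test_that("huber loss agrees with l2 on clean data and resists an outlier", {
  set.seed(43)
  r <- seq(0, 1, length.out = 10)
  pr <- plogis(-1 + 2 * r)
  expect_equal(
    fit_bin(r, pr, loss = "huber"), fit_bin(r, pr, loss = "l2"),
    tolerance = 1e-6
  )
  pr_out <- pr
  pr_out[10] <- 0.999 # gross outlier on the logit scale
  err_l2 <- abs(fit_bin(r, pr_out, loss = "l2")["feature_1"] - 2)
  err_hub <- abs(fit_bin(r, pr_out, loss = "huber")["feature_1"] - 2)
  expect_lt(err_hub, err_l2)
})

test_that("fit_coefficient_table fits K - 1 rows and recovers a noiseless
           logit-linear family exactly", {
  K <- 50
  beta <- monotone_beta(K)
  fam <- simulate_null_family(c(0, 0.25, 0.5, 0.75, 1), beta, K = K)
  ct <- fit_coefficient_table(fam$nulls, fam$features)
  expect_equal(nrow(ct), K - 1)
  expect_equal(attr(ct, "K"), K)
  expect_lt(max(abs(cbind(ct$intercept, ct$feature_1) - beta)), 1e-6)
  # identical nulls with distinct features -> zero slopes
  same <- simulate_null_family(c(0.1, 0.9), cbind(qlogis((1:9) / 10), 0),
    K = 10
  )
  ct0 <- fit_coefficient_table(same$nulls, same$features)
  expect_equal(ct0$feature_1, rep(0, 9))
  # mismatched bin structure across nulls
  other <- simulate_null_family(0.5, cbind(qlogis((1:19) / 20), 0), K = 20)
  expect_error(
    fit_coefficient_table(
      c(fam$nulls[1], other$nulls),
      tibble::tibble(r_1 = c(0, 0.5))
    ),
    "mismatched bin structure"
  )
})

test_that("noisy-fit coefficients still track the generating coefficients", {
  K <- 50
  beta <- monotone_beta(K)
  fam <- simulate_null_family(seq(0, 1, length.out = 10), beta,
    K = K, noise_sd = 0.1, seed = 99
  )
  ct <- fit_coefficient_table(fam$nulls, fam$features)
  expect_gt(cor(ct$intercept, beta[, 1]), 0.95)
  expect_gt(cor(ct$feature_1, beta[, 2]), 0.95)
})

test_that("predict_cum_prob evaluates the logistic link", {
  expect_equal(predict_cum_prob(c(0, 0), r0 = 0.7), 0.5)
  # printed reference coefficients, feature 0: direct link evaluation
  expect_equal(
    predict_cum_prob(c(-6.0539, -18.607), r0 = 0),
    1 / (1 + exp(6.0539))
  )
  # monotone in the linear term; extreme terms stay inside (0, 1)
  etas <- vapply(
    seq(-5, 5, by = 1),
    function(b1) predict_cum_prob(c(0, b1), r0 = 1), numeric(1)
  )
  expect_true(all(diff(etas) > 0))
  expect_gt(predict_cum_prob(c(-1e9, 0), r0 = 0), 0)
  expect_lt(predict_cum_prob(c(1e9, 0), r0 = 0), 1)
})

test_that("infer_null differences the predicted CDF into a valid density", {
  # hand-checkable K = 3 table: coefficients chosen so that at r0 = 0 the
  # predicted cumulative sequence is (0.2, 0.5), completed by 1
  ct <- permfdr:::coef_table_from_parts(
    data.frame(
      bin = 1:2, intercept = qlogis(c(0.2, 0.5)), feature_1 = c(0, 0)
    ),
    list(
      K = 3, J = 1, bin_width = 1 / 3, lo = 0, hi = 1,
      loss = "l2", clip_eps = 1e-6
    )
  )
  nd <- infer_null(ct, 0.4)
  expect_equal(nd$density, c(0.2, 0.3, 0.5))
  # constant-zero coefficients: cumulative (0.5, 0.5, 1)
  ct0 <- permfdr:::coef_table_from_parts(
    data.frame(bin = 1:2, intercept = c(0, 0), feature_1 = c(0, 0)),
    list(
      K = 3, J = 1, bin_width = 1 / 3, lo = 0, hi = 1,
      loss = "l2", clip_eps = 1e-6
    )
  )
  expect_equal(infer_null(ct0, 1.23)$density, c(0.5, 0, 0.5))
})

test_that("non-monotone predictions are repaired isotonic and all inferred
           nulls satisfy the density invariants", {
  # deliberately non-monotone: bin 2 predicts below bin 1
  ct <- permfdr:::coef_table_from_parts(
    data.frame(
      bin = 1:3, intercept = qlogis(c(0.6, 0.4, 0.7)), feature_1 = rep(0, 3)
    ),
    list(
      K = 4, J = 1, bin_width = 0.25, lo = 0, hi = 1,
      loss = "l2", clip_eps = 1e-6
    )
  )
  nd <- infer_null(ct, 0)
  expect_true(all(nd$density >= 0))
  expect_equal(sum(nd$density), 1)
  expect_true(all(diff(nd$cum) >= 0))
  # isotonic projection pools the violating pair to its mean
  expect_equal(nd$cum[1:2], c(0.5, 0.5))
  set.seed(47)
  for (i in 1:10) {
    K <- sample(5:40, 1)
    tab <- data.frame(
      bin = seq_len(K - 1),
      intercept = rnorm(K - 1, 0, 2), # wildly non-monotone
      feature_1 = rnorm(K - 1)
    )
    ct <- permfdr:::coef_table_from_parts(
      tab,
      list(
        K = K, J = 1, bin_width = 1 / K, lo = 0, hi = 1,
        loss = "l2", clip_eps = 1e-6
      )
    )
    nd <- infer_null(ct, runif(1))
    expect_true(all(nd$density >= -1e-12))
    expect_equal(sum(nd$density), 1)
    expect_true(all(diff(nd$cum) >= -1e-12))
  }
})

test_that("round trip: inference at a training feature reproduces that
           training null", {
  K <- 50
  beta <- monotone_beta(K)
  feats <- c(0, 0.25, 0.5, 0.75, 1)
  fam <- simulate_null_family(feats, beta, K = K)
  ct <- fit_coefficient_table(fam$nulls, fam$features)
  for (i in c(1, 3, 5)) {
    nd <- infer_null(ct, feats[i])
    expect_lt(max(abs(nd$density - fam$nulls[[i]]$density)), 1e-6)
  }
})

test_that("coefficient table TSV + sidecar round trip is lossless", {
  fam <- simulate_null_family(c(0, 0.5, 1), monotone_beta(10), K = 10)
  ct <- fit_coefficient_table(fam$nulls, fam$features)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coef_table(ct, path)
  ct2 <- read_coef_table(path)
  expect_equal(tidy(ct2), tidy(ct))
  expect_equal(glance(ct2), glance(ct))
  expect_error(
    read_coef_table(file.path(tempdir(), "absent.tsv")),
    "missing"
  )
})
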