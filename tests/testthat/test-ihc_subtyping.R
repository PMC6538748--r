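rec <- function(er = NA, pr = NA, her2 = NA, fish = NA, ki67 = NA)
  list(er_ihc = er, pr_ihc = pr, her2_ihc = her2, her2_fish = fish,
       ki67_pct = ki67)

test_that("marker thresholds follow the clinical conventions", {
  # ER/PR positive only strictly above 1% staining
  expect_equal(call_marker_status(rec(er = 1))[["er"]], "negative")
  expect_equal(call_marker_status(rec(er = 1.5))[["er"]], "positive")
  # HER2 2+ resolved by FISH
  expect_equal(call_marker_status(rec(her2 = "2+", fish = "amplified"))[["her2"]],
               "positive")
  expect_equal(call_marker_status(rec(her2 = "2+", fish = "not_amplified"))[["her2"]],
               "negative")
  expect_equal(call_marker_status(rec(her2 = "2+"))[["her2"]], "missing")
  expect_equal(call_marker_status(rec(her2 = "1+"))[["her2"]], "negative")
  expect_equal(call_marker_status(rec(her2 = "3+"))[["her2"]], "positive")
  # Ki67 boundary inclusive at 15%
  expect_equal(call_marker_status(rec(ki67 = 15))[["ki67"]], "positive")
  expect_equal(call_marker_status(rec(ki67 = 14.9))[["ki67"]], "negative")
  # categorical spellings accepted
  expect_equal(call_marker_status(rec(er = "pos"))[["er"]], "positive")
})

test_that("subtype grid covers the five classes and nothing else", {
  st <- function(er, pr, her2, ki67)
    call_ihc_subtype(c(er = er, pr = pr, her2 = her2, ki67 = ki67))
  expect_equal(st("negative", "negative", "negative", "positive"), "TN")
  expect_equal(st("negative", "negative", "positive", "missing"), "HER2+")
  expect_equal(st("positive", "negative", "positive", "negative"), "LB2")
  expect_equal(st("positive", "positive", "negative", "negative"), "LA")
  expect_equal(st("positive", "missing", "negative", "positive"), "LB1")
  # uncovered combinations are unassignable, not guessed
  expect_equal(st("negative", "positive", "negative", "negative"), "unassignable")
  expect_equal(st("negative", "negative", "missing", "negative"), "unassignable")
  expect_equal(st("positive", "negative", "negative", "missing"), "unassignable")
  expect_equal(st("missing", "negative", "negative", "negative"), "unassignable")
})

test_that("complete markers partition into exactly one of the five classes", {
  lv <- c("positive", "negative")
  grid <- expand.grid(er = lv, pr = lv, her2 = lv, ki67 = lv,
                      stringsAsFactors = FALSE)
  labs <- apply(grid, 1L, function(r) call_ihc_subtype(r))
  defined <- labs != "unassignable"
  expect_true(all(labs[defined] %in% c("TN", "HER2+", "LA", "LB1", "LB2")))
  # the only uncovered complete-marker combination is ER-/PR+
  expect_identical(sort(unique(paste(grid$er, grid$pr)[!defined])),
                   "negative positive")
})

kde_ref <- function(labels, values) {
  ids <- sprintf("R%04d", seq_along(values))
  list(ref = matrix(values, 1, dimnames = list("MKI67", ids)),
       labs = data.frame(sample_id = ids, label = labels,
                         stringsAsFactors = FALSE))
}

test_that("equal-size symmetric Gaussians cut at the midpoint", {
  set.seed(5)
  x <- kde_ref(rep(c("LA", "LB1"), each = 400),
               c(rnorm(400, 0, 1), rnorm(400, 4, 1)))
  ct <- derive_mki67_cutoff(x$ref, x$labs)
  expect_s3_class(ct, "mki67_cutoff")
  expect_equal(ct$cutoff_value, 2, tolerance = 0.15)
  expect_gt(ct$cutoff_value, ct$search_interval[["low"]])
  expect_lt(ct$cutoff_value, ct$search_interval[["high"]])
})

test_that("cutoff equals the fine-grid density-equality oracle", {
  set.seed(11)
  vals <- c(rnorm(200, 0, 1), rnorm(100, 3, 1))
  x <- kde_ref(rep(c("LA", "LB1"), c(200, 100)), vals)
  ct <- derive_mki67_cutoff(x$ref, x$labs)
  # independent brute-force scan of the two Gaussian KDEs at step 0.001
  bw_la <- stats::bw.nrd0(vals[1:200]); bw_lb <- stats::bw.nrd0(vals[201:300])
  f <- function(q, xs, bw) vapply(q, function(qi) mean(dnorm(qi, xs, bw)), 0)
  grid <- seq(ct$search_interval[["low"]], ct$search_interval[["high"]],
              by = 0.001)
  diffs <- f(grid, vals[1:200], bw_la) - f(grid, vals[201:300], bw_lb)
  oracle <- grid[which.min(abs(diffs))]
  expect_equal(ct$cutoff_value, oracle, tolerance = 0.002)
})

test_that("degenerate and swapped inputs behave as specified", {
  set.seed(3)
  same <- rnorm(60, 1, 0.5)
  x <- kde_ref(rep(c("LA", "LB1"), each = 30), c(same[1:30], same[1:30]))
  expect_error(derive_mki67_cutoff(x$ref, x$labs), "not ordered")

  # label swap + axis negation gives the negated cutoff
  vals <- c(rnorm(150, 0, 1), rnorm(150, 3, 1))
  a <- kde_ref(rep(c("LA", "LB1"), each = 150), vals)
  b <- kde_ref(rep(c("LB1", "LA"), each = 150), -vals)
  expect_equal(derive_mki67_cutoff(a$ref, a$labs)$cutoff_value,
               -derive_mki67_cutoff(b$ref, b$labs)$cutoff_value,
               tolerance = 1e-6)

  expect_error(derive_mki67_cutoff(a$ref[, 1:15, drop = FALSE],
                                   a$labs[1:15, ]), ">= 10")
  expect_error(derive_mki67_cutoff(matrix(1, 1, 30,
                 dimnames = list("OTHER", sprintf("R%04d", 1:30))), a$labs),
               "MKI67")
})

test_that("surrogate touches only ER+/HER2- samples and includes the boundary", {
  ihc <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                    er = c("positive", "positive", "negative", "positive"),
                    pr = "positive",
                    her2 = c("negative", "negative", "negative", "positive"),
                    ki67 = c("missing", "missing", "missing", "missing"),
                    label = c("unassignable", "unassignable", "TN", "LB2"),
                    stringsAsFactors = FALSE)
  target <- matrix(c(5, 3, 9, 9), 1,
                   dimnames = list("MKI67", c("S1", "S2", "S3", "S4")))
  out <- apply_mki67_surrogate(ihc, target, cutoff = 5)
  expect_equal(out$ki67, c("surrogate_positive", "surrogate_negative",
                           "missing", "missing"))
  expect_equal(out$label, c("LB1", "LA", "TN", "LB2"))
  expect_error(apply_mki67_surrogate(ihc, `rownames<-`(target, "X"), 5), "MKI67")
})
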