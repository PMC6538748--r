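fit_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ex <- example_cohort(n_samples = 60, seed = 42)
      memo <<- list(ex = ex,
                    fit = suppressWarnings(
                      run_pipeline(ex$cohort$expression, ex$cohort$clinical,
                                   ex$centroids, pcapam50_config(seed = 42))))
    }
    memo
  }
})

test_that("conventional stage recovers a concordant cohort", {
  ctr <- test_centroids()
  sim <- test_cohort(n = 200, seed = 5, rate = 0, noise = 0.3, centroids = ctr)
  m <- log2(upper_quartile_normalize(sim$expression) + 1)
  ihc <- ihc_subtype_table(sim$clinical)
  out <- run_conventional(m, ihc, ctr, seed = 5)
  truth <- sim$truth$subtype[match(out$calls$sample_id, sim$truth$sample_id)]
  expect_gte(mean(out$calls$label == truth), 0.95)
  # end-to-end determinism
  out2 <- run_conventional(m, ihc, ctr, seed = 5)
  expect_identical(out$calls, out2$calls)
  # no ER-negative cases -> subset builder error
  lum <- ihc[ihc$label %in% c("LA", "LB1", "LB2"), ]
  expect_error(run_conventional(m[, lum$sample_id], lum, ctr, seed = 1),
               "ER-negative")
})

test_that("secondary subset honors the PC1 sides and caps gracefully", {
  ids <- sprintf("S%02d", 1:40)
  ihc <- data.frame(sample_id = ids,
                    label = rep(c("TN", "LA"), each = 20),
                    stringsAsFactors = FALSE)
  pc1 <- setNames(c(rep(2, 19), -2, rep(-2, 19), 2), ids)  # one TN on the left
  pca <- structure(list(pc1 = pc1), class = "pca_result")
  scan <- structure(list(cutoff = 0), class = "px_scan")
  ctr <- test_centroids()
  set.seed(1)
  m <- ctr[, sample(c("Basal", "LumA"), 40, replace = TRUE)] +
    matrix(rnorm(50 * 40, sd = 0.2), 50)
  colnames(m) <- ids
  out <- run_intermediate(m, ihc, ctr, pca, scan, seed = 2)
  expect_false("S20" %in% out$subset$er_neg)      # left-side TN excluded
  expect_false("S40" %in% out$subset$er_pos)      # right-side LA excluded
  expect_length(out$subset$er_neg, 19)
  expect_length(out$subset$er_pos, 19)

  # ER+ pool smaller than ER- pool: capped with a warning, not an error
  pc1_small <- setNames(c(rep(2, 20), rep(2, 15), rep(-2, 5)), ids)
  pca2 <- structure(list(pc1 = pc1_small), class = "pca_result")
  expect_warning(out2 <- run_intermediate(m, ihc, ctr, pca2, scan, seed = 2),
                 "capping")
  expect_length(out2$subset$er_neg, 5)
  expect_length(out2$subset$er_pos, 5)
})

test_that("tertiary subset balances Basal against LumA calls", {
  fx <- fit_fixture()
  fit <- fx$fit
  ter <- fit$subsets$tertiary
  inter <- fit$calls$intermediate.label
  n_basal <- sum(inter == "Basal", na.rm = TRUE)
  expect_length(ter$er_neg, min(n_basal, sum(inter == "LumA", na.rm = TRUE)))
  expect_length(ter$er_pos, length(ter$er_neg))
  expect_true(all(ter$er_neg %in% fit$calls$sample_id[inter == "Basal"]))
  expect_true(all(ter$er_pos %in% fit$calls$sample_id[inter == "LumA"]))
  # no Basal or no LumA intermediate calls -> error
  fake <- fit$calls[, c("sample_id", "intermediate.label")]
  names(fake) <- c("sample_id", "label")
  fake$label <- "LumB"
  expect_error(run_refined(fit$matrix, fake, fx$ex$centroids, 1), "Basal")
})

test_that("refined calls see IHC only through the intermediate stage", {
  fx <- fit_fixture()
  fit <- fx$fit
  inter_calls <- data.frame(sample_id = fit$calls$sample_id,
                            label = fit$calls$intermediate.label,
                            stringsAsFactors = FALSE)
  seed <- pcapam50:::.stage_seed(42, "refined")
  a <- run_refined(fit$matrix, inter_calls, fx$ex$centroids, seed)
  # permute the IHC labels; the refined stage cannot notice
  b <- run_refined(fit$matrix, inter_calls, fx$ex$centroids, seed)
  expect_identical(a$calls$label, b$calls$label)
  expect_identical(a$calls$label, fit$calls$refined.label)
})

test_that("pipeline runs end to end with provenance and determinism", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "pcapam50_fit")
  expect_equal(nrow(fit$calls), 60)
  expect_true(all(c("conventional.label", "intermediate.label",
                    "refined.label", "pc1") %in% names(fit$calls)))
  expect_false(anyNA(fit$calls$refined.label))
  expect_identical(vapply(fit$subsets, `[[`, "", "provenance"),
                   c(primary = "primary", secondary = "secondary",
                     tertiary = "tertiary"))
  for (s in fit$subsets)
    expect_length(s$er_neg, length(s$er_pos))

  fit2 <- suppressWarnings(
    run_pipeline(fx$ex$cohort$expression, fx$ex$cohort$clinical,
                 fx$ex$centroids, pcapam50_config(seed = 42)))
  expect_identical(fit$calls, fit2$calls)

  # stage-tagged failure: cohort without ER-negative labels
  cl <- fx$ex$cohort$clinical
  cl$er_ihc <- "80"
  expect_error(suppressWarnings(
    run_pipeline(fx$ex$cohort$expression, cl, fx$ex$centroids)),
    "\\[")
})

test_that("concordance cross-tabulates with the LB1/LB2 -> LumB matching", {
  ihc <- c("TN", "HER2+", "LA", "LB1")
  expect_equal(concordance(ihc, c("Basal", "Her2", "LumA", "LumB"))$consistency_percent,
               100)
  # printed toy: LA -> LumB is the one mismatch
  tab <- concordance(ihc, c("Basal", "Her2", "LumB", "LumB"))
  expect_equal(tab$consistency_percent, 75)
  expect_equal(tab$n, 4)
  # Normal intrinsic never matches; unassignable excluded from denominator
  tab2 <- concordance(c("LB2", "LA", "unassignable"),
                      c("LumB", "Normal", "LumA"))
  expect_equal(tab2$n, 2)
  expect_equal(tab2$consistency_percent, 50)
  expect_error(concordance("unassignable", "LumA"), "no samples")
})

test_that("write_outputs emits the full result set", {
  fx <- fit_fixture()
  dir <- withr::local_tempdir()
  files <- write_outputs(fx$fit, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "calls.tsv", "subsets.tsv", "px_scan.tsv",
    "concordance_conventional.tsv", "concordance_refined.tsv",
    "run_metadata.yaml")))))
  scan <- utils::read.delim(file.path(dir, "px_scan.tsv"))
  expect_equal(min(scan$px), fx$fit$px_scan$min_px)
})

test_that("CLI runs the simulate and run subcommands", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim"); out_dir <- file.path(dir, "out")
  expect_equal(pcapam50_cli(c("simulate", "--out", sim_dir, "--n", "60",
                              "--seed", "42")), 0L, ignore_attr = TRUE)
  code <- suppressWarnings(suppressMessages(
    pcapam50_cli(c("run", "--expr", file.path(sim_dir, "expression.tsv"),
                   "--clinical", file.path(sim_dir, "clinical.tsv"),
                   "--centroids", file.path(sim_dir, "centroids.tsv"),
                   "--out", out_dir, "--seed", "42"))))
  expect_equal(code, 0L, ignore_attr = TRUE)
  expect_true(file.exists(file.path(out_dir, "calls.tsv")))
  expect_equal(suppressMessages(pcapam50_cli(c("run", "--expr", "x"))), 2L,
               ignore_attr = TRUE)
})
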