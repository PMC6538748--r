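# Three-stage PCA-PAM50 orchestration.
#
# Stage 1 (conventional): center on the IHC-derived primary ER-balanced
# subset and classify. Stage 2 (intermediate): locate the expression ER
# boundary on PC1, build the secondary subset from samples whose PC1 side
# agrees with their IHC class, re-center, re-classify. Stage 3 (refined):
# build the tertiary subset from the intermediate Basal and LumA calls —
# no IHC information enters this stage — re-center, re-classify.

#' Default pipeline configuration
#'
#' @param seed Pipeline-level integer seed; per-stage seeds are derived from
#'   it deterministically so stages are independently reproducible.
#' @param corr_method `"spearman"` or `"pearson"` for [classify()].
#' @param normalize Upper-quartile normalize the input (default TRUE).
#' @param log2_transform log2(x+1)-transform after normalization (default
#'   TRUE; appropriate for count-like RNA-Seq input, where centroid
#'   correlation on the raw scale is dominated by magnitude outliers).
#' @param uq_target Upper-quartile target value.
#' @param mki67_gene_id Gene id used by the Ki67 expression surrogate.
#' @param er_pr_pct_threshold,ki67_pct_threshold IHC thresholds.
#' @return Named list of configuration values.
#' @export
pcapam50_config <- function(seed = 1L,
                            corr_method = "spearman",
                            normalize = TRUE,
                            log2_transform = TRUE,
                            uq_target = 1000,
                            mki67_gene_id = "MKI67",
                            er_pr_pct_threshold = 1,
                            ki67_pct_threshold = 15) {
  list(seed = as.integer(seed), corr_method = corr_method,
       normalize = normalize, log2_transform = log2_transform,
       uq_target = uq_target, mki67_gene_id = mki67_gene_id,
       er_pr_pct_threshold = er_pr_pct_threshold,
       ki67_pct_threshold = ki67_pct_threshold)
}

#' @noRd
.stage_seed <- function(seed, stage) {
  # deterministic per-stage offset from the stage name; stays < 2^31
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131 + h) %% 2147483647)
}

#' @noRd
.er_class <- function(ihc) {
  er <- rep(NA_character_, nrow(ihc))
  er[ihc$label %in% c("LA", "LB1", "LB2")] <- "pos"
  er[ihc$label %in% c("TN", "HER2+")] <- "neg"
  stats::setNames(er, ihc$sample_id)
}

#' Conventional stage: primary subset, center, classify
#'
#' @param m genes x samples normalized (and log-transformed) matrix.
#' @param ihc IHC subtype table ([ihc_subtype_table()]).
#' @param centroids Centroid matrix.
#' @param seed Stage seed.
#' @param corr_method Correlation method for [classify()].
#' @return list with `calls` (classification data.frame) and `subset`.
#' @export
run_conventional <- function(m, ihc, centroids, seed = 1L,
                             corr_method = "spearman") {
  subset <- build_primary_subset(ihc, seed)
  calls <- classify(median_center(m, subset), centroids, corr_method)
  list(calls = calls, subset = subset)
}

#' Intermediate stage: PC1-filtered secondary subset, center, classify
#'
#' ER-negative half: TN and HER2+ samples on the right (ER-negative) side of
#' the PC1 cutoff. ER-positive half: an equal count drawn from the LA, LB1,
#' LB2 samples on the left side. If the eligible ER+ pool is smaller, the
#' subset is capped at the smaller pool with a warning.
#'
#' @inheritParams run_conventional
#' @param pca `pca_result` from [run_pca()].
#' @param px_scan `px_scan` from [find_cutoff()].
#' @return list with `calls` and `subset`.
#' @export
run_intermediate <- function(m, ihc, centroids, pca, px_scan, seed = 1L,
                             corr_method = "spearman") {
  sides <- split_by_cutoff(pca$pc1, px_scan)
  er_neg <- intersect(ihc$sample_id[ihc$label %in% c("TN", "HER2+")], sides$right)
  er_pos_pool <- intersect(ihc$sample_id[ihc$label %in% c("LA", "LB1", "LB2")],
                           sides$left)
  subset <- .balanced_subset(er_neg, er_pos_pool, "secondary", seed, cap = TRUE)
  calls <- classify(median_center(m, subset), centroids, corr_method)
  list(calls = calls, subset = subset)
}

#' Refined stage: tertiary subset from intermediate Basal/LumA calls
#'
#' ER-negative half: every intermediate Basal call. ER-positive half: an
#' equal count drawn from the intermediate LumA calls. Only the intermediate
#' labels enter; IHC plays no role in this stage.
#'
#' @inheritParams run_conventional
#' @param intermediate_calls Classification data.frame from the
#'   intermediate stage.
#' @return list with `calls` and `subset`.
#' @export
run_refined <- function(m, intermediate_calls, centroids, seed = 1L,
                        corr_method = "spearman") {
  er_neg <- intermediate_calls$sample_id[intermediate_calls$label %in% "Basal"]
  er_pos_pool <- intermediate_calls$sample_id[intermediate_calls$label %in% "LumA"]
  if (length(er_neg) == 0L || length(er_pos_pool) == 0L)
    stop("tertiary subset: intermediate stage produced ", length(er_neg),
         " Basal and ", length(er_pos_pool), " LumA calls", call. = FALSE)
  subset <- .balanced_subset(er_neg, er_pos_pool, "tertiary", seed, cap = TRUE)
  calls <- classify(median_center(m, subset), centroids, corr_method)
  list(calls = calls, subset = subset)
}

#' Run the full PCA-PAM50 pipeline
#'
#' Normalization, IHC subtyping (with the MKI67 surrogate when Ki67 IHC is
#' absent and `mki67_cutoff` is supplied), the conventional stage, the PC1
#' misclassification scan, and the intermediate and refined stages. All
#' seeds, the cutoff, and the three subsets are recorded for provenance.
#'
#' @param m genes x samples nonnegative expression matrix (restricted or
#'   restrictable to the centroid panel).
#' @param clinical Clinical table from [read_clinical()], or a pre-built IHC
#'   table from [ihc_subtype_table()] (recognized by its `label` column).
#' @param centroids Centroid matrix.
#' @param config List from [pcapam50_config()].
#' @param mki67_cutoff Optional `mki67_cutoff` (or numeric) applied to
#'   ER+/HER2- samples with missing Ki67 before subtyping.
#' @return Object of class `pcapam50_fit`: list with `calls` (wide per-sample
#'   data.frame), `subsets`, `px_scan`, `pca`, `ihc`, `config`, `matrix`
#'   (the processed matrix used for classification).
#' @export
run_pipeline <- function(m, clinical, centroids, config = pcapam50_config(),
                         mki67_cutoff = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  .check_expression(m)
  if (config$normalize)
    m <- stage("normalize", upper_quartile_normalize(m, config$uq_target))
  if (config$log2_transform) m <- log2(m + 1)

  ihc <- stage("ihc", {
    tab <- if ("label" %in% names(clinical)) clinical
      else ihc_subtype_table(clinical, config$er_pr_pct_threshold,
                             config$ki67_pct_threshold)
    if (!is.null(mki67_cutoff))
      tab <- apply_mki67_surrogate(tab, m, mki67_cutoff, config$mki67_gene_id)
    tab
  })
  ihc <- ihc[match(colnames(m), ihc$sample_id), , drop = FALSE]
  if (anyNA(ihc$sample_id))
    stop("[ihc] clinical record missing for sample(s): ",
         paste(utils::head(setdiff(colnames(m), ihc$sample_id[!is.na(ihc$sample_id)]), 5L),
               collapse = ", "), call. = FALSE)

  conv <- stage("conventional",
    run_conventional(m, ihc, centroids, .stage_seed(config$seed, "conventional"),
                     config$corr_method))
  pca <- stage("pca", run_pca(m, .er_class(ihc)))
  scan <- stage("pca", find_cutoff(pca$pc1, .er_class(ihc)))
  inter <- stage("intermediate",
    run_intermediate(m, ihc, centroids, pca, scan,
                     .stage_seed(config$seed, "intermediate"), config$corr_method))
  refined <- stage("refined",
    run_refined(m, inter$calls, centroids, .stage_seed(config$seed, "refined"),
                config$corr_method))

  calls <- .assemble_calls(ihc, conv$calls, inter$calls, refined$calls, pca)
  structure(list(calls = calls,
                 subsets = list(primary = conv$subset,
                                secondary = inter$subset,
                                tertiary = refined$subset),
                 px_scan = scan, pca = pca, ihc = ihc,
                 config = config, matrix = m),
            class = "pcapam50_fit")
}

#' @noRd
.assemble_calls <- function(ihc, conv, inter, refined, pca) {
  wide <- function(calls, prefix) {
    if (is.null(calls)) {
      out <- data.frame(label = rep(NA_character_, nrow(ihc)))
      for (s in SUBTYPES) out[[paste0("cor.", s)]] <- NA_real_
    } else {
      out <- calls[match(ihc$sample_id, calls$sample_id), -1L, drop = FALSE]
    }
    names(out) <- paste0(prefix, ".", names(out))
    rownames(out) <- NULL
    out
  }
  cbind(data.frame(sample_id = ihc$sample_id, ihc_subtype = ihc$label,
                   stringsAsFactors = FALSE),
        wide(conv, "conventional"), wide(inter, "intermediate"),
        wide(refined, "refined"),
        data.frame(pc1 = unname(pca$pc1[ihc$sample_id])))
}

#' @export
print.pcapam50_fit <- function(x, ...) {
  cat("PCA-PAM50 fit:", nrow(x$calls), "samples\n")
  cat("  PC1 cutoff:", signif(x$px_scan$cutoff, 6),
      "(Px =", signif(x$px_scan$min_px, 4), "%)\n")
  cat("  subset sizes (neg+pos): primary ",
      length(x$subsets$primary$er_neg), "+", length(x$subsets$primary$er_pos),
      ", secondary ", length(x$subsets$secondary$er_neg), "+",
      length(x$subsets$secondary$er_pos),
      ", tertiary ", length(x$subsets$tertiary$er_neg), "+",
      length(x$subsets$tertiary$er_pos), "\n", sep = "")
  cat("  refined calls:\n")
  print(table(x$calls$refined.label, useNA = "ifany"))
  invisible(x)
}

# -- concordance --------------------------------------------------------------

#' Default IHC-to-intrinsic matching map
#'
#' IHC LB1 and LB2 both match intrinsic LumB; intrinsic Normal matches no
#' IHC class and always counts as disagreement.
#' @export
IHC_INTRINSIC_MATCH <- c("TN" = "Basal", "HER2+" = "Her2", "LA" = "LumA",
                         "LB1" = "LumB", "LB2" = "LumB")

#' Cross-tabulate IHC against intrinsic subtype calls
#'
#' @param ihc_labels Named (by sample) or parallel vector of IHC labels.
#' @param intrinsic_labels Vector of intrinsic labels, same samples.
#' @param matching Named map IHC label -> matching intrinsic label.
#' @return Object of class `concordance_table`: list with `counts` (IHC x
#'   intrinsic contingency matrix), `consistency_percent`, `n`, `matching`.
#'   Samples with an unassignable/missing label on either side are excluded.
#' @export
concordance <- function(ihc_labels, intrinsic_labels,
                        matching = IHC_INTRINSIC_MATCH) {
  stopifnot(length(ihc_labels) == length(intrinsic_labels))
  keep <- ihc_labels %in% names(matching) & intrinsic_labels %in% SUBTYPES
  if (!any(keep)) stop("no samples with both labels defined", call. = FALSE)
  ih <- factor(ihc_labels[keep], levels = names(matching))
  it <- factor(intrinsic_labels[keep], levels = SUBTYPES)
  counts <- table(IHC = ih, intrinsic = it)
  matched <- sum(vapply(names(matching), function(l)
    counts[l, matching[[l]]], 0))
  structure(list(counts = counts,
                 consistency_percent = 100 * matched / sum(counts),
                 n = sum(counts), matching = matching),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("consistency: %.2f%% of %d samples\n",
              x$consistency_percent, x$n))
  invisible(x)
}
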