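# Upper-quartile normalization, ER-balanced median gene-centering, and
# nearest-centroid classification against the PAM50 subtype centroids.

#' Upper-quartile normalize an expression matrix
#'
#' Scales each sample (column) so its 75th percentile over its *nonzero*
#' genes equals `target_value`. The percentile uses linear interpolation
#' between order statistics (`stats::quantile` type 7); upper-quartile
#' values differ across percentile conventions, so this is fixed and
#' documented. Missing values are ignored in the quantile.
#'
#' @param m genes x samples nonnegative matrix.
#' @param target_value Positive scalar the upper quartile is scaled to
#'   (default 1000; recorded in pipeline metadata because downstream log2
#'   classification is only approximately invariant to it).
#' @return Matrix of the same shape, gene and sample order preserved.
#' @export
upper_quartile_normalize <- function(m, target_value = 1000) {
  .check_expression(m)
  stopifnot(target_value > 0)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    nz <- v[!is.na(v) & v > 0]
    if (length(nz) == 0L)
      stop("sample '", colnames(m)[j], "' has no nonzero expression", call. = FALSE)
    uq <- stats::quantile(nz, 0.75, type = 7, names = FALSE)
    m[, j] <- v * (target_value / uq)
  }
  m
}

#' Build the primary (IHC-based) ER-balanced subset
#'
#' ER-negative half: all TN and HER2+ samples. ER-positive half: an equal
#' count drawn uniformly without replacement from the LA, LB1 and LB2
#' samples. Cohorts are typically ER+ rich, so the negative pool sets the
#' subset size.
#'
#' @param ihc data.frame from [ihc_subtype_table()] (needs `sample_id`,
#'   `label`).
#' @param seed Integer seed for the ER+ draw.
#' @return Object of class `er_balanced_subset`: list with `er_neg`,
#'   `er_pos` (sample id vectors), `provenance`, `seed`.
#' @export
build_primary_subset <- function(ihc, seed = 1L) {
  er_neg <- ihc$sample_id[ihc$label %in% c("TN", "HER2+")]
  er_pos_pool <- ihc$sample_id[ihc$label %in% c("LA", "LB1", "LB2")]
  .balanced_subset(er_neg, er_pos_pool, "primary", seed, cap = FALSE)
}

#' @noRd
.balanced_subset <- function(er_neg, er_pos_pool, provenance, seed, cap = TRUE) {
  if (length(er_neg) < 1L)
    stop(provenance, " subset: empty ER-negative pool", call. = FALSE)
  if (length(er_pos_pool) < 1L)
    stop(provenance, " subset: empty ER-positive pool", call. = FALSE)
  n <- length(er_neg)
  if (length(er_pos_pool) < n) {
    if (!cap)
      stop(provenance, " subset: ER-positive pool (", length(er_pos_pool),
           ") smaller than ER-negative pool (", n, ")", call. = FALSE)
    warning(provenance, " subset: ER-positive pool (", length(er_pos_pool),
            ") smaller than ER-negative pool (", n, "); capping both at ",
            length(er_pos_pool), call. = FALSE)
    n <- length(er_pos_pool)
    er_neg <- .seeded_sample(er_neg, n, seed + 1L)
  }
  er_pos <- .seeded_sample(er_pos_pool, n, seed)
  structure(list(er_neg = er_neg, er_pos = er_pos,
                 provenance = provenance, seed = seed),
            class = "er_balanced_subset")
}

#' @noRd
.seeded_sample <- function(x, n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  x[sample.int(length(x), n)]
}

#' Median-center genes using an ER-balanced subset
#'
#' For each gene, subtracts the median computed over the subset samples only
#' from *every* sample in the cohort. Centering with a balanced reference
#' makes an ER-skewed cohort comparable to centroids trained on a balanced
#' one.
#'
#' @param m genes x samples matrix.
#' @param subset `er_balanced_subset`, or a character vector of sample ids.
#' @return Centered matrix (may contain negatives).
#' @export
median_center <- function(m, subset) {
  ids <- if (inherits(subset, "er_balanced_subset"))
    c(subset$er_neg, subset$er_pos) else as.character(subset)
  absent <- setdiff(ids, colnames(m))
  if (length(absent))
    stop("subset sample(s) absent from matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  med <- apply(m[, ids, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  m - med
}

#' Nearest-centroid PAM50 classification
#'
#' Correlates each sample's centered profile with each of the five subtype
#' centroids over the shared gene panel and assigns the subtype with the
#' maximal correlation. Spearman rank correlation is the default, matching
#' the single-sample convention of common PAM50 deployments; Pearson is
#' available. Ties (measure-zero on real data) are broken by the fixed
#' priority `Basal, Her2, LumA, LumB, Normal` with a warning.
#'
#' A sample with a constant profile over the shared genes has undefined
#' correlations and is labeled `NA` (unclassifiable). A sample missing more
#' than 20% of the shared panel is rejected with an error.
#'
#' @param m_centered genes x samples centered matrix.
#' @param centroids genes x 5 centroid matrix from [read_centroids()] or
#'   [make_centroids()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: `sample_id`, `label`, and five correlation columns
#'   `cor.Basal .. cor.Normal`.
#' @export
classify <- function(m_centered, centroids, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(rownames(m_centered), rownames(centroids))
  if (length(shared) < 40L)
    stop("only ", length(shared), " genes shared with centroids; >= 40 required",
         call. = FALSE)
  x <- m_centered[shared, , drop = FALSE]
  ctr <- centroids[shared, SUBTYPES, drop = FALSE]
  n_sample <- ncol(x)
  cors <- matrix(NA_real_, n_sample, 5L, dimnames = list(colnames(x), SUBTYPES))
  labels <- rep(NA_character_, n_sample)
  tie_hit <- FALSE
  for (j in seq_len(n_sample)) {
    v <- x[, j]
    ok <- !is.na(v)
    if (mean(ok) < 0.8)
      stop("sample '", colnames(x)[j], "' missing more than 20% of panel genes",
           call. = FALSE)
    if (stats::sd(v[ok]) == 0) next  # constant profile: unclassifiable
    cors[j, ] <- suppressWarnings(
      stats::cor(v[ok], ctr[ok, , drop = FALSE], method = method))
    mx <- max(cors[j, ])
    hits <- which(cors[j, ] == mx)
    if (length(hits) > 1L) tie_hit <- TRUE
    labels[j] <- SUBTYPES[hits[1L]]
  }
  if (tie_hit)
    warning("correlation tie(s) broken by subtype priority order", call. = FALSE)
  out <- data.frame(sample_id = colnames(x), label = labels,
                    stringsAsFactors = FALSE)
  colnames(cors) <- paste0("cor.", SUBTYPES)
  cbind(out, as.data.frame(cors, row.names = NULL))
}
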