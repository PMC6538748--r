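# Clinical subtyping from immunohistochemistry biomarkers.
#
# ER/PR call follows the ASCO/CAP rule: positive iff nuclear staining
# strictly exceeds 1%. HER2: 0/1+ negative, 3+ positive, 2+ arbitrated by
# FISH. Ki67: positive iff staining >= 15%. Subtype grid:
#   TN    ER-/PR-/HER2-        LB2  ER+/HER2+
#   HER2+ ER-/PR-/HER2+        LA   ER+/HER2-/Ki67-
#                              LB1  ER+/HER2-/Ki67+
# Any uncovered combination (e.g. ER-/PR+) is 'unassignable' and is excluded
# from ER-balanced pools and concordance denominators.

#' @noRd
.pct_or_cat <- function(x, threshold) {
  # percent staining or categorical positive/negative -> status
  if (is.na(x)) return("missing")
  xl <- tolower(trimws(as.character(x)))
  if (xl %in% c("positive", "pos", "+")) return("positive")
  if (xl %in% c("negative", "neg", "-")) return("negative")
  v <- suppressWarnings(as.numeric(xl))
  if (is.na(v)) return("missing")
  if (v > threshold) "positive" else "negative"
}

#' Call per-marker IHC statuses for one clinical record
#'
#' @param record One-row data.frame (or list) with fields `er_ihc`, `pr_ihc`,
#'   `her2_ihc`, `her2_fish`, `ki67_pct` as produced by [read_clinical()].
#' @param er_pr_pct_threshold ER/PR positivity threshold on percent nuclear
#'   staining, exclusive (default 1: positive iff > 1%).
#' @param ki67_pct_threshold Ki67 positivity threshold, inclusive (default
#'   15: positive iff >= 15%).
#' @return Named character vector `c(er=, pr=, her2=, ki67=)` with values in
#'   `positive`/`negative`/`missing`.
#' @export
call_marker_status <- function(record, er_pr_pct_threshold = 1,
                               ki67_pct_threshold = 15) {
  er <- .pct_or_cat(record$er_ihc, er_pr_pct_threshold)
  pr <- .pct_or_cat(record$pr_ihc, er_pr_pct_threshold)
  her2 <- "missing"
  h <- record$her2_ihc
  if (!is.na(h)) {
    her2 <- switch(as.character(h),
      "0" = , "1+" = "negative",
      "3+" = "positive",
      "2+" = {
        f <- record$her2_fish
        if (is.na(f)) "missing"
        else if (f == "amplified") "positive" else "negative"
      },
      stop("invalid her2_ihc value: ", h, call. = FALSE))
  }
  k <- suppressWarnings(as.numeric(record$ki67_pct))
  ki67 <- if (is.na(k)) "missing" else if (k >= ki67_pct_threshold) "positive" else "negative"
  c(er = er, pr = pr, her2 = her2, ki67 = ki67)
}

#' Derive the clinical subtype label from marker statuses
#'
#' @param statuses Named vector from [call_marker_status()].
#' @return Label: one of `TN`, `HER2+`, `LA`, `LB1`, `LB2`, `unassignable`.
#' @export
call_ihc_subtype <- function(statuses) {
  er <- statuses[["er"]]; pr <- statuses[["pr"]]
  her2 <- statuses[["her2"]]; ki67 <- statuses[["ki67"]]
  if (er == "positive") {
    if (her2 == "positive") return("LB2")
    if (her2 == "negative") {
      if (ki67 == "positive") return("LB1")
      if (ki67 == "negative") return("LA")
    }
    return("unassignable")
  }
  if (er == "negative" && pr == "negative") {
    if (her2 == "negative") return("TN")
    if (her2 == "positive") return("HER2+")
  }
  "unassignable"
}

#' IHC-subtype a whole clinical table
#'
#' @param clinical data.frame from [read_clinical()].
#' @inheritParams call_marker_status
#' @return data.frame: `sample_id`, statuses `er`, `pr`, `her2`, `ki67`, and
#'   `label`.
#' @export
ihc_subtype_table <- function(clinical, er_pr_pct_threshold = 1,
                              ki67_pct_threshold = 15) {
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    st <- call_marker_status(clinical[i, ], er_pr_pct_threshold, ki67_pct_threshold)
    data.frame(sample_id = clinical$sample_id[i],
               er = st[["er"]], pr = st[["pr"]], her2 = st[["her2"]],
               ki67 = st[["ki67"]], label = call_ihc_subtype(st),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# -- MKI67 surrogate cutoff ---------------------------------------------------

#' @noRd
.gauss_kde <- function(x, bw) {
  force(x); force(bw)
  function(q) vapply(q, function(qi) mean(stats::dnorm(qi, mean = x, sd = bw)), 0)
}

#' @noRd
.resolve_bw <- function(x, bw) {
  if (identical(bw, "silverman")) stats::bw.nrd0(x) else as.numeric(bw)
}

#' Derive an MKI67 expression cutoff separating IHC-LA from IHC-LB1
#'
#' When Ki67 IHC is unavailable, MKI67 gene expression substitutes for the
#' Ki67 protein in splitting ER+/HER2- cases into LA and LB1. The cutoff is
#' placed where the Gaussian-kernel density estimates of a reference
#' cohort's LA and LB1 groups are equal, between the two group modes. At
#' that point the pooled LA+LB1 mixture density crosses both group curves
#' simultaneously (up to mixture weights), so the equality point coincides
#' with the pooled-vs-group curve intersection and is the numerically better
#' conditioned target.
#'
#' The reference and target matrices must already be on a common scale;
#' harmonization is the caller's responsibility.
#'
#' @param reference genes x samples expression matrix containing
#'   `mki67_gene_id`.
#' @param reference_labels data.frame with `sample_id` and IHC `label`
#'   columns (from [ihc_subtype_table()]), containing at least 10 LA and 10
#'   LB1 samples present in `reference`.
#' @param mki67_gene_id Row name of the MKI67 gene (default `"MKI67"`).
#' @param bandwidth `"silverman"` (per-group `bw.nrd0`) or a numeric
#'   bandwidth used for both groups.
#' @param reference_cohort_id Free-text audit tag stored on the result.
#' @return Object of class `mki67_cutoff`: list with `cutoff_value`,
#'   `bandwidth` (named, per group), `search_interval` (the two modes),
#'   `reference_cohort_id`.
#' @export
derive_mki67_cutoff <- function(reference, reference_labels,
                                mki67_gene_id = "MKI67",
                                bandwidth = "silverman",
                                reference_cohort_id = NA_character_) {
  if (!mki67_gene_id %in% rownames(reference))
    stop("gene '", mki67_gene_id, "' absent from reference matrix", call. = FALSE)
  expr <- reference[mki67_gene_id, ]
  la_ids  <- reference_labels$sample_id[reference_labels$label == "LA"]
  lb1_ids <- reference_labels$sample_id[reference_labels$label == "LB1"]
  x_la  <- expr[intersect(la_ids,  colnames(reference))]
  x_lb1 <- expr[intersect(lb1_ids, colnames(reference))]
  x_la <- x_la[!is.na(x_la)]; x_lb1 <- x_lb1[!is.na(x_lb1)]
  if (length(x_la) < 10L || length(x_lb1) < 10L)
    stop("need >= 10 LA and >= 10 LB1 reference samples (got ",
         length(x_la), " / ", length(x_lb1), ")", call. = FALSE)
  bw_la  <- .resolve_bw(x_la,  bandwidth)
  bw_lb1 <- .resolve_bw(x_lb1, bandwidth)
  f_la  <- .gauss_kde(x_la,  bw_la)
  f_lb1 <- .gauss_kde(x_lb1, bw_lb1)
  rng <- range(c(x_la, x_lb1))
  pad <- 3 * max(bw_la, bw_lb1)
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = 2048L)
  mode_la  <- grid[which.max(f_la(grid))]
  mode_lb1 <- grid[which.max(f_lb1(grid))]
  if (mode_la >= mode_lb1)
    stop("groups not ordered: LA density mode (", signif(mode_la, 4),
         ") is not below LB1 mode (", signif(mode_lb1, 4), ")", call. = FALSE)
  diff_f <- function(q) f_la(q) - f_lb1(q)
  lo <- mode_la; hi <- mode_lb1
  if (diff_f(lo) <= 0 || diff_f(hi) >= 0)
    stop("no density crossing inside (", signif(lo, 4), ", ", signif(hi, 4), ")",
         call. = FALSE)
  root <- stats::uniroot(diff_f, c(lo, hi), tol = 1e-9)$root
  structure(list(cutoff_value = root,
                 bandwidth = c(LA = bw_la, LB1 = bw_lb1),
                 search_interval = c(low = mode_la, high = mode_lb1),
                 reference_cohort_id = reference_cohort_id),
            class = "mki67_cutoff")
}

#' @export
print.mki67_cutoff <- function(x, ...) {
  cat("MKI67 surrogate cutoff:", signif(x$cutoff_value, 6),
      "\n  search interval (modes):", signif(x$search_interval[1L], 4), "..",
      signif(x$search_interval[2L], 4),
      "\n  bandwidths (LA, LB1):", signif(x$bandwidth, 4), "\n")
  invisible(x)
}

#' Apply the MKI67 surrogate to ER+/HER2- samples lacking Ki67 IHC
#'
#' Sets Ki67 status to `surrogate_positive` when the sample's MKI67
#' expression is at or above the cutoff (boundary inclusive, mirroring the
#' Ki67 >= 15% IHC convention), `surrogate_negative` below it. Only samples
#' that are ER-positive / HER2-negative with missing Ki67 are touched; the
#' derived label then resolves to LB1 or LA.
#'
#' @param ihc data.frame from [ihc_subtype_table()].
#' @param target genes x samples expression matrix on the cutoff's scale.
#' @param cutoff `mki67_cutoff` object or a bare numeric threshold.
#' @param mki67_gene_id Row name of MKI67 in `target`.
#' @return `ihc` with `ki67` and `label` updated.
#' @export
apply_mki67_surrogate <- function(ihc, target, cutoff, mki67_gene_id = "MKI67") {
  if (!mki67_gene_id %in% rownames(target))
    stop("gene '", mki67_gene_id, "' absent from target matrix", call. = FALSE)
  cut_val <- if (inherits(cutoff, "mki67_cutoff")) cutoff$cutoff_value else as.numeric(cutoff)
  expr <- target[mki67_gene_id, ]
  eligible <- ihc$er == "positive" & ihc$her2 == "negative" &
    ihc$ki67 == "missing" & ihc$sample_id %in% colnames(target)
  for (i in which(eligible)) {
    v <- expr[[ihc$sample_id[i]]]
    if (is.na(v)) next
    pos <- v >= cut_val
    ihc$ki67[i]  <- if (pos) "surrogate_positive" else "surrogate_negative"
    ihc$label[i] <- if (pos) "LB1" else "LA"
  }
  ihc
}
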