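# Expression-based ER separation: PCA on the PAM50 panel, a deterministic
# PC1 orientation, and a cutoff minimizing the Px misclassification
# statistic between IHC ER classes.
#
#   Px(x) = (Rx/R + Nx/N) * 100
#
# where Rx counts IHC ER-positive cases with PC1 >= x (boundary inclusive)
# and Nx counts IHC ER-negative cases with PC1 < x. Under the orientation
# convention ER-positive cases sit on the negative PC1 side, so Px sums the
# two misclassified fractions and ranges over [0, 200].

#' Sample-space PCA of the PAM50 panel with deterministic PC1 orientation
#'
#' Runs PCA with samples as observations and genes as features, per-gene
#' mean-centered and unscaled. The sign of PC1 is an arbitrary reflection;
#' it is fixed, independently of input order, so that the mean PC1 of
#' IHC-ER-positive samples is at or below the mean of ER-negative samples
#' (ER+ on the negative axis).
#'
#' @param m genes x samples matrix (normalized, uncentered).
#' @param ihc_er Named character vector (or factor) sample -> `"pos"`/`"neg"`;
#'   samples with other/missing values are projected but ignored for
#'   orientation. Both classes must be represented.
#' @return Object of class `pca_result`: list with `pc1` (named numeric),
#'   `pc2`, `explained_variance_ratio_pc1`, `orientation_flipped`.
#' @export
run_pca <- function(m, ihc_er) {
  if (ncol(m) < 3L || nrow(m) < 2L)
    stop("PCA needs >= 3 samples and >= 2 genes", call. = FALSE)
  ihc_er <- as.character(ihc_er)[match(colnames(m), names(ihc_er))]
  names(ihc_er) <- colnames(m)
  pos <- names(ihc_er)[ihc_er %in% "pos"]
  neg <- names(ihc_er)[ihc_er %in% "neg"]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both ER classes must be represented (orientation undefined)", call. = FALSE)
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  pc1 <- p$x[, 1L]
  pc2 <- if (ncol(p$x) >= 2L) p$x[, 2L] else stats::setNames(rep(0, ncol(m)), colnames(m))
  flipped <- mean(pc1[pos]) > mean(pc1[neg])
  if (flipped) { pc1 <- -pc1; pc2 <- -pc2 }
  evr <- p$sdev[1L]^2 / sum(p$sdev^2)
  structure(list(pc1 = pc1, pc2 = pc2,
                 explained_variance_ratio_pc1 = evr,
                 orientation_flipped = flipped),
            class = "pca_result")
}

#' Percentage of misclassified ER cases at a PC1 point
#'
#' `Px = (Rx/R + Nx/N) * 100` with `Rx` the ER-positive cases at or right of
#' `x` and `Nx` the ER-negative cases strictly left of `x`.
#'
#' @param x Candidate PC1 value.
#' @param pc1 Named numeric vector of PC1 coordinates.
#' @param ihc_er Named vector sample -> `"pos"`/`"neg"`.
#' @return Px in percent, in `[0, 200]`.
#' @export
compute_px <- function(x, pc1, ihc_er) {
  er <- as.character(ihc_er)[match(names(pc1), names(ihc_er))]
  p <- pc1[er %in% "pos"]; n <- pc1[er %in% "neg"]
  R <- length(p); N <- length(n)
  if (R < 1L || N < 1L)
    stop("need at least one sample in each ER class (R=", R, ", N=", N, ")",
         call. = FALSE)
  (sum(p >= x) / R + sum(n < x) / N) * 100
}

#' Scan PC1 for the misclassification-minimizing ER cutoff
#'
#' Px is a step function of `x` that changes only at observed PC1 values, so
#' the default candidate set — every observed coordinate, the midpoint
#' between each pair of consecutive sorted coordinates, and one sentinel
#' beyond each extreme — attains the exact global minimum that any finite
#' grid can only approximate. Among equal-Px candidates the smallest `x`
#' is chosen.
#'
#' @inheritParams compute_px
#' @param candidates Optional explicit numeric candidate vector (e.g. a
#'   fixed grid); `NULL` uses the exact default set.
#' @return Object of class `px_scan`: list with `candidate_points`,
#'   `px_values`, `cutoff`, `min_px`, `R`, `N`, `Rx_at_cutoff`,
#'   `Nx_at_cutoff`.
#' @export
find_cutoff <- function(pc1, ihc_er, candidates = NULL) {
  if (is.null(candidates)) {
    s <- sort(unique(pc1))
    mids <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else numeric()
    candidates <- sort(c(s[1L] - 1, s, mids, s[length(s)] + 1))
  }
  if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  px <- vapply(candidates, compute_px, 0, pc1 = pc1, ihc_er = ihc_er)
  i <- which(px == min(px))[1L]  # smallest x attaining the minimum
  cutoff <- candidates[i]
  er <- as.character(ihc_er)[match(names(pc1), names(ihc_er))]
  p <- pc1[er %in% "pos"]; n <- pc1[er %in% "neg"]
  structure(list(candidate_points = candidates, px_values = px,
                 cutoff = cutoff, min_px = px[i],
                 R = length(p), N = length(n),
                 Rx_at_cutoff = sum(p >= cutoff),
                 Nx_at_cutoff = sum(n < cutoff)),
            class = "px_scan")
}

#' @export
print.px_scan <- function(x, ...) {
  cat("PC1 cutoff:", signif(x$cutoff, 6), " (Px =", signif(x$min_px, 4), "%)\n",
      " ER+ misclassified:", x$Rx_at_cutoff, "/", x$R,
      "  ER- misclassified:", x$Nx_at_cutoff, "/", x$N, "\n")
  invisible(x)
}

#' Partition samples at the PC1 cutoff
#'
#' Right side (`PC1 >= cutoff`) is the expression-ER-negative side under the
#' orientation convention; left side is ER-positive. The boundary sample
#' goes right, consistent with the `Rx` boundary inclusivity.
#'
#' @param pc1 Named PC1 coordinates.
#' @param cutoff Finite numeric cutoff (or a `px_scan`).
#' @return list with `left` and `right` character vectors of sample ids;
#'   a disjoint, exhaustive partition.
#' @export
split_by_cutoff <- function(pc1, cutoff) {
  if (inherits(cutoff, "px_scan")) cutoff <- cutoff$cutoff
  stopifnot(is.finite(cutoff))
  list(left  = names(pc1)[pc1 <  cutoff],
       right = names(pc1)[pc1 >= cutoff])
}
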