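#' Canonical intrinsic subtype names, in tie-break priority order
#'
#' Fixed order used for correlation tie-breaking in [classify()].
#' @export
SUBTYPES <- c("Basal", "Her2", "LumA", "LumB", "Normal")

#' Clinical (IHC) subtype labels
#' @export
IHC_LABELS <- c("TN", "HER2+", "LA", "LB1", "LB2", "unassignable")

# -- internal helpers ---------------------------------------------------------

#' @noRd
.sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else
    stop("cannot detect delimiter (tab or comma) in ", path,
         "; pass sep= explicitly", call. = FALSE)
}

#' @noRd
.check_expression <- function(m, allow_negative = FALSE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene and sample identifiers", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers", call. = FALSE)
  if (!allow_negative && any(m < 0, na.rm = TRUE))
    stop("negative expression values on input", call. = FALSE)
  invisible(m)
}

# -- readers ------------------------------------------------------------------

#' Read a genes x samples expression matrix
#'
#' Reads a tab- or comma-separated table with one header row of sample
#' identifiers and one leading column of gene identifiers (or the transpose,
#' with `orientation = "samples_in_rows"`). Duplicate gene rows are collapsed
#' by keeping the row with the highest variance, mirroring the
#' highest-variability probe policy used when several array probes map to one
#' gene; the number dropped is reported via `message()`.
#'
#' Non-numeric data cells other than the usual missing-value spellings are an
#' error naming the offending row and column. Missing values are kept and
#' excluded pairwise downstream. Sample order in the file is preserved and is
#' the single source of truth for all downstream output.
#'
#' @param path File path to a TSV/CSV table.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep Field separator; `NULL` (default) sniffs tab then comma.
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- .sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs an identifier column plus data", call. = FALSE)
  ids <- df[[1L]]
  dat <- df[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow(dat), ncol(dat), dimnames = list(NULL, colnames(dat)))
  na_spell <- c("", "NA", "NaN", "na", "null", "NULL")
  for (j in seq_len(ncol(dat))) {
    cell <- dat[[j]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- is.na(v) & !(trimws(cell) %in% na_spell) & !is.na(cell)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cell[i], ids[i], colnames(dat)[j]), call. = FALSE)
    }
    num[, j] <- v
  }
  rownames(num) <- ids
  if (orientation == "samples_in_rows") num <- t(num)
  num <- .collapse_duplicate_genes(num)
  .check_expression(num)
  num
}

#' @noRd
.collapse_duplicate_genes <- function(m) {
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  rv <- apply(m, 1L, stats::var, na.rm = TRUE)
  rv[is.na(rv)] <- -Inf
  # stable: among duplicates keep the max-variance row, first wins ties
  ord <- order(match(ids, ids), -rv)
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)
  dropped <- nrow(m) - length(keep)
  message(dropped, " duplicate gene row(s) dropped (kept highest-variance row)")
  m[keep, , drop = FALSE]
}

#' Read a PAM50 centroid table
#'
#' TSV with a leading gene-identifier column and one column per intrinsic
#' subtype. Column names are canonicalized case-insensitively: `LA`/`LumA`,
#' `LB`/`LumB`, `Her2`/`HER2-enriched`, `Basal`, `Normal`/`Normal-like`.
#' Having both members of an alias pair present is an ambiguity error.
#' Fewer than 40 genes is an error; 40-49 genes is accepted with a warning
#' (real deployments sometimes lose panel genes to platform quality filters).
#'
#' @param path File path.
#' @param sep Field separator; `NULL` sniffs.
#' @return Numeric matrix, genes x 5 subtypes with canonical column names
#'   `Basal, Her2, LumA, LumB, Normal`.
#' @export
read_centroids <- function(path, sep = NULL) {
  sep <- .sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("centroid table needs a gene column plus subtype columns", call. = FALSE)
  genes <- as.character(df[[1L]])
  prof <- df[, -1L, drop = FALSE]
  aliases <- list(
    Basal  = c("basal", "basal-like", "basallike"),
    Her2   = c("her2", "her2-enriched", "her2enriched", "her2e"),
    LumA   = c("luma", "la", "luminala", "luminal a", "luminal-a"),
    LumB   = c("lumb", "lb", "luminalb", "luminal b", "luminal-b"),
    Normal = c("normal", "normal-like", "normallike"))
  low <- tolower(trimws(colnames(prof)))
  canon <- rep(NA_character_, length(low))
  for (s in names(aliases)) {
    hit <- which(low %in% aliases[[s]])
    if (length(hit) > 1L)
      stop("ambiguous centroid columns for subtype ", s, ": ",
           paste(colnames(prof)[hit], collapse = ", "), call. = FALSE)
    if (length(hit) == 1L) canon[hit] <- s
  }
  missing <- setdiff(SUBTYPES, canon)
  if (length(missing))
    stop("centroid table missing subtype column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  prof <- prof[, !is.na(canon), drop = FALSE]
  colnames(prof) <- canon[!is.na(canon)]
  prof <- as.matrix(prof[, SUBTYPES])
  storage.mode(prof) <- "double"
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in centroid table", call. = FALSE)
  rownames(prof) <- genes
  if (nrow(prof) < 40L)
    stop("centroid table has ", nrow(prof), " genes; at least 40 required", call. = FALSE)
  if (nrow(prof) < 50L)
    warning("centroid table has ", nrow(prof), " genes (< 50)", call. = FALSE)
  prof
}

#' Read a per-sample clinical (IHC) table
#'
#' Accepts TSV/CSV with a `sample_id` column and any subset of the IHC
#' biomarker fields `er_ihc`, `pr_ihc` (percent nuclear staining or
#' positive/negative), `her2_ihc` (`0`, `1+`, `2+`, `3+`), `her2_fish`
#' (`amplified` / `not_amplified`), `ki67_pct` (percent). Absent columns and
#' blank cells become `NA`; nothing is imputed.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` sniffs.
#' @return `data.frame` with columns `sample_id, er_ihc, pr_ihc, her2_ihc,
#'   her2_fish, ki67_pct` (character except `ki67_pct`, numeric).
#' @export
read_clinical <- function(path, sep = NULL) {
  sep <- .sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  names(df) <- tolower(trimws(names(df)))
  if (!"sample_id" %in% names(df))
    stop("clinical table has no 'sample_id' column", call. = FALSE)
  blank_na <- function(x) { x <- trimws(x); x[x %in% c("", "NA", "na")] <- NA; x }
  get <- function(col) if (col %in% names(df)) blank_na(df[[col]]) else rep(NA_character_, nrow(df))
  out <- data.frame(
    sample_id = blank_na(df[["sample_id"]]),
    er_ihc    = get("er_ihc"),
    pr_ihc    = get("pr_ihc"),
    her2_ihc  = get("her2_ihc"),
    her2_fish = get("her2_fish"),
    ki67_pct  = suppressWarnings(as.numeric(get("ki67_pct"))),
    stringsAsFactors = FALSE)
  bad <- !is.na(out$her2_ihc) & !out$her2_ihc %in% c("0", "1+", "2+", "3+")
  if (any(bad))
    stop("invalid her2_ihc value '", out$her2_ihc[which(bad)[1L]],
         "' for sample ", out$sample_id[which(bad)[1L]], call. = FALSE)
  bad <- !is.na(out$her2_fish) & !out$her2_fish %in% c("amplified", "not_amplified")
  if (any(bad))
    stop("invalid her2_fish value for sample ", out$sample_id[which(bad)[1L]], call. = FALSE)
  out
}

# -- writers ------------------------------------------------------------------

#' @noRd
.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

#' Write per-sample subtype calls to TSV
#'
#' One row per sample in cohort order: `sample_id`, IHC subtype, the three
#' stage labels (conventional, intermediate, refined), five per-centroid
#' correlations per stage that was run, and the PC1 coordinate. Stages not
#' run keep their columns, emitted empty, so the schema is stable. Numbers
#' are written with 15 significant digits so a read-back round-trips at full
#' float precision.
#'
#' @param fit A `pcapam50_fit` object from [run_pipeline()], or any list with
#'   a `calls` data.frame in the same layout.
#' @param path Output file path.
#' @return Invisibly, the written data.frame.
#' @export
write_calls <- function(fit, path) {
  calls <- if (is.data.frame(fit)) fit else fit$calls
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L)
  out <- calls
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    out[[j]][is.na(out[[j]])] <- ""
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Write a generic numeric table as TSV at full precision
#' @param df data.frame
#' @param path output path
#' @return invisibly `df`
#' @export
write_tsv15 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(df)
}

#' Write an expression matrix as TSV (genes in rows)
#' @param m genes x samples matrix
#' @param path output path
#' @param digits significant digits (default 15 for exact round-trip)
#' @return invisibly `m`
#' @export
write_expression <- function(m, path, digits = 15L) {
  df <- data.frame(gene_id = rownames(m),
                   matrix(sprintf(paste0("%.", digits, "g"), m), nrow(m),
                          dimnames = list(NULL, colnames(m))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(m)
}
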