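# Row-wise Pearson correlation between paired rows of two matrices,
# pairwise-complete with a minimum pair count. Returns NA (with one
# warning) for rows with too few pairs or zero variance.
.paired_row_cor <- function(a, b, min_pairs = 10) {
  stopifnot(identical(dim(a), dim(b)))
  n <- ncol(a)
  complete <- !is.na(a) & !is.na(b)
  if (all(complete) && n >= min_pairs) {
    ac <- a - rowMeans(a)
    bc <- b - rowMeans(b)
    sa <- sqrt(rowSums(ac^2))
    sb <- sqrt(rowSums(bc^2))
    r <- rowSums(ac * bc) / (sa * sb)
    bad <- sa == 0 | sb == 0
    if (any(bad)) {
      warning(sum(bad), " gene(s) with zero variance; correlation set to NA")
      r[bad] <- NA_real_
    }
    return(r)
  }
  r <- rep(NA_real_, nrow(a))
  few <- 0L; degen <- 0L
  for (g in seq_len(nrow(a))) {
    ok <- complete[g, ]
    if (sum(ok) < min_pairs) { few <- few + 1L; next }
    x <- a[g, ok]; y <- b[g, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { degen <- degen + 1L; next }
    r[g] <- stats::cor(x, y)
  }
  if (few) warning(few, " gene(s) with fewer than ", min_pairs,
                   " complete pairs; correlation set to NA")
  if (degen) warning(degen, " gene(s) with zero variance; correlation set to NA")
  r
}

#' Per-gene in-cis correlation
#'
#' Pearson correlation between each gene's log2 copy number (PCF-derived)
#' and its own log2 expression, over pairwise-complete samples.
#'
#' @param records A `gene_records` object from [match_probes].
#' @param min_pairs Minimum complete pairs required per gene (default 10);
#'   genes below it get `NA`.
#' @return Named numeric vector of correlations, one per gene.
#' @export
cis_correlation <- function(records, min_pairs = 10) {
  stopifnot(inherits(records, "gene_records"))
  r <- .paired_row_cor(records$cn, records$expr, min_pairs)
  names(r) <- records$genes$gene_symbol
  r
}

#' Fit the log-linear cis model for one gene
#'
#' Ordinary least squares of log2 expression on log2 copy number,
#' `e = a + b * c + noise`, in log2 space. The residuals are the
#' copy-number-adjusted expression values. When the copy number has zero
#' variance the slope is set to 0, the intercept to the expression mean,
#' and the residuals are the centered expression (with a warning).
#'
#' @param e Numeric vector of log2 expression over samples.
#' @param c Numeric vector of log2 copy number over samples.
#' @return List with `a` (intercept), `b` (slope) and `residuals`
#'   (same length as the inputs; `NA` where either value is missing).
#' @export
fit_cis_model <- function(e, c) {
  stopifnot(length(e) == length(c))
  ok <- !is.na(e) & !is.na(c)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  x <- c[ok]; y <- e[ok]
  vx <- sum((x - mean(x))^2)
  if (vx == 0) {
    warning("copy number has zero variance; slope set to 0")
    b <- 0
    a <- mean(y)
  } else {
    b <- sum((x - mean(x)) * (y - mean(y))) / vx
    a <- mean(y) - b * mean(x)
  }
  res <- e - a - b * c
  res[!ok] <- NA_real_
  list(a = a, b = b, residuals = res)
}

#' Fit the cis model for every gene of a cohort
#'
#' Vectorized per-gene OLS of expression on copy number over
#' pairwise-complete samples, producing the coefficient vectors, the full
#' residual-expression matrix and the in-cis correlations.
#'
#' @param records A `gene_records` object.
#' @param min_pairs Minimum complete pairs for the correlation (default
#'   10); the fit itself degrades to slope 0 for genes with fewer than 3
#'   pairs or zero copy-number variance.
#' @return Object of class `cis_fit`: list with `a`, `b`, `cis_r` (named
#'   vectors) and `residuals` (genes-by-samples matrix aligned with the
#'   expression matrix).
#' @export
fit_cis_models <- function(records, min_pairs = 10) {
  stopifnot(inherits(records, "gene_records"))
  cn <- records$cn; ex <- records$expr
  complete <- !is.na(cn) & !is.na(ex)
  cnz <- cn; cnz[!complete] <- 0
  exz <- ex; exz[!complete] <- 0
  np <- rowSums(complete)
  mx <- rowSums(cnz) / np
  my <- rowSums(exz) / np
  sxx <- rowSums(complete * (cnz - mx)^2)
  sxy <- rowSums(complete * (cnz - mx) * (exz - my))
  b <- ifelse(np >= 3 & sxx > 0, sxy / sxx, 0)
  a <- ifelse(np >= 1, my - b * mx, NA_real_)
  res <- ex - a - b * cn
  r <- suppressWarnings(.paired_row_cor(cn, ex, min_pairs))
  names(a) <- names(b) <- names(r) <- records$genes$gene_symbol
  structure(list(a = a, b = b, cis_r = r, residuals = res),
            class = "cis_fit")
}

#' Residual (copy-number-adjusted) expression matrix
#'
#' @param fits A `cis_fit` object from [fit_cis_models].
#' @return Genes-by-samples matrix of residual log2 expression.
#' @export
residual_matrix <- function(fits) {
  stopifnot(inherits(fits, "cis_fit"))
  fits$residuals
}

#' Empirical FDR of the in-cis correlation cutoff by gene shuffling
#'
#' Estimates the false discovery rate of selecting genes with in-cis
#' correlation above `cutoff` by repeatedly shuffling the gene order of
#' the copy-number matrix only (expression untouched), recomputing all
#' per-gene correlations against the mismatched copy-number rows, and
#' counting exceedances. The estimate is the mean null exceedance count
#' divided by the observed count.
#'
#' @param records A `gene_records` object.
#' @param cutoff Correlation cutoff (strict `>`; default 0.6).
#' @param n_shuffles Number of shuffles (default 2000).
#' @param seed Optional integer seed for reproducibility.
#' @param min_pairs Minimum complete pairs per correlation.
#' @return List of class `cis_fdr`: `cutoff`, `n_observed`, `mean_null`,
#'   `fdr_estimate`, `n_shuffles`.
#' @export
shuffle_fdr <- function(records, cutoff = 0.6, n_shuffles = 2000,
                        seed = NULL, min_pairs = 10) {
  stopifnot(inherits(records, "gene_records"), n_shuffles >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- suppressWarnings(
    .paired_row_cor(records$cn, records$expr, min_pairs))
  n_observed <- sum(obs > cutoff, na.rm = TRUE)
  n_genes <- nrow(records$cn)
  null_counts <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    perm <- sample.int(n_genes)
    r <- suppressWarnings(.paired_row_cor(
      records$cn[perm, , drop = FALSE], records$expr, min_pairs))
    null_counts[k] <- sum(r > cutoff, na.rm = TRUE)
  }
  structure(list(cutoff = cutoff, n_observed = n_observed,
                 mean_null = mean(null_counts),
                 fdr_estimate = mean(null_counts) / max(n_observed, 1L),
                 n_shuffles = n_shuffles),
            class = "cis_fdr")
}

#' Select in-cis genes
#'
#' In-cis genes are the commonly aberrant genes whose in-cis Pearson
#' correlation strictly exceeds the cutoff (one-sided positive: both
#' amplification-driven overexpression and deletion-driven
#' underexpression produce positive cis correlation).
#'
#' @param cis_r Named per-gene correlation vector, e.g.
#'   `fit_cis_models(records)$cis_r`.
#' @param common_table A `common_aberrant_table` from
#'   [select_common_aberrant].
#' @param cutoff Correlation cutoff in (0, 1) (default 0.6).
#' @return Character vector of selected gene symbols.
#' @export
select_cis_genes <- function(cis_r, common_table, cutoff = 0.6) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  ab <- common_table$gene_symbol[common_table$commonly_aberrant]
  sel <- names(cis_r)[!is.na(cis_r) & cis_r > cutoff]
  intersect(ab, sel)
}

#' Rank all genes by in-trans correlation with a pivot gene
#'
#' All genes are ranked by the Pearson correlation between the pivot's
#' observed log2 expression and each gene's copy-number-adjusted residual
#' expression, from high positive to high negative. Genes with
#' zero-variance residuals are placed at correlation 0 (with a warning).
#' Ties are broken by gene symbol, so the ranking is deterministic.
#'
#' @param pivot Gene symbol of the pivot (an in-cis gene).
#' @param expr_matrix Genes-by-samples observed expression matrix.
#' @param residuals Genes-by-samples residual matrix from
#'   [residual_matrix], row-aligned with `expr_matrix`.
#' @param exclude_self If `TRUE`, drop the pivot from its own ranking
#'   (default `FALSE`: the pivot is ranked like any other gene).
#' @return Object of class `trans_ranking`: list with `pivot`, `genes`
#'   (symbols in rank order) and `r` (correlations in the same order).
#' @export
trans_ranking <- function(pivot, expr_matrix, residuals,
                          exclude_self = FALSE) {
  if (!pivot %in% rownames(expr_matrix)) stop("pivot not in gene universe")
  e <- expr_matrix[pivot, ]
  ok <- !is.na(e)
  ec <- e[ok] - mean(e[ok])
  se <- sqrt(sum(ec^2))
  if (se == 0) stop("pivot expression has zero variance")
  rs <- residuals[, ok, drop = FALSE]
  rc <- rs - rowMeans(rs, na.rm = TRUE)
  rc[is.na(rc)] <- 0
  sr <- sqrt(rowSums(rc^2))
  r <- as.vector(rc %*% ec) / (sr * se)
  degen <- sr == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero-variance residuals; ",
            "trans correlation set to 0")
    r[degen] <- 0
  }
  names(r) <- rownames(residuals)
  if (exclude_self) r <- r[names(r) != pivot]
  o <- order(-r, names(r))
  structure(list(pivot = pivot, genes = names(r)[o], r = unname(r[o])),
            class = "trans_ranking")
}
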