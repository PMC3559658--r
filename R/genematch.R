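#' Match copy-number and expression probes into gene-level matrices
#'
#' For every expression probe carrying a gene symbol, the copy-number
#' probe at the nearest position on the same chromosome is identified
#' (equidistant ties go to the lower coordinate). Copy-number values,
#' expression values and probe positions are then averaged per gene
#' symbol (on the log2 scale), yielding one matched copy-number row and
#' one expression row per gene.
#'
#' @param expr An expression [genomic_matrix] with gene symbols.
#' @param cn A copy-number [genomic_matrix]; normally the PCF-value matrix
#'   from [segment_matrix].
#' @return An object of class `gene_records`: list with `genes`
#'   (data.frame `gene_symbol`, `chromosome`, `position`), `cn` and `expr`
#'   (genes-by-samples matrices with identical row/column order).
#' @export
match_probes <- function(expr, cn) {
  stopifnot(inherits(expr, "genomic_matrix"), inherits(cn, "genomic_matrix"))
  if (!identical(colnames(expr$values), colnames(cn$values)))
    stop("expression and copy-number matrices must share the sample list")
  keep <- !is.na(expr$anno$gene_symbol) & nzchar(expr$anno$gene_symbol)
  if (!any(keep)) stop("no expression probes carry a gene symbol")
  ea <- expr$anno[keep, ]
  ev <- expr$values[keep, , drop = FALSE]

  # nearest same-chromosome CN probe for each expression probe
  cn_row <- rep(NA_integer_, nrow(ea))
  for (chr in unique(ea$chromosome)) {
    ei <- which(ea$chromosome == chr)
    ci <- which(cn$anno$chromosome == chr)
    if (length(ci) == 0L) next
    cpos <- cn$anno$position[ci]
    o <- order(cpos, ci)  # lower coordinate wins ties deterministically
    ci <- ci[o]; cpos <- cpos[o]
    for (k in ei) {
      d <- abs(cpos - ea$position[k])
      cn_row[k] <- ci[which.min(d)]  # first minimum = lowest coordinate
    }
  }
  unmatched <- is.na(cn_row)
  if (any(unmatched)) {
    warning(sprintf(
      "%d expression probe(s) on chromosome(s) without copy-number probes dropped (%s)",
      sum(unmatched),
      paste(unique(ea$chromosome[unmatched]), collapse = ", ")))
    ea <- ea[!unmatched, ]; ev <- ev[!unmatched, , drop = FALSE]
    cn_row <- cn_row[!unmatched]
  }
  cv <- cn$values[cn_row, , drop = FALSE]

  sym <- factor(ea$gene_symbol, levels = unique(ea$gene_symbol))
  g <- levels(sym)
  agg <- function(m) {
    cnt <- rowsum((!is.na(m)) * 1, sym, reorder = FALSE)
    out <- rowsum(m, sym, reorder = FALSE, na.rm = TRUE) / cnt
    out[cnt == 0] <- NA_real_
    rownames(out) <- g
    out
  }
  genes <- data.frame(
    gene_symbol = g,
    chromosome = as.character(tapply(ea$chromosome, sym, `[`, 1L)),
    position = as.numeric(tapply(ea$position, sym, mean)),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, cn = agg(cv), expr = agg(ev)),
            class = "gene_records")
}

#' @export
print.gene_records <- function(x, ...) {
  cat(sprintf("gene_records: %d genes x %d samples\n",
              nrow(x$genes), ncol(x$expr)))
  invisible(x)
}
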