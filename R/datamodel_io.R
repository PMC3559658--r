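#' Construct a genomic matrix
#'
#' A `genomic_matrix` is the shared in-memory carrier for probe-level
#' copy-number (log2 ratio) and expression (log2 intensity) tracks: a
#' features-by-samples numeric matrix plus per-feature genome coordinates.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are probe ids, column names sample ids.
#' @param chromosome Character vector of chromosome labels, one per row.
#'   Labels are free text and compared verbatim throughout the package.
#' @param position Integer-valued vector of 1-based basepair positions.
#' @param gene_symbol Optional character vector of gene symbols (expression
#'   tracks); `NA` marks probes without an annotated symbol.
#' @param kind Either `"copy_number"` or `"expression"`.
#'
#' @return An object of class `genomic_matrix`: a list with elements
#'   `values`, `anno` (data.frame with `probe_id`, `chromosome`, `position`,
#'   `gene_symbol`) and `kind`.
#' @export
genomic_matrix <- function(values, chromosome, position, gene_symbol = NULL,
                           kind = c("copy_number", "expression")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(rownames(values)))
    stop("probe ids (row names) are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (length(chromosome) != n || length(position) != n)
    stop("annotation length does not match row count")
  if (any(!nzchar(chromosome)) || anyNA(chromosome))
    stop("chromosome labels must be non-empty")
  if (any(position < 1, na.rm = TRUE) || anyNA(position))
    stop("positions must be >= 1 and non-missing")
  if (is.null(gene_symbol)) gene_symbol <- rep(NA_character_, n)
  if (any(is.infinite(values)))
    stop("values must be finite or NA")
  anno <- data.frame(probe_id = rownames(values),
                     chromosome = as.character(chromosome),
                     position = as.numeric(position),
                     gene_symbol = as.character(gene_symbol),
                     stringsAsFactors = FALSE)
  structure(list(values = values, anno = anno, kind = kind),
            class = "genomic_matrix")
}

#' @export
dim.genomic_matrix <- function(x) dim(x$values)

#' @export
print.genomic_matrix <- function(x, ...) {
  cat(sprintf("genomic_matrix [%s]: %d probes x %d samples, %d chromosome(s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              length(unique(x$anno$chromosome))))
  invisible(x)
}

#' Read a probe-level matrix from TSV
#'
#' Expected layout: a header row naming the annotation columns and the
#' samples; leading columns `probe_id`, `chromosome`, `position` and, for
#' expression tracks, `gene_symbol`; remaining columns hold one numeric
#' value per sample. Empty cells and the literal `NA` are recorded as
#' missing.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"copy_number"` or `"expression"`; expression tracks carry a
#'   `gene_symbol` column.
#' @param log2_transform If `TRUE`, values are assumed linear scale and
#'   `log2(x + log2_offset)` is applied on read; by default input values are
#'   assumed to be log2 already.
#' @param log2_offset Offset added before the log when `log2_transform` is
#'   set (default 1).
#' @return A [genomic_matrix].
#' @export
read_matrix <- function(path, kind = c("copy_number", "expression"),
                        log2_transform = FALSE, log2_offset = 1) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  lead <- if (kind == "expression")
    c("probe_id", "gene_symbol", "chromosome", "position")
  else c("probe_id", "chromosome", "position")
  if (ncol(df) < length(lead) + 1L ||
      !identical(colnames(df)[seq_along(lead)], lead))
    stop("malformed header in ", path, ": expected leading columns ",
         paste(lead, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id in ", path, ": ",
         df$probe_id[duplicated(df$probe_id)][1L])
  sample_cols <- setdiff(seq_len(ncol(df)), seq_along(lead))
  vals <- df[, sample_cols, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                     v[bad[1L]], bad[1L], colnames(vals)[j], path))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- df$probe_id
  if (log2_transform) m <- log2(m + log2_offset)
  genomic_matrix(m, chromosome = df$chromosome, position = df$position,
                 gene_symbol = if (kind == "expression") df$gene_symbol,
                 kind = kind)
}

#' Write a probe-level matrix to TSV
#'
#' Inverse of [read_matrix]: the written file round-trips to an identical
#' object.
#'
#' @param gm A [genomic_matrix].
#' @param path Output path.
#' @export
write_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "genomic_matrix"))
  lead <- if (gm$kind == "expression")
    gm$anno[, c("probe_id", "gene_symbol", "chromosome", "position")]
  else gm$anno[, c("probe_id", "chromosome", "position")]
  df <- cbind(lead, as.data.frame(gm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#' Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of members with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i))
    ids[i] <- f[1L]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- f[2L]
    sets[[i]] <- members
  }
  if (anyDuplicated(ids))
    stop("duplicate set id in ", path, ": ", ids[duplicated(ids)][1L])
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A named list of character vectors (optionally with a
#'   `description` attribute each), e.g. from [read_gmt].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}

#' Write a results table as deterministic TSV
#'
#' Columns keep their order; numeric columns are formatted at a fixed
#' number of significant digits; missing values are written as `NA`; rows
#' are sorted by the given key columns so repeated writes of the same table
#' are byte-identical.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param sort_by Character vector of column names used as the sort key
#'   (default: all columns, left to right).
#' @param digits Significant digits for numeric columns (default 6).
#' @export
write_results <- function(records, path, sort_by = colnames(records),
                          digits = 6) {
  stopifnot(is.data.frame(records))
  sort_by <- intersect(sort_by, colnames(records))
  if (nrow(records) > 1L && length(sort_by))
    records <- records[do.call(order, records[sort_by]), , drop = FALSE]
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         signif(out[[j]], digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}
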