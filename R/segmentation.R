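#' Piecewise-constant fitting parameters
#'
#' @param gamma Nonnegative penalty per breakpoint, on the scale of the
#'   summed squared deviations. The default (40) is a conservative choice
#'   for log2 array copy-number data; lower values yield more, shorter
#'   segments.
#' @param kmin Minimum number of probes per segment (default 5).
#' @return An object of class `pcf_params`.
#' @export
pcf_params <- function(gamma = 40, kmin = 5) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("gamma must be a single nonnegative number")
  if (!is.numeric(kmin) || length(kmin) != 1L || kmin < 1)
    stop("kmin must be a single integer >= 1")
  structure(list(gamma = as.numeric(gamma), kmin = as.integer(kmin)),
            class = "pcf_params")
}

#' Segment one copy-number profile
#'
#' Fits a piecewise-constant function to an ordered vector of log2 copy
#' numbers for one sample on one chromosome, minimizing the total
#' within-segment sum of squared deviations plus `gamma` per breakpoint,
#' over all segmentations with at least `kmin` probes per segment. The
#' solution is exact (dynamic programming over breakpoints, O(n^2)); ties
#' in cost are broken toward fewer segments, then earlier breakpoints.
#'
#' Missing values are dropped before fitting; dropped probes inherit the
#' fitted value of the covering segment (segment spans are extended over
#' them in index space).
#'
#' @param values Numeric vector, probes in genome order; at least one
#'   finite value.
#' @param params A [pcf_params] object.
#' @return data.frame with one row per segment: `start_index`, `end_index`
#'   (1-based inclusive, in the original probe indexing), `n_probes`
#'   (finite probes in the segment) and `mean_value` (the PCF value: the
#'   mean of the finite member values).
#' @export
segment_profile <- function(values, params = pcf_params()) {
  stopifnot(inherits(params, "pcf_params"))
  ok <- which(is.finite(values))
  if (length(ok) == 0L) stop("no finite values to segment")
  x <- values[ok]
  if (length(x) < params$kmin) {
    warning("profile shorter than kmin; returning a single segment")
    starts <- 1L
  } else {
    starts <- pcf_segment_cpp(x, params$gamma, params$kmin)
  }
  ends <- c(starts[-1L] - 1L, length(x))
  # map back to original indices, extending spans over dropped probes
  orig_start <- ok[starts]
  orig_end <- ok[ends]
  orig_start[1L] <- 1L
  if (length(orig_start) > 1L)
    orig_start[-1L] <- orig_end[-length(orig_end)] + 1L
  orig_end[length(orig_end)] <- length(values)
  means <- vapply(seq_along(starts), function(k)
    mean(x[starts[k]:ends[k]]), numeric(1))
  data.frame(start_index = orig_start, end_index = orig_end,
             n_probes = ends - starts + 1L, mean_value = means)
}

#' Expand segments to per-probe PCF values
#'
#' Each probe inherits the mean value of its covering segment.
#'
#' @param segments data.frame as returned by [segment_profile].
#' @param n_probes Total number of probes the segments must tile.
#' @return Numeric vector of length `n_probes`.
#' @export
pcf_values <- function(segments, n_probes) {
  if (segments$start_index[1L] != 1L ||
      segments$end_index[nrow(segments)] != n_probes ||
      (nrow(segments) > 1L &&
       any(segments$start_index[-1L] != segments$end_index[-nrow(segments)] + 1L)))
    stop("segments do not tile 1..n_probes")
  rep(segments$mean_value, segments$end_index - segments$start_index + 1L)
}

#' Segment every sample of a copy-number matrix
#'
#' Runs [segment_profile] per sample per chromosome (probes ordered by
#' position within chromosome) and assembles both the per-probe PCF value
#' matrix and a SEG-like segment table.
#'
#' @param gm A copy-number [genomic_matrix].
#' @param params A [pcf_params] object.
#' @return List with `pcf` (a [genomic_matrix] of PCF values, same shape
#'   and annotation as the input) and `segments` (data.frame: `sample`,
#'   `chromosome`, `start_pos`, `end_pos`, `n_probes`, `seg_mean`).
#' @export
segment_matrix <- function(gm, params = pcf_params()) {
  stopifnot(inherits(gm, "genomic_matrix"))
  pcf <- gm$values
  pcf[] <- NA_real_
  chroms <- unique(gm$anno$chromosome)
  seg_list <- list()
  for (chr in chroms) {
    idx <- which(gm$anno$chromosome == chr)
    idx <- idx[order(gm$anno$position[idx])]
    pos <- gm$anno$position[idx]
    for (s in seq_len(ncol(gm$values))) {
      segs <- segment_profile(gm$values[idx, s], params)
      pcf[idx, s] <- pcf_values(segs, length(idx))
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        sample = colnames(gm$values)[s], chromosome = chr,
        start_pos = pos[segs$start_index], end_pos = pos[segs$end_index],
        n_probes = segs$n_probes, seg_mean = segs$mean_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- gm
  out$values <- pcf
  list(pcf = out, segments = do.call(rbind, seg_list))
}
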