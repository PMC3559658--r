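#' Call per-gene gains and losses from PCF values
#'
#' A gene is called gained in a sample when its PCF-derived log2 copy
#' number exceeds `tau`, lost when it is below `-tau` (strict
#' inequalities), and neutral otherwise.
#'
#' @param gene_cn Genes-by-samples matrix of PCF values.
#' @param tau Positive calling threshold on the log2 scale (default 0.1).
#' @return List of class `aberration_calls`: `calls` (matrix in
#'   \{-1, 0, +1\}, `NA` where the PCF value is missing) and `tau`.
#' @export
call_aberrations <- function(gene_cn, tau = 0.1) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("tau must be a single positive number")
  calls <- matrix(0L, nrow(gene_cn), ncol(gene_cn),
                  dimnames = dimnames(gene_cn))
  calls[gene_cn > tau] <- 1L
  calls[gene_cn < -tau] <- -1L
  calls[is.na(gene_cn)] <- NA_integer_
  structure(list(calls = calls, tau = tau), class = "aberration_calls")
}

#' Rejection threshold of the exact binomial sign test
#'
#' For a gene with `m = G + L` aberrations of which `G` are gains, the
#' skew statistic is `D = G - L = 2G - m`. Under the null of no skew,
#' `G ~ Binomial(m, 1/2)`. Returns the least integer `c >= 1` such that
#' `P(|2X - m| >= c) <= alpha` for every `m` from 1 to `m_max`, computed
#' by exact binomial tail sums. When even the most extreme outcome at the
#' largest `m` is not rare enough, the returned `c` exceeds `m_max` and no
#' gene can be rejected.
#'
#' @param m_max Largest aberration count observed at any gene.
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return Integer threshold `c`.
#' @export
sign_test_threshold <- function(m_max, alpha = 0.05) {
  if (!is.numeric(m_max) || length(m_max) != 1L || m_max < 1)
    stop("m_max must be a single integer >= 1")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  m_max <- as.integer(m_max)
  for (c in seq_len(m_max + 1L)) {
    ok <- TRUE
    for (m in seq_len(m_max)) {
      # |2X - m| >= c  <=>  X >= (m + c)/2  or  X <= (m - c)/2
      hi <- ceiling((m + c) / 2)
      lo <- floor((m - c) / 2)
      p <- stats::pbinom(hi - 1L, m, 0.5, lower.tail = FALSE) +
        (if (lo >= 0) stats::pbinom(lo, m, 0.5) else 0)
      if (p > alpha) { ok <- FALSE; break }
    }
    if (ok) return(c)
  }
  m_max + 1L
}

#' Select commonly aberrant genes
#'
#' Combines the aberration-frequency filter (strictly more than
#' `freq_min` of samples gained or lost) with the binomial sign test on
#' the gain-loss skew: a gene is commonly gained when `D = G - L >= c`,
#' commonly lost when `-D >= c`. A gene can never be both. Both filters
#' are applied conjunctively by default and can be toggled independently.
#'
#' @param calls An `aberration_calls` object from [call_aberrations].
#' @param freq_min Frequency threshold in \[0, 1) (default 0.10; strict
#'   `>`).
#' @param c Sign-test rejection threshold from [sign_test_threshold].
#' @param use_frequency,use_sign_test Toggles for the two filters.
#' @return data.frame of class `common_aberrant_table`: per gene
#'   `gene_symbol`, `n_gain`, `n_loss`, `frequency`, `D`, `direction`
#'   (`gained`/`lost`/`none`) and `commonly_aberrant`.
#' @export
select_common_aberrant <- function(calls, freq_min = 0.10, c,
                                   use_frequency = TRUE,
                                   use_sign_test = TRUE) {
  stopifnot(inherits(calls, "aberration_calls"))
  if (freq_min < 0 || freq_min >= 1) stop("freq_min must be in [0, 1)")
  if (missing(c) || c < 1) stop("c must be a sign-test threshold >= 1")
  m <- calls$calls
  n_samples <- ncol(m)
  n_gain <- rowSums(m == 1L, na.rm = TRUE)
  n_loss <- rowSums(m == -1L, na.rm = TRUE)
  frequency <- (n_gain + n_loss) / n_samples
  D <- n_gain - n_loss
  direction <- ifelse(D >= c, "gained", ifelse(-D >= c, "lost", "none"))
  ok <- rep(TRUE, nrow(m))
  if (use_frequency) ok <- ok & frequency > freq_min
  if (use_sign_test) ok <- ok & direction != "none"
  out <- data.frame(gene_symbol = rownames(m), n_gain = n_gain,
                    n_loss = n_loss, frequency = frequency, D = D,
                    direction = direction, commonly_aberrant = ok,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("common_aberrant_table", "data.frame")
  out
}

#' Largest per-gene aberration count
#'
#' Helper to compute `m_max` for [sign_test_threshold] from the observed
#' calls rather than assuming a fixed bound.
#'
#' @param calls An `aberration_calls` object.
#' @return Integer: the maximum of `G + L` over genes (0 when no gene has
#'   any aberration).
#' @export
max_aberration_count <- function(calls) {
  stopifnot(inherits(calls, "aberration_calls"))
  as.integer(max(rowSums(abs(calls$calls), na.rm = TRUE)))
}
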