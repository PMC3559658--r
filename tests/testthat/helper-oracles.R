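# Independent brute-force oracles used across the suite. These stay
# deliberately naive (enumeration, direct tail summation) so they cannot
# share a defect with the implementations they check.

# Exact mHG p-value by enumerating every arrangement of B ones in N slots
# and scoring each with the prefix-minimum hypergeometric tail.
brute_mhg_pvalue <- function(lambda) {
  N <- length(lambda)
  B <- sum(lambda)
  if (B == 0) return(1)
  s_obs <- brute_mhg_score(lambda)
  combs <- utils::combn(N, B)
  scores <- apply(combs, 2, function(pos) {
    l <- integer(N); l[pos] <- 1L
    brute_mhg_score(l)
  })
  mean(scores <= s_obs * (1 + 1e-9))
}

# mHG score by direct evaluation of every prefix 1..N-1.
brute_mhg_score <- function(lambda) {
  N <- length(lambda)
  B <- sum(lambda)
  b <- cumsum(lambda)
  min(vapply(seq_len(N - 1), function(n)
    phyper(b[n] - 1, B, N - B, n, lower.tail = FALSE), numeric(1)))
}

# Optimal segmentation cost by enumerating all breakpoint subsets.
brute_seg_cost <- function(x, gamma, kmin) {
  n <- length(x)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, bp + 1)
    ends <- c(bp, n)
    if (any(ends - starts + 1 < kmin)) next
    cost <- sum(mapply(function(s, e) sum((x[s:e] - mean(x[s:e]))^2),
                       starts, ends)) + gamma * length(bp)
    best <- min(best, cost)
  }
  best
}

# Cost of a segmentation returned by segment_profile (complete data).
seg_cost_of <- function(x, segs, gamma) {
  sum(mapply(function(s, e, m) sum((x[s:e] - m)^2),
             segs$start_index, segs$end_index, segs$mean_value)) +
    gamma * (nrow(segs) - 1)
}

# Sign-test threshold by direct tail summation over the binomial pmf.
brute_sign_threshold <- function(m_max, alpha) {
  for (c in 1:(m_max + 1)) {
    ok <- TRUE
    for (m in 1:m_max) {
      x <- 0:m
      p <- sum(dbinom(x[abs(2 * x - m) >= c], m, 0.5))
      if (p > alpha) { ok <- FALSE; break }
    }
    if (ok) return(c)
  }
  m_max + 1
}

# Small gene_records object built directly from matrices.
make_records <- function(cn, expr, chromosome = "1") {
  g <- rownames(cn)
  structure(list(
    genes = data.frame(gene_symbol = g, chromosome = chromosome,
                       position = seq_along(g) * 1e5,
                       stringsAsFactors = FALSE),
    cn = cn, expr = expr), class = "gene_records")
}

# Reduced cohort spec for fast pipeline-level tests.
small_spec <- function(...) {
  synth_spec(n_genes = 400, n_samples = 60, n_chromosomes = 4,
             n_decoys = 30, module_size = 25, decoy_size = 25, ...)
}
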