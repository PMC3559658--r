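#' Hypergeometric tail probability
#'
#' `P(X >= b)` for `X ~ Hypergeometric(N, B, n)`: the probability of
#' drawing at least `b` marked elements in `n` draws without replacement
#' from a universe of `N` elements of which `B` are marked.
#'
#' @param b Number of marked elements observed (0..min(n, B)).
#' @param n Number of draws.
#' @param B Number of marked elements in the universe.
#' @param N Universe size.
#' @return Upper-tail probability (vectorized over the arguments).
#' @export
hypergeometric_tail <- function(b, n, B, N) {
  if (any(b < 0) || any(b > n) || any(n > N) || any(B > N) || any(b > B))
    stop("invalid hypergeometric parameters: need 0 <= b <= n <= N, b <= B <= N")
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

# Minimum hypergeometric score from sorted member positions in a ranking.
# pos: strictly increasing 1-based positions of the B set members.
# Only prefixes ending at a member position can attain the minimum
# (appending a non-member never decreases the tail), and the prefix length
# ranges over 1..N-1.
.mhg_score_from_pos <- function(pos, N, B) {
  if (B == 0L) return(list(score = 1, n_star = 1L, b_star = 0L))
  keep <- pos < N
  if (!any(keep)) return(list(score = 1, n_star = 1L, b_star = 0L))
  n <- pos[keep]
  b <- seq_len(B)[keep]
  tails <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
  i <- which.min(tails)  # first minimum: smallest n attaining it
  if (tails[i] >= 1)
    return(list(score = 1, n_star = 1L, b_star = 0L))
  list(score = tails[i], n_star = as.integer(n[i]), b_star = as.integer(b[i]))
}

#' Minimum hypergeometric (mHG) enrichment score of a ranked binary list
#'
#' The mHG score is the minimum, over all prefixes of length 1..N-1, of
#' the hypergeometric tail `P(X >= b(n))` where `b(n)` counts set members
#' in the top `n` of the ranking. Smaller scores indicate stronger
#' concentration of members at the top. The score is not a p-value; see
#' [mhg_pvalue] for the exact correction over all prefix choices.
#'
#' @param lambda Binary (0/1) vector in ranking order; 1 marks set
#'   members.
#' @return List of class `mhg_result`: `score`, `n_star` (smallest prefix
#'   length attaining the minimum), `b_star` (members in that prefix) and
#'   `fold` (`(b_star/n_star)/(B/N)` enrichment over chance).
#' @export
mhg_score <- function(lambda) {
  lambda <- as.integer(lambda != 0)
  N <- length(lambda)
  if (N < 2L) stop("ranking must contain at least 2 genes")
  B <- sum(lambda)
  res <- .mhg_score_from_pos(which(lambda == 1L), N, B)
  res$fold <- if (B > 0L && res$b_star > 0L)
    (res$b_star / res$n_star) / (B / N) else NA_real_
  class(res) <- "mhg_result"
  res
}

#' Exact p-value of the mHG score
#'
#' Probability, under a uniform random arrangement of the `B` member
#' labels among `N` ranked positions, that the mHG score is at most `s`.
#' Computed exactly by dynamic programming over the prefix lattice
#' (O(N*B)), accumulating the probability mass of label arrangements
#' whose prefix path enters the rejection region.
#'
#' @param s Observed mHG score in (0, 1].
#' @param N Universe (ranking) size.
#' @param B Number of set members in the universe.
#' @return Exact p-value; satisfies `s <= p <= min(1, N * s)`.
#' @export
mhg_pvalue <- function(s, N, B) {
  if (N < 2L) stop("N must be >= 2")
  if (B < 0L || B > N) stop("B must be in 0..N")
  if (s <= 0 || s > 1) stop("s must be in (0, 1]")
  mhg_pvalue_cpp(s, as.integer(N), as.integer(B))
}

# Score all sets against one ranking, both directions, without exact
# p-values (used by the empirical null). ranking_r: named correlation
# vector (full universe); set_members: list of character vectors.
# Returns matrix n_sets x 2 (top, bottom) of scores; NA for skipped sets.
.score_all_sets <- function(r, gene_names, set_idx, N, min_size, max_size) {
  o <- order(-r, gene_names)
  rnk <- integer(N)
  rnk[o] <- seq_len(N)
  out <- matrix(NA_real_, length(set_idx), 2,
                dimnames = list(names(set_idx), c("top", "bottom")))
  for (j in seq_along(set_idx)) {
    idx <- set_idx[[j]]
    B <- length(idx)
    if (B < min_size || B > max_size) next
    p <- sort.int(rnk[idx])
    out[j, 1L] <- .mhg_score_from_pos(p, N, B)$score
    out[j, 2L] <- .mhg_score_from_pos(sort.int(N + 1L - p), N, B)$score
  }
  out
}

#' Score every gene set against one pivot's trans ranking
#'
#' Computes the mHG score and its exact p-value for each gene set in both
#' the top direction (members concentrated among the genes most
#' positively correlated with the pivot) and, when requested, the bottom
#' direction (the reversed ranking). Set membership is intersected with
#' the ranking's gene universe before computing `B`; sets with fewer than
#' `min_size` or more than `max_size` members in the universe are
#' skipped.
#'
#' @param ranking A `trans_ranking` from [trans_ranking].
#' @param sets A `gene_set_collection` from [read_gmt] (or a named list
#'   of member vectors).
#' @param direction `"top"`, `"bottom"` or `"both"` (default).
#' @param min_size,max_size Universe-membership bounds (defaults 3 and
#'   2000).
#' @return data.frame with one row per (set, direction): `pivot`,
#'   `set_id`, `direction`, `mhg_score`, `p_exact`, `n_star`, `b_star`,
#'   `fold`.
#' @export
enrich_pivot <- function(ranking, sets, direction = c("both", "top", "bottom"),
                         min_size = 3, max_size = 2000) {
  stopifnot(inherits(ranking, "trans_ranking"))
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("top", "bottom") else direction
  N <- length(ranking$genes)
  rnk <- stats::setNames(seq_len(N), ranking$genes)
  keep <- names(sets)[vapply(sets, function(m) {
    B <- sum(m %in% ranking$genes)
    B >= min_size && B <= max_size
  }, logical(1))]
  nr <- length(keep) * length(dirs)
  score <- p_exact <- fold <- numeric(nr)
  n_star <- b_star <- integer(nr)
  i <- 0L
  for (sid in keep) {
    p <- sort.int(unname(rnk[intersect(sets[[sid]], ranking$genes)]))
    B <- length(p)
    for (d in dirs) {
      i <- i + 1L
      pos <- if (d == "top") p else sort.int(N + 1L - p)
      sc <- .mhg_score_from_pos(pos, N, B)
      score[i] <- sc$score
      p_exact[i] <- mhg_pvalue_cpp(sc$score, N, B)
      n_star[i] <- sc$n_star
      b_star[i] <- sc$b_star
      fold[i] <- if (sc$b_star > 0L) (sc$b_star / sc$n_star) / (B / N)
                 else NA_real_
    }
  }
  data.frame(pivot = rep(ranking$pivot, nr),
             set_id = rep(keep, each = length(dirs)),
             direction = rep_len(dirs, nr),
             mhg_score = score, p_exact = p_exact,
             n_star = n_star, b_star = b_star, fold = fold,
             stringsAsFactors = FALSE)
}

#' Bonferroni screen on association records
#'
#' Flags records whose exact mHG p-value remains below `alpha` after
#' multiplying by the size of the test family (by default the number of
#' pivots times the number of scored sets times the two directions).
#'
#' @param records data.frame from [enrich_pivot] (rows from several
#'   pivots may be concatenated).
#' @param alpha Family-wise level (default 0.05; strict `<` after
#'   correction).
#' @param n_tests Size of the test family; default
#'   `n_pivots * n_sets * n_directions` computed from the records.
#' @return `records` with a logical `bonferroni_pass` column added.
#' @export
bonferroni_filter <- function(records, alpha = 0.05, n_tests = NULL) {
  if (is.null(n_tests))
    n_tests <- length(unique(records$pivot)) *
      length(unique(records$set_id)) * length(unique(records$direction))
  records$bonferroni_pass <- records$p_exact * n_tests < alpha
  records
}

#' Sample-shuffle empirical null for mHG association scores
#'
#' For each simulation, the columns (samples) of the residual-expression
#' matrix are randomly permuted while the pivot expression values stay
#' fixed, all trans rankings are rebuilt and all gene sets rescored. This
#' preserves the correlation structure among residuals while destroying
#' any pivot-residual association. For each (set, direction) the minimum
#' score over all pivots and all simulations is retained and converted to
#' an exact p-value, which is the reference bar an observed association
#' must beat.
#'
#' @param residuals Genes-by-samples residual matrix ([residual_matrix]).
#' @param pivots Character vector of pivot gene symbols.
#' @param expr_matrix Genes-by-samples observed expression matrix.
#' @param sets Gene-set collection.
#' @param n_sims Number of simulations (default 100).
#' @param seed Optional integer seed.
#' @param min_size,max_size Set-size bounds, as in [enrich_pivot].
#' @return data.frame of class `null_score_store`: per (set, direction)
#'   `set_id`, `direction`, `min_score` (smallest null mHG score) and
#'   `p_star` (its exact p-value), plus attributes `n_sims` and `B`.
#' @export
empirical_null <- function(residuals, pivots, expr_matrix, sets,
                           n_sims = 100, seed = NULL,
                           min_size = 3, max_size = 2000) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  gene_names <- rownames(residuals)
  N <- length(gene_names)
  n <- ncol(residuals)
  set_idx <- lapply(sets, function(m)
    which(gene_names %in% m))
  names(set_idx) <- names(sets)
  Bvec <- lengths(set_idx)

  # standardized rows are invariant to column permutation
  rc <- residuals - rowMeans(residuals, na.rm = TRUE)
  rc[is.na(rc)] <- 0
  sr <- sqrt(rowSums(rc^2))
  rs <- rc / ifelse(sr == 0, 1, sr)
  ec <- expr_matrix[pivots, , drop = FALSE]
  ec <- ec - rowMeans(ec)
  ec <- ec / sqrt(rowSums(ec^2))

  mins <- matrix(Inf, length(sets), 2,
                 dimnames = list(names(sets), c("top", "bottom")))
  for (k in seq_len(n_sims)) {
    perm <- sample.int(n)
    rmat <- rs[, perm, drop = FALSE] %*% t(ec)  # genes x pivots
    for (p in seq_along(pivots)) {
      sc <- .score_all_sets(rmat[, p], gene_names, set_idx, N,
                            min_size, max_size)
      mins <- pmin(mins, sc)
    }
  }
  out <- data.frame(
    set_id = rep(rownames(mins), 2L),
    direction = rep(c("top", "bottom"), each = nrow(mins)),
    min_score = c(mins[, 1L], mins[, 2L]),
    stringsAsFactors = FALSE)
  out$p_star <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (is.finite(out$min_score[i]))
      out$p_star[i] <- mhg_pvalue_cpp(out$min_score[i], N,
                                      Bvec[[out$set_id[i]]])
  }
  attr(out, "n_sims") <- n_sims
  class(out) <- c("null_score_store", "data.frame")
  out
}

#' Final iPAC calls against the empirical null
#'
#' An association is called significant when it passed the Bonferroni
#' screen and its exact p-value is strictly below the empirical-null bar
#' for its gene set and direction (the p-value of the minimum null score
#' over all pivots and simulations). iPAC genes are the pivots with at
#' least one significant association. The signed log score is
#' `-log10(p_exact)`, negated for bottom-direction associations.
#'
#' @param records data.frame from [bonferroni_filter].
#' @param null_store A `null_score_store` from [empirical_null].
#' @return List with `records` (input plus `empirical_significant` and
#'   `signed_log_score` columns) and `ipac_genes` (character vector).
#' @export
call_ipac <- function(records, null_store) {
  if (is.null(records$bonferroni_pass))
    stop("records must be Bonferroni-filtered first")
  key <- paste(records$set_id, records$direction)
  nkey <- paste(null_store$set_id, null_store$direction)
  p_star <- null_store$p_star[match(key, nkey)]
  records$empirical_significant <- records$bonferroni_pass &
    !is.na(p_star) & records$p_exact < p_star
  records$signed_log_score <- ifelse(records$direction == "bottom", -1, 1) *
    -log10(pmax(records$p_exact, 1e-300))
  list(records = records,
       ipac_genes = sort(unique(
         records$pivot[records$empirical_significant])))
}

#' Cross-cohort consistency of iPAC associations
#'
#' Re-scores chosen (pivot gene, gene set, direction) associations in a
#' second cohort and compares each signed log score to the background of
#' scores obtained by pairing random pivot genes with the same set. The
#' z-score `(score - mean(background)) / sd(background)` quantifies how
#' far the association stands above what arbitrary genes achieve.
#'
#' @param pairs data.frame with columns `pivot`, `set_id`, `direction`.
#' @param records2 A `gene_records` object for the validation cohort.
#' @param fits2 A `cis_fit` for the validation cohort
#'   ([fit_cis_models]).
#' @param sets Gene-set collection.
#' @param n_random Number of random background genes per set (default
#'   100).
#' @param seed Optional integer seed.
#' @return data.frame: per pair `pivot`, `set_id`, `direction`,
#'   `signed_log_score` (in cohort 2), `bg_mean`, `bg_sd`, `z`
#'   (`NA` with a warning when the background is degenerate); pairs whose
#'   pivot is absent from cohort 2 are dropped with a message.
#' @export
cross_cohort_consistency <- function(pairs, records2, fits2, sets,
                                     n_random = 100, seed = NULL) {
  stopifnot(inherits(records2, "gene_records"), inherits(fits2, "cis_fit"))
  if (!is.null(seed)) set.seed(seed)
  res2 <- residual_matrix(fits2)
  expr2 <- records2$expr
  universe <- rownames(expr2)
  present <- pairs$pivot %in% universe
  if (any(!present))
    message(sum(!present), " pair(s) skipped: pivot absent from cohort 2")
  pairs <- pairs[present, , drop = FALSE]
  score_one <- function(pivot, sid, dir) {
    rk <- suppressWarnings(trans_ranking(pivot, expr2, res2))
    rec <- enrich_pivot(rk, sets[sid], direction = dir)
    if (!nrow(rec)) return(NA_real_)
    sgn <- if (dir == "bottom") -1 else 1
    sgn * -log10(pmax(rec$p_exact, 1e-300))
  }
  out <- pairs
  out$signed_log_score <- NA_real_
  out$bg_mean <- out$bg_sd <- out$z <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    s <- score_one(pairs$pivot[i], pairs$set_id[i], pairs$direction[i])
    bg_genes <- sample(setdiff(universe, pairs$pivot[i]), n_random)
    bg <- vapply(bg_genes, score_one, numeric(1),
                 sid = pairs$set_id[i], dir = pairs$direction[i])
    out$signed_log_score[i] <- s
    out$bg_mean[i] <- mean(bg, na.rm = TRUE)
    out$bg_sd[i] <- stats::sd(bg, na.rm = TRUE)
    if (!is.na(out$bg_sd[i]) && out$bg_sd[i] > 0) {
      out$z[i] <- (s - out$bg_mean[i]) / out$bg_sd[i]
    } else {
      warning("degenerate background for set ", pairs$set_id[i],
              "; z undefined")
    }
  }
  out
}
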