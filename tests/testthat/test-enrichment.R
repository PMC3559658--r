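test_that("hypergeometric tail matches enumeration and the pmf identity", {
  expect_equal(hypergeometric_tail(0, 3, 2, 10), 1)
  expect_equal(hypergeometric_tail(1, 1, 1, 2), 0.5)
  expect_equal(hypergeometric_tail(2, 2, 2, 4), 1 / 6)
  expect_error(hypergeometric_tail(3, 2, 2, 4), "parameters")
  # HGT(b) - HGT(b+1) = PMF(b)
  for (b in 0:3) {
    d <- hypergeometric_tail(b, 5, 4, 12) - hypergeometric_tail(b + 1, 5, 4, 12)
    expect_equal(d, dhyper(b, 4, 8, 5), tolerance = 1e-12)
  }
})

test_that("mHG score scans prefixes correctly", {
  r <- mhg_score(c(1, 1, 0, 0))
  expect_equal(r$score, 1 / 6)
  expect_equal(r$n_star, 2L)
  expect_equal(r$b_star, 2L)
  expect_equal(r$fold, 2)           # (2/2)/(2/4)
  expect_equal(mhg_score(c(0, 0, 1, 1))$score, 1)
  expect_equal(mhg_score(c(0, 0, 0, 0))$score, 1)
  set.seed(61)
  for (i in 1:50) {
    N <- sample(4:12, 1)
    l <- integer(N); l[sample(N, sample(1:(N - 1), 1))] <- 1L
    expect_equal(mhg_score(l)$score, brute_mhg_score(l), tolerance = 1e-12)
  }
})

test_that("exact mHG p-value equals brute-force enumeration", {
  expect_equal(mhg_pvalue(1, 6, 0), 1)
  expect_equal(mhg_pvalue(1 / 6, 4, 2), 1 / 6)
  set.seed(71)
  for (i in 1:100) {
    N <- sample(4:12, 1)
    B <- sample(1:(N - 1), 1)
    l <- integer(N); l[sample(N, B)] <- 1L
    s <- mhg_score(l)$score
    p <- mhg_pvalue(s, N, B)
    expect_equal(p, brute_mhg_pvalue(l), tolerance = 1e-10,
                 info = paste(l, collapse = ""))
    # sandwich bound
    expect_gte(p, s - 1e-12)
    expect_lte(p, min(1, N * s) + 1e-12)
  }
})

test_that("pivot enrichment scores depend only on the membership pattern", {
  set.seed(81)
  n <- 30; g <- 60
  ids <- sprintf("g%02d", 1:g)
  ex <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  res <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  rk <- trans_ranking("g01", ex, res)
  sets <- list(TOP5 = rk$genes[1:5],
               MIXED = rk$genes[c(2, 10, 30, 50)],
               TINY = rk$genes[1:2],
               ABSENT = c("zz1", "zz2", "zz3"))
  rec <- enrich_pivot(rk, sets, "both", min_size = 3)
  # absent and undersized sets are skipped
  expect_setequal(unique(rec$set_id), c("TOP5", "MIXED"))
  # a set equal to the top k attains the minimal attainable score
  top <- rec[rec$set_id == "TOP5" & rec$direction == "top", ]
  expect_equal(top$mhg_score,
               hypergeometric_tail(5, 5, 5, g))
  expect_equal(top$n_star, 5L)
  # relabeling genes outside the set leaves scores unchanged
  rk2 <- rk
  out_idx <- which(!rk2$genes %in% sets$MIXED)
  rk2$genes[out_idx] <- paste0("x", rk2$genes[out_idx])
  rec2 <- enrich_pivot(rk2, sets["MIXED"], "both", min_size = 3)
  expect_equal(rec2$mhg_score,
               rec[rec$set_id == "MIXED", "mhg_score"])
})

test_that("Bonferroni screen is strict and monotone in the family size", {
  rec <- data.frame(pivot = "p", set_id = c("s1", "s2"),
                    direction = "top", p_exact = c(0.005, 0.04))
  r1 <- bonferroni_filter(rec, alpha = 0.05, n_tests = 10)
  expect_equal(r1$bonferroni_pass, c(FALSE, FALSE))  # 0.005*10 = alpha: strict
  r2 <- bonferroni_filter(rec, alpha = 0.05, n_tests = 1)
  expect_equal(r2$bonferroni_pass, c(TRUE, TRUE))
  r3 <- bonferroni_filter(rec, alpha = 0.05, n_tests = 20)
  expect_false(any(r3$bonferroni_pass & !r1$bonferroni_pass))
})

test_that("empirical null bar tightens with more simulations", {
  set.seed(91)
  n <- 20; g <- 80
  ids <- sprintf("g%02d", 1:g)
  ex <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  res <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  sets <- lapply(1:10, function(i) sample(ids, 8))
  names(sets) <- sprintf("SET%02d", 1:10)
  n1 <- empirical_null(res, "g01", ex, sets, n_sims = 2, seed = 5)
  n2 <- empirical_null(res, "g01", ex, sets, n_sims = 10, seed = 5)
  expect_true(all(n2$min_score <= n1$min_score + 1e-12))
  expect_true(all(n1$p_star > 0 & n1$p_star <= 1))
})

test_that("planted-null data produce no significant iPAC calls", {
  set.seed(101)
  n <- 30; g <- 150
  ids <- sprintf("g%03d", 1:g)
  ex <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  res <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  sets <- lapply(1:30, function(i) sample(ids, 10))
  names(sets) <- sprintf("SET%02d", 1:30)
  pivots <- c("g001", "g002")
  recs <- do.call(rbind, lapply(pivots, function(p)
    enrich_pivot(trans_ranking(p, ex, res), sets)))
  recs <- bonferroni_filter(recs, 0.05,
                            length(pivots) * length(sets) * 2)
  null_store <- empirical_null(res, pivots, ex, sets, n_sims = 10,
                               seed = 7)
  out <- call_ipac(recs, null_store)
  expect_lte(length(out$ipac_genes), 1)
  # strictness: a record exactly at the bar is not significant
  recs2 <- recs[1, , drop = FALSE]
  recs2$bonferroni_pass <- TRUE
  ns2 <- null_store
  ns2$p_star[paste(ns2$set_id, ns2$direction) ==
               paste(recs2$set_id, recs2$direction)] <- recs2$p_exact
  out2 <- call_ipac(recs2, ns2)
  expect_false(out2$records$empirical_significant)
})

test_that("signed log scores carry the direction", {
  rec <- data.frame(pivot = "p", set_id = "s", direction = c("top", "bottom"),
                    p_exact = c(1e-4, 1e-3), bonferroni_pass = TRUE)
  ns <- data.frame(set_id = "s", direction = c("top", "bottom"),
                   min_score = 1e-6, p_star = 1e-2)
  out <- call_ipac(rec, ns)
  expect_equal(out$records$signed_log_score, c(4, -3))
  expect_true(all(out$records$empirical_significant))
})

test_that("true associations replicate in an independent cohort", {
  spec <- small_spec()
  zs <- vapply(1:3, function(s) {
    c1 <- generate_cohort(spec, seed = s)
    c2 <- generate_cohort(spec, seed = s + 100, template = c1)
    seg2 <- segment_matrix(c2$cn, pcf_params())
    rec2 <- match_probes(c2$expr, seg2$pcf)
    fits2 <- suppressWarnings(fit_cis_models(rec2))
    pairs <- data.frame(pivot = c1$truth$driver, set_id = "MODULE_1",
                        direction = "top", stringsAsFactors = FALSE)
    cc <- cross_cohort_consistency(pairs, rec2, fits2, c2$sets,
                                   n_random = 40, seed = s)
    cc$z
  }, numeric(1))
  expect_true(all(zs > 2))
})

test_that("cross-cohort scoring skips absent pivots and flags flat backgrounds", {
  set.seed(111)
  n <- 20; g <- 40
  ids <- sprintf("g%02d", 1:g)
  ex <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  cn <- matrix(rnorm(g * n), g, dimnames = list(ids, sprintf("S%02d", 1:n)))
  rec <- make_records(cn, ex)
  fits <- fit_cis_models(rec, min_pairs = 10)
  sets <- list(S1 = ids[1:8])
  pairs <- data.frame(pivot = c("missing_gene", "g05"), set_id = "S1",
                      direction = "top", stringsAsFactors = FALSE)
  expect_message(out <- cross_cohort_consistency(pairs, rec, fits, sets,
                                                 n_random = 10, seed = 2),
                 "skipped")
  expect_equal(out$pivot, "g05")
  expect_true(is.finite(out$z) || is.na(out$z))
})
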