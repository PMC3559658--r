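test_that("cis correlation matches hand-computed Pearson values", {
  cn <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3), c = c(0, 1, 2, 3))
  ex <- rbind(a = c(0, 1, 2, 3), b = -c(0, 1, 2, 3), c = c(1, 1, 3, 3))
  colnames(cn) <- colnames(ex) <- sprintf("S%d", 1:4)
  rec <- make_records(cn, ex)
  r <- cis_correlation(rec, min_pairs = 3)
  expect_equal(unname(r["a"]), 1)
  expect_equal(unname(r["b"]), -1)
  expect_equal(unname(r["c"]), 0.894427, tolerance = 1e-6)
})

test_that("zero-variance and short rows yield NA with a warning", {
  cn <- rbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, NA))
  ex <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
  colnames(cn) <- colnames(ex) <- sprintf("S%d", 1:4)
  rec <- make_records(cn, ex)
  expect_warning(r <- cis_correlation(rec, min_pairs = 3), "zero variance")
  expect_true(is.na(r["a"]))
  expect_equal(unname(r["b"]), 1)
  expect_warning(expect_warning(r2 <- cis_correlation(rec, min_pairs = 4),
                                "pairs"), "zero variance")
  expect_true(is.na(r2["b"]))
})

test_that("cis model fit reproduces closed-form OLS", {
  # exact linear relation
  c0 <- c(0, 0.5, 1, 1.5)
  f <- fit_cis_model(2 + 3 * c0, c0)
  expect_equal(f$a, 2)
  expect_equal(f$b, 3)
  expect_equal(f$residuals, rep(0, 4))

  # hand-derived: b = 3/2, a = 5/6, residuals (1/6, -1/3, 1/6)
  f2 <- fit_cis_model(c(1, 2, 4), c(0, 1, 2))
  expect_equal(f2$b, 1.5)
  expect_equal(f2$a, 5 / 6)
  expect_equal(f2$residuals, c(1 / 6, -1 / 3, 1 / 6))

  # degenerate copy number: slope 0, centered residuals
  expect_warning(f3 <- fit_cis_model(c(1, 2, 3), c(1, 1, 1)), "variance")
  expect_equal(f3$b, 0)
  expect_equal(f3$residuals, c(-1, 0, 1))
})

test_that("OLS identities hold for every fitted gene", {
  set.seed(17)
  n <- 40; g <- 30
  cn <- matrix(rnorm(g * n), g, dimnames = list(sprintf("g%02d", 1:g), NULL))
  ex <- 0.8 * cn + matrix(rnorm(g * n, 0, 0.5), g)
  colnames(cn) <- colnames(ex) <- sprintf("S%02d", 1:n)
  fits <- fit_cis_models(make_records(cn, ex))
  res <- residual_matrix(fits)
  expect_equal(dim(res), dim(ex))
  for (i in seq_len(g)) {
    expect_lt(abs(mean(res[i, ])), 1e-9)
    expect_lt(abs(cor(res[i, ], cn[i, ])), 1e-9)
  }
  # vectorized fits agree with the single-gene fit
  f1 <- fit_cis_model(ex[3, ], cn[3, ])
  expect_equal(unname(fits$a["g03"]), f1$a)
  expect_equal(unname(fits$b["g03"]), f1$b)
})

test_that("residuals of a flat-copy-number gene are centered expression", {
  set.seed(2)
  n <- 30
  cn <- rbind(flat = rep(0, n), strong = rnorm(n))
  ex <- rbind(flat = rnorm(n, 5), strong = 2 + cn["strong", ])
  colnames(cn) <- colnames(ex) <- sprintf("S%02d", 1:n)
  fits <- suppressWarnings(fit_cis_models(make_records(cn, ex)))
  res <- residual_matrix(fits)
  expect_equal(res["flat", ], ex["flat", ] - mean(ex["flat", ]),
               tolerance = 1e-9)
  expect_equal(unname(res["strong", ]), rep(0, n), tolerance = 1e-9)
})

test_that("gene-shuffle FDR behaves at the permutation-invariant extremes", {
  set.seed(9)
  n <- 20; g <- 15
  base <- rnorm(n)
  # all CN rows identical: shuffling changes nothing => fdr = 1
  cn <- matrix(rep(base, each = g), g,
               dimnames = list(sprintf("g%02d", 1:g), NULL))
  ex <- cn + matrix(rnorm(g * n, 0, 0.1), g)
  colnames(cn) <- colnames(ex) <- sprintf("S%02d", 1:n)
  f <- shuffle_fdr(make_records(cn, ex), cutoff = 0.6, n_shuffles = 20,
                   seed = 1, min_pairs = 10)
  expect_gt(f$n_observed, 0)
  expect_equal(f$fdr_estimate, 1)

  # independent rows far below the cutoff: no null exceedance
  cn2 <- matrix(rnorm(g * n, 0, 1e-4), g,
                dimnames = list(sprintf("g%02d", 1:g), NULL))
  ex2 <- matrix(seq_len(g * n), g,
                dimnames = list(sprintf("g%02d", 1:g), NULL))
  ex2 <- ex2 + rnorm(g * n, 0, 1e6)  # uncorrelated noise
  colnames(cn2) <- colnames(ex2) <- sprintf("S%02d", 1:n)
  f2 <- shuffle_fdr(make_records(cn2, ex2), cutoff = 0.99,
                    n_shuffles = 20, seed = 1, min_pairs = 10)
  expect_equal(f2$mean_null, 0)
  expect_equal(f2$fdr_estimate, 0)
})

test_that("gene-shuffle FDR is calibrated under a global null", {
  fdrs <- vapply(1:20, function(s) {
    set.seed(s)
    ng <- 300; n <- 15
    ids <- sprintf("g%03d", 1:ng)
    cn <- matrix(rnorm(ng * n), ng, dimnames = list(ids, NULL))
    ex <- matrix(rnorm(ng * n), ng, dimnames = list(ids, NULL))
    colnames(cn) <- colnames(ex) <- sprintf("S%02d", 1:n)
    shuffle_fdr(make_records(cn, ex), cutoff = 0.6, n_shuffles = 50,
                min_pairs = 10)$fdr_estimate
  }, numeric(1))
  # with CN and expression independent every discovery is false; the
  # shuffle estimate should be near 1 on average
  expect_gt(mean(fdrs), 0.5)
  expect_lt(mean(fdrs), 2)
})

test_that("in-cis selection intersects aberrance with a strict cutoff", {
  cis_r <- c(a = 0.6, b = 0.9, c = 0.9, d = NA)
  common <- data.frame(gene_symbol = c("a", "b", "c", "d"),
                       commonly_aberrant = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(select_cis_genes(cis_r, common, 0.6), "b")
  expect_error(select_cis_genes(cis_r, common, 1.1), "cutoff")
})

test_that("in-cis selection is invariant to joint sample permutation", {
  set.seed(31)
  coh <- generate_cohort(small_spec(), seed = 4)
  seg <- segment_matrix(coh$cn, pcf_params())
  rec <- match_probes(coh$expr, seg$pcf)
  fits <- suppressWarnings(fit_cis_models(rec))
  calls <- call_aberrations(rec$cn, 0.1)
  c_thr <- sign_test_threshold(max_aberration_count(calls), 0.05)
  common <- select_common_aberrant(calls, 0.1, c_thr)
  sel1 <- select_cis_genes(fits$cis_r, common, 0.6)

  perm <- sample(ncol(rec$cn))
  rec2 <- rec
  rec2$cn <- rec$cn[, perm]
  rec2$expr <- rec$expr[, perm]
  fits2 <- suppressWarnings(fit_cis_models(rec2))
  calls2 <- call_aberrations(rec2$cn, 0.1)
  common2 <- select_common_aberrant(calls2, 0.1, c_thr)
  expect_identical(sort(sel1),
                   sort(select_cis_genes(fits2$cis_r, common2, 0.6)))
})

test_that("trans ranking orders genes by correlation with deterministic ties", {
  set.seed(12)
  n <- 24
  piv <- rnorm(n)
  ids <- c("p", "mirror", "noise1", "noise2", "flat")
  ex <- rbind(p = piv, mirror = rnorm(n), noise1 = rnorm(n),
              noise2 = rnorm(n), flat = rnorm(n))
  res <- rbind(p = rnorm(n), mirror = piv, noise1 = rnorm(n),
               noise2 = rnorm(n), flat = rep(1, n))
  dimnames(ex) <- dimnames(res) <- list(ids, sprintf("S%02d", 1:n))
  expect_warning(rk <- trans_ranking("p", ex, res), "zero-variance")
  expect_equal(rk$genes[1], "mirror")
  expect_equal(rk$r[1], 1)
  # zero-variance residual row sits at correlation 0
  expect_equal(rk$r[match("flat", rk$genes)], 0)
  # full universe covered, descending order
  expect_setequal(rk$genes, ids)
  expect_true(all(diff(rk$r) <= 0))
  # exclude_self drops the pivot
  expect_warning(rk2 <- trans_ranking("p", ex, res, exclude_self = TRUE))
  expect_false("p" %in% rk2$genes)
})

test_that("copy-number adjustment removes co-amplification confounding", {
  un <- ad <- numeric(10)
  for (s in 1:10) {
    rec <- co_amplicon_fixture(n_samples = 100, event_fraction = 0.4,
                               magnitude = 1.0, noise_sd = 0.3, seed = s)
    un[s] <- cor(rec$expr["GA", ], rec$expr["GB", ])
    fits <- fit_cis_models(rec, min_pairs = 10)
    res <- residual_matrix(fits)
    ad[s] <- cor(res["GA", ], res["GB", ])
  }
  expect_gt(mean(un), 0.5)
  expect_lt(mean(abs(ad)), 0.15)
})
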