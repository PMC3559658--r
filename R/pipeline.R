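#' Pipeline configuration
#'
#' Collects every tunable parameter of the workflow with validation.
#' Unknown keys are rejected.
#'
#' @param gamma,kmin Segmentation penalty and minimum segment length
#'   ([pcf_params]).
#' @param tau Aberration-calling threshold on the log2 scale.
#' @param alpha_sign Level of the binomial sign test.
#' @param freq_min Aberration-frequency threshold (strict `>`).
#' @param use_frequency,use_sign_test Toggles for the two
#'   commonly-aberrant filters.
#' @param cis_cutoff In-cis correlation cutoff in (0, 1).
#' @param n_shuffles Gene shuffles for the cis FDR estimate.
#' @param bonferroni_alpha Family-wise level of the Bonferroni screen.
#' @param n_sims Sample shuffles for the empirical enrichment null.
#' @param min_set_size,max_set_size Gene-set size bounds in the universe.
#' @param min_pairs Minimum complete sample pairs for correlations.
#' @param exclude_self Drop each pivot from its own ranking.
#' @param seed Integer seed driving every random step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gamma = 40, kmin = 5, tau = 0.1,
                            alpha_sign = 0.05, freq_min = 0.10,
                            use_frequency = TRUE, use_sign_test = TRUE,
                            cis_cutoff = 0.6, n_shuffles = 2000,
                            bonferroni_alpha = 0.05, n_sims = 100,
                            min_set_size = 3, max_set_size = 2000,
                            min_pairs = 10, exclude_self = FALSE,
                            seed = 1) {
  cfg <- list(gamma = gamma, kmin = kmin, tau = tau,
              alpha_sign = alpha_sign, freq_min = freq_min,
              use_frequency = use_frequency, use_sign_test = use_sign_test,
              cis_cutoff = cis_cutoff, n_shuffles = n_shuffles,
              bonferroni_alpha = bonferroni_alpha, n_sims = n_sims,
              min_set_size = min_set_size, max_set_size = max_set_size,
              min_pairs = min_pairs, exclude_self = exclude_self,
              seed = seed)
  if (cfg$gamma < 0) stop("gamma must be >= 0")
  if (cfg$kmin < 1) stop("kmin must be >= 1")
  if (cfg$tau <= 0) stop("tau must be > 0")
  if (cfg$alpha_sign <= 0 || cfg$alpha_sign >= 1)
    stop("alpha_sign must be in (0, 1)")
  if (cfg$freq_min < 0 || cfg$freq_min >= 1)
    stop("freq_min must be in [0, 1)")
  if (cfg$cis_cutoff <= 0 || cfg$cis_cutoff >= 1)
    stop("cis_cutoff must be in (0, 1)")
  if (cfg$n_shuffles < 1 || cfg$n_sims < 1)
    stop("n_shuffles and n_sims must be >= 1")
  if (cfg$bonferroni_alpha <= 0 || cfg$bonferroni_alpha >= 1)
    stop("bonferroni_alpha must be in (0, 1)")
  if (cfg$min_set_size < 1 || cfg$max_set_size < cfg$min_set_size)
    stop("invalid set size bounds")
  structure(cfg, class = "pipeline_config")
}

#' Validate a configuration given as a plain list
#'
#' Convenience for configs read from YAML/flat files: unknown keys are an
#' error, known keys override the defaults of [pipeline_config].
#'
#' @param x Named list of parameter overrides.
#' @return A validated `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Run the full workflow on in-memory inputs
#'
#' Executes the complete analysis in order: segmentation of the
#' copy-number track, probe matching into gene-level matrices, aberration
#' calling with the frequency filter and binomial sign test, cis-model
#' fitting with the gene-shuffle FDR estimate, in-cis gene selection,
#' per-pivot trans rankings, mHG enrichment with Bonferroni screening,
#' the sample-shuffle empirical null, and the final iPAC calls. All
#' randomness is driven by `config$seed`, so identical inputs and config
#' reproduce the result exactly.
#'
#' @param cn Probe-level copy-number [genomic_matrix].
#' @param expr Probe-level expression [genomic_matrix] with gene symbols.
#' @param sets Gene-set collection ([read_gmt]).
#' @param config A [pipeline_config].
#' @return List with `segments`, `records`, `common`, `fits`, `cis_fdr`,
#'   `cis_genes`, `associations`, `null_store`, `ipac_genes` and
#'   `manifest` (config, seed, stage-wise counts).
#' @export
run_ipac <- function(cn, expr, sets, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  set.seed(config$seed)

  seg <- segment_matrix(cn, pcf_params(config$gamma, config$kmin))
  records <- match_probes(expr, seg$pcf)

  calls <- call_aberrations(records$cn, config$tau)
  m_max <- max_aberration_count(calls)
  c_thr <- if (m_max >= 1L)
    sign_test_threshold(m_max, config$alpha_sign) else 1L
  common <- select_common_aberrant(calls, config$freq_min, c_thr,
                                   config$use_frequency,
                                   config$use_sign_test)

  fits <- suppressWarnings(fit_cis_models(records, config$min_pairs))
  cis_fdr <- shuffle_fdr(records, config$cis_cutoff, config$n_shuffles,
                         min_pairs = config$min_pairs)
  cis_genes <- select_cis_genes(fits$cis_r, common, config$cis_cutoff)

  residuals <- residual_matrix(fits)
  assoc <- list()
  for (g in cis_genes) {
    rk <- suppressWarnings(
      trans_ranking(g, records$expr, residuals, config$exclude_self))
    assoc[[g]] <- enrich_pivot(rk, sets, "both",
                               config$min_set_size, config$max_set_size)
  }
  assoc <- if (length(assoc)) do.call(rbind, c(assoc, make.row.names = FALSE))
  else data.frame(pivot = character(), set_id = character(),
                  direction = character(), mhg_score = numeric(),
                  p_exact = numeric(), n_star = integer(),
                  b_star = integer(), fold = numeric(),
                  stringsAsFactors = FALSE)

  n_tests <- max(1L, length(cis_genes) * length(unique(assoc$set_id)) * 2L)
  assoc <- bonferroni_filter(assoc, config$bonferroni_alpha, n_tests)

  if (length(cis_genes)) {
    null_store <- empirical_null(residuals, cis_genes, records$expr, sets,
                                 config$n_sims,
                                 min_size = config$min_set_size,
                                 max_size = config$max_set_size)
    final <- call_ipac(assoc, null_store)
  } else {
    null_store <- NULL
    assoc$empirical_significant <- logical(0)
    assoc$signed_log_score <- numeric(0)
    final <- list(records = assoc, ipac_genes = character(0))
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    counts = list(
      n_genes = nrow(records$genes),
      n_commonly_aberrant = sum(common$commonly_aberrant),
      n_cis = length(cis_genes),
      n_ipac = length(final$ipac_genes),
      n_associations_tested = nrow(final$records),
      n_bonferroni = sum(final$records$bonferroni_pass),
      n_significant = sum(final$records$empirical_significant)),
    cis_fdr_estimate = cis_fdr$fdr_estimate,
    sign_test = list(m_max = m_max, c = c_thr))

  list(segments = seg$segments, records = records, common = common,
       fits = fits, cis_fdr = cis_fdr, cis_genes = cis_genes,
       associations = final$records, null_store = null_store,
       ipac_genes = final$ipac_genes, manifest = manifest)
}

#' Run the workflow from files and write the result bundle
#'
#' File-level front end for [run_ipac]: reads the probe-level TSV tracks
#' and the GMT collection, runs the pipeline, and writes
#' `segments.seg`, `common.tsv`, `cis.tsv`, `associations.tsv`,
#' `ipac_genes.tsv` and `manifest.tsv` into the output directory. Output
#' files are deterministic: rerunning with the same inputs and seed
#' produces byte-identical files.
#'
#' @param cn_path,expr_path,gmt_path Input file paths.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config] or plain list of overrides.
#' @return The [run_ipac] result bundle, invisibly.
#' @export
run_pipeline <- function(cn_path, expr_path, gmt_path, out_dir,
                         config = pipeline_config()) {
  config <- as_pipeline_config(config)
  cn <- read_matrix(cn_path, "copy_number")
  expr <- read_matrix(expr_path, "expression")
  sets <- read_gmt(gmt_path)
  res <- run_ipac(cn, expr, sets, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(res$segments, file.path(out_dir, "segments.seg"),
                sort_by = c("sample", "chromosome", "start_pos"))
  write_results(res$common, file.path(out_dir, "common.tsv"),
                sort_by = "gene_symbol")
  cis_tab <- data.frame(gene_symbol = names(res$fits$cis_r),
                        cis_r = unname(res$fits$cis_r),
                        a = unname(res$fits$a), b = unname(res$fits$b),
                        selected = names(res$fits$cis_r) %in% res$cis_genes,
                        stringsAsFactors = FALSE)
  write_results(cis_tab, file.path(out_dir, "cis.tsv"),
                sort_by = "gene_symbol")
  write_results(res$associations, file.path(out_dir, "associations.tsv"),
                sort_by = c("pivot", "set_id", "direction"))
  write_results(data.frame(gene_symbol = res$ipac_genes,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "ipac_genes.tsv"))
  man <- res$manifest
  flat <- c(list(seed = man$seed), man$config, man$counts,
            list(cis_fdr_estimate = man$cis_fdr_estimate,
                 sign_test_m_max = man$sign_test$m_max,
                 sign_test_c = man$sign_test$c))
  write_results(data.frame(key = names(flat),
                           value = vapply(flat, function(v)
                             paste(format(v), collapse = ","), character(1)),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "manifest.tsv"), sort_by = "key")
  invisible(res)
}
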