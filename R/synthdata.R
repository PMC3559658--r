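#' Specification of a synthetic matched cohort
#'
#' Describes the ground truth of a simulated cohort of matched
#' copy-number and expression profiles: a regular probe layout, segmental
#' aberration events hitting a fixed fraction of samples, a dosage-driven
#' (cis) expression response for the genes under an event, and one
#' planted trans module whose members track the driver gene's expression.
#'
#' The defaults describe the benchmark cohort used throughout the
#' package's validation: 3000 genes on 20 chromosomes, 100 samples, one
#' high-level amplicon (log2 magnitude 1.5, 30% of samples) spanning a
#' driver and 10 passenger genes, unit cis slope for amplicon genes, a
#' 50-gene trans module coupled to the driver at 0.7, and 500 size-matched
#' decoy sets. Copy-number probes are laid 4 per gene with Gaussian probe
#' noise (sd 0.2); expression noise sd is 0.3.
#'
#' @param n_genes,n_samples,n_chromosomes Cohort dimensions.
#' @param cn_probes_per_gene Copy-number probes per gene position.
#' @param cn_noise_sd,expr_noise_sd Gaussian noise sd for copy-number
#'   probes and expression values (log2 scale).
#' @param events data.frame with columns `chromosome`, `start`, `end`
#'   (basepair span), `magnitude` (log2 shift) and `fraction` (affected
#'   sample fraction in (0, 1]). Default: one amplicon on chromosome 1.
#' @param cis_slope Slope `b` of the cis model for genes under an event.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   expression intercepts `a`.
#' @param module_size,coupling,module_noise_sd Trans-module membership
#'   count, coupling coefficient to the driver's expression deviation,
#'   and member-level noise sd.
#' @param n_decoys,decoy_size Number and size of decoy gene sets.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 3000, n_samples = 100, n_chromosomes = 20,
                       cn_probes_per_gene = 4,
                       cn_noise_sd = 0.2, expr_noise_sd = 0.3,
                       events = NULL, cis_slope = 1.0,
                       baseline_mean = 7, baseline_sd = 1,
                       module_size = 50, coupling = 0.7,
                       module_noise_sd = 0.3,
                       n_decoys = 500, decoy_size = 50) {
  genes_per_chr <- n_genes / n_chromosomes
  if (genes_per_chr != round(genes_per_chr))
    stop("n_genes must be divisible by n_chromosomes")
  spacing <- 1e5
  if (is.null(events)) {
    # one 11-gene amplicon centred mid-chromosome 1; driver is the middle gene
    ev_genes <- (round(genes_per_chr / 2) - 5):(round(genes_per_chr / 2) + 5)
    events <- data.frame(chromosome = "1",
                         start = ev_genes[1L] * spacing,
                         end = ev_genes[length(ev_genes)] * spacing,
                         magnitude = 1.5, fraction = 0.3,
                         stringsAsFactors = FALSE)
  }
  if (any(events$fraction <= 0 | events$fraction > 1))
    stop("event fractions must be in (0, 1]")
  if (any(events$end < events$start)) stop("event end before start")
  if (any(events$end > genes_per_chr * spacing))
    stop("event outside chromosome bounds")
  for (chr in unique(events$chromosome)) {
    ev <- events[events$chromosome == chr, , drop = FALSE]
    if (nrow(ev) > 1L) {
      o <- order(ev$start)
      ev <- ev[o, ]
      overl <- ev$start[-1L] <= ev$end[-nrow(ev)]
      if (any(overl & (ev$magnitude[-1L] != ev$magnitude[-nrow(ev)])))
        stop("overlapping events with conflicting magnitudes on chromosome ",
             chr)
    }
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_chromosomes = n_chromosomes,
                 genes_per_chr = genes_per_chr, gene_spacing = spacing,
                 cn_probes_per_gene = cn_probes_per_gene,
                 cn_noise_sd = cn_noise_sd, expr_noise_sd = expr_noise_sd,
                 events = events, cis_slope = cis_slope,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 module_size = module_size, coupling = coupling,
                 module_noise_sd = module_noise_sd,
                 n_decoys = n_decoys, decoy_size = decoy_size),
            class = "synth_spec")
}

#' Generate a synthetic matched cohort with known truth
#'
#' Simulates probe-level copy-number and expression tracks under a
#' [synth_spec]: copy number is baseline 0 plus event magnitudes for the
#' affected samples plus Gaussian probe noise; expression of gene `g` is
#' `a_g + b_g * c_g + noise` where `c_g` is the true (noise-free) segment
#' value at the gene; each trans-module member additionally receives
#' `coupling * (driver expression - its mean)`. Exactly
#' `round(fraction * n_samples)` samples are affected per event, drawn
#' without replacement.
#'
#' @param spec A [synth_spec].
#' @param seed Integer seed; the cohort is a deterministic function of
#'   `(spec, seed)`.
#' @param template Optional: a previous [generate_cohort] result. Its
#'   planted truth (driver, module membership) and gene-set collection
#'   are reused so that the new cohort is an independent sample of the
#'   same underlying biology — the setting of a validation cohort.
#' @return List with `cn` and `expr` ([genomic_matrix] objects), `sets`
#'   (gene-set collection embedding the planted module plus decoys) and
#'   `truth` (list: `events` with affected sample ids, `driver`,
#'   `passengers`, `module_members`, `a`, `b`, `true_gene_cn`).
#' @export
generate_cohort <- function(spec = synth_spec(), seed = 1, template = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  ns <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(ns))
  gpc <- spec$genes_per_chr
  gene_chr <- rep(as.character(seq_len(spec$n_chromosomes)), each = gpc)
  gene_pos <- rep(seq_len(gpc) * spec$gene_spacing, spec$n_chromosomes)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))

  # affected samples per event (exact count, without replacement)
  events <- spec$events
  events$n_affected <- as.integer(round(events$fraction * ns))
  affected <- lapply(events$n_affected, function(k) sample.int(ns, k))

  # true gene-level copy number
  true_cn <- matrix(0, spec$n_genes, ns, dimnames = list(genes, samples))
  for (i in seq_len(nrow(events))) {
    hit <- gene_chr == events$chromosome[i] &
      gene_pos >= events$start[i] & gene_pos <= events$end[i]
    true_cn[hit, affected[[i]]] <- true_cn[hit, affected[[i]]] +
      events$magnitude[i]
  }
  under_event <- rowSums(true_cn != 0) > 0

  # copy-number probes: cn_probes_per_gene per gene, evenly spaced
  k <- spec$cn_probes_per_gene
  probe_off <- (seq_len(k) - (k + 1) / 2) * spec$gene_spacing / k
  cn_chr <- rep(gene_chr, each = k)
  cn_pos <- rep(gene_pos, each = k) + rep(probe_off, spec$n_genes)
  cn_pos <- pmax(1, round(cn_pos))
  cn_true_probe <- true_cn[rep(seq_len(spec$n_genes), each = k), ,
                           drop = FALSE]
  cn_vals <- cn_true_probe +
    matrix(stats::rnorm(length(cn_true_probe), 0, spec$cn_noise_sd),
           nrow(cn_true_probe))
  rownames(cn_vals) <- sprintf("CP%06d", seq_len(nrow(cn_vals)))
  colnames(cn_vals) <- samples

  # expression: baseline + cis response + module coupling + noise
  a <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  b <- ifelse(under_event, spec$cis_slope, 0)
  names(a) <- names(b) <- genes
  expr <- a + b * true_cn +
    matrix(stats::rnorm(length(true_cn), 0, spec$expr_noise_sd),
           spec$n_genes)
  dimnames(expr) <- list(genes, samples)

  driver <- NA_character_; passengers <- character(); members <- character()
  if (nrow(events) >= 1L && any(under_event)) {
    ev_genes <- genes[gene_chr == events$chromosome[1L] &
                        gene_pos >= events$start[1L] &
                        gene_pos <= events$end[1L]]
    driver <- ev_genes[ceiling(length(ev_genes) / 2)]
    passengers <- setdiff(ev_genes, driver)
    eligible <- genes[!under_event]
    members <- if (!is.null(template)) template$truth$module_members
    else sort(sample(eligible, spec$module_size))
    drv_dev <- expr[driver, ] - mean(expr[driver, ])
    # member rows are rebuilt: baseline + coupled driver deviation +
    # member-level noise (replacing the background expression noise)
    expr[members, ] <- a[members] +
      rep(spec$coupling, length(members)) %o% drv_dev +
      matrix(stats::rnorm(length(members) * ns, 0, spec$module_noise_sd),
             length(members))
  }

  # gene sets: the planted module plus size-matched decoys drawn from
  # genes that are neither module members nor under an event
  sets <- list()
  if (!is.null(template)) {
    sets <- template$sets
  } else if (length(members)) {
    decoy_pool <- setdiff(genes[!under_event], members)
    sets <- c(list(MODULE_1 = members),
              stats::setNames(
                lapply(seq_len(spec$n_decoys), function(i)
                  sort(sample(decoy_pool, spec$decoy_size))),
                sprintf("DECOY_%04d", seq_len(spec$n_decoys))))
    sets <- lapply(sets, function(s) {
      attr(s, "description") <- "synthetic"
      s
    })
    class(sets) <- "gene_set_collection"
  }

  cn_gm <- genomic_matrix(cn_vals, chromosome = cn_chr, position = cn_pos,
                          kind = "copy_number")
  ex_gm <- genomic_matrix(expr, chromosome = gene_chr, position = gene_pos,
                          gene_symbol = genes, kind = "expression")
  events$affected_samples <- vapply(affected, function(x)
    paste(samples[sort(x)], collapse = ","), character(1))
  list(cn = cn_gm, expr = ex_gm, sets = sets,
       truth = list(events = events, driver = driver,
                    passengers = passengers, module_members = members,
                    a = a, b = b, true_gene_cn = true_cn))
}

#' Two-gene co-amplification fixture
#'
#' The smallest cohort exhibiting copy-number confounding: two genes
#' share one copy-number event, and their expression values are the
#' (shared, noise-free) copy number plus independent Gaussian noise.
#' Their raw expression profiles are therefore correlated through the
#' event alone, while their copy-number-adjusted residuals are
#' independent by construction.
#'
#' @param n_samples Number of samples (default 100).
#' @param event_fraction Fraction of samples carrying the event (default
#'   0.4).
#' @param magnitude Log2 magnitude of the event (default 1.0).
#' @param noise_sd Expression noise sd (default 0.3).
#' @param seed Integer seed.
#' @return A `gene_records` object with genes `GA` and `GB`.
#' @export
co_amplicon_fixture <- function(n_samples = 100, event_fraction = 0.4,
                                magnitude = 1.0, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  n_aff <- as.integer(round(event_fraction * n_samples))
  c_shared <- numeric(n_samples)
  c_shared[sample.int(n_samples, n_aff)] <- magnitude
  cn <- rbind(GA = c_shared, GB = c_shared)
  expr <- cn + matrix(stats::rnorm(2 * n_samples, 0, noise_sd), 2)
  dimnames(cn) <- dimnames(expr) <- list(c("GA", "GB"), samples)
  structure(list(
    genes = data.frame(gene_symbol = c("GA", "GB"), chromosome = "1",
                       position = c(1e6, 2e6), stringsAsFactors = FALSE),
    cn = cn, expr = expr), class = "gene_records")
}
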