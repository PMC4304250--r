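#' Configuration for a synthetic PDAC-like cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. The defaults
#' describe a 96-sample cohort with three latent molecular subtypes of sizes
#' 43/45/8, subtype-specific marker genes shifted up on the log2 scale,
#' exponential survival with subtype medians 37.6/19.2/13.8 months,
#' per-subtype censoring fractions 27/43, 22/45 and 4/8, and binary
#' clinicopathologic covariates (R0 resection, distant metastasis,
#' recurrence) at per-subtype rates taken from the observed contingency
#' counts.
#'
#' @param n_genes Number of genes (default 2000).
#' @param subtype_sizes Integer vector of per-subtype sample counts
#'   (default \code{c(43, 45, 8)}).
#' @param markers_per_subtype Marker genes planted per subtype (default 100).
#' @param marker_log2_shift Upward shift, in log2 units, of a subtype's
#'   markers within that subtype (default 2).
#' @param noise_sd Gaussian noise sd in log2 units (default 0.5).
#' @param baseline_mean Baseline log2 expression level (default 8).
#' @param survival_medians Median survival per subtype in months
#'   (default \code{c(37.6, 19.2, 13.8)}).
#' @param censor_rate_per_subtype Target censoring fractions
#'   (default \code{c(27/43, 22/45, 4/8)}).
#' @param covariate_rates Named list of per-subtype probabilities for binary
#'   covariates \code{r0}, \code{distant_met}, \code{recurrence}.
#' @param seed Integer seed.
#' @return A validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_genes = 2000L,
                          subtype_sizes = c(43L, 45L, 8L),
                          markers_per_subtype = 100L,
                          marker_log2_shift = 2,
                          noise_sd = 0.5,
                          baseline_mean = 8,
                          survival_medians = c(37.6, 19.2, 13.8),
                          censor_rate_per_subtype = c(27 / 43, 22 / 45, 4 / 8),
                          covariate_rates = list(
                            r0          = c(39 / 43, 31 / 45, 6 / 8),
                            distant_met = c(17 / 43, 30 / 45, 3 / 8),
                            recurrence  = c(21 / 43, 32 / 45, 5 / 8)),
                          seed = 1L) {
  n_sub <- length(subtype_sizes)
  if (n_genes < 1) stop("n_genes must be positive")
  if (any(subtype_sizes < 1)) stop("subtype sizes must be >= 1")
  if (markers_per_subtype < 1) stop("markers_per_subtype must be >= 1")
  if (markers_per_subtype * n_sub > n_genes) {
    stop("marker blocks exceed the gene universe")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(survival_medians) != n_sub || any(survival_medians <= 0)) {
    stop("survival_medians must be positive, one per subtype")
  }
  if (length(censor_rate_per_subtype) != n_sub ||
      any(censor_rate_per_subtype < 0) || any(censor_rate_per_subtype >= 1)) {
    stop("censor rates must lie in [0, 1), one per subtype")
  }
  for (nm in names(covariate_rates)) {
    p <- covariate_rates[[nm]]
    if (length(p) != n_sub || any(p < 0) || any(p > 1)) {
      stop(sprintf("covariate rate '%s' must be in [0,1], one per subtype", nm))
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 subtype_sizes = as.integer(subtype_sizes),
                 markers_per_subtype = as.integer(markers_per_subtype),
                 marker_log2_shift = marker_log2_shift,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 survival_medians = survival_medians,
                 censor_rate_per_subtype = censor_rate_per_subtype,
                 covariate_rates = covariate_rates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Upper end u of the Uniform(0, u) follow-up window such that
# P(censor) = P(C < T) = (1 - exp(-rate * u)) / (rate * u) hits `target`.
.censor_window <- function(rate, target) {
  if (target <= 0) return(Inf)
  f <- function(u) (1 - exp(-rate * u)) / (rate * u) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e6, tol = 1e-10)$root
}

#' Simulate an expression cohort with planted subtypes
#'
#' Generates a log2-scale expression matrix, a clinical table and the ground
#' truth behind them. Expression is baseline Gaussian noise (mean
#' \code{baseline_mean}, sd \code{noise_sd}); each subtype owns a disjoint
#' block of \code{markers_per_subtype} genes shifted up by
#' \code{marker_log2_shift} in that subtype's samples only. Survival times
#' are exponential with rate \code{log(2) / median} for the sample's
#' subtype; censoring truncates by an independent uniform follow-up window
#' calibrated so the expected censoring fraction matches the configured
#' per-subtype rate. Binary covariates are Bernoulli draws at the
#' per-subtype rates. The same config and seed always reproduce identical
#' output.
#'
#' @param config A \code{"cohort_config"}.
#' @return List with \code{expression} (log2 matrix, genes x samples, ids
#'   \code{G000001...} / \code{S001...}), \code{clinical} (data.frame with
#'   columns sample_id, time_months, event, r_status, distant_met,
#'   recurrence, subtype_true), and \code{truth} (list with \code{labels},
#'   \code{marker_ids} per subtype, \code{enriched_set_ids}).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_genes = 200, seed = 7))
#' table(cohort$truth$labels)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_sub <- length(config$subtype_sizes)
  m <- sum(config$subtype_sizes)
  n <- config$n_genes
  labels <- rep(seq_len(n_sub), config$subtype_sizes)

  gene_ids <- sprintf("G%06d", seq_len(n))
  sample_ids <- sprintf("S%03d", seq_len(m))

  # disjoint random marker blocks
  marker_pool <- sample(n, config$markers_per_subtype * n_sub)
  marker_idx <- split(marker_pool, rep(seq_len(n_sub),
                                       each = config$markers_per_subtype))
  marker_ids <- lapply(marker_idx, function(i) gene_ids[i])
  names(marker_ids) <- paste0("subtype", seq_len(n_sub))

  expr <- matrix(stats::rnorm(n * m, mean = config$baseline_mean,
                              sd = config$noise_sd),
                 nrow = n, ncol = m, dimnames = list(gene_ids, sample_ids))
  for (s in seq_len(n_sub)) {
    expr[marker_idx[[s]], labels == s] <-
      expr[marker_idx[[s]], labels == s] + config$marker_log2_shift
  }

  rate <- log(2) / config$survival_medians
  t_event <- stats::rexp(m, rate = rate[labels])
  windows <- vapply(seq_len(n_sub), function(s) {
    .censor_window(rate[s], config$censor_rate_per_subtype[s])
  }, numeric(1))
  t_cens <- ifelse(is.infinite(windows[labels]), Inf,
                   stats::runif(m, 0, windows[labels]))
  time_months <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  draw <- function(p) stats::rbinom(m, 1L, p[labels])
  r0 <- draw(config$covariate_rates$r0)
  clinical <- data.frame(
    sample_id = sample_ids,
    time_months = time_months,
    event = event,
    r_status = ifelse(r0 == 1L, "R0", "R1R2"),
    distant_met = draw(config$covariate_rates$distant_met),
    recurrence = draw(config$covariate_rates$recurrence),
    subtype_true = labels,
    stringsAsFactors = FALSE
  )

  truth <- list(labels = stats::setNames(labels, sample_ids),
                marker_ids = marker_ids,
                enriched_set_ids = paste0(toupper(names(marker_ids)),
                                          "_MARKERS"))
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Build a gene-set collection around the planted markers
#'
#' Creates one gene set per planted marker group (named after
#' \code{truth$enriched_set_ids}) plus \code{n_decoy_sets} decoy sets of
#' genes drawn at random from the universe. The planted sets are the truth
#' an enrichment analysis should recover; the decoys calibrate its false
#' positive behavior.
#'
#' @param ground_truth The \code{truth} element of [simulate_cohort()].
#' @param n_decoy_sets Number of random decoy sets.
#' @param set_size Genes per decoy set (planted sets keep at most
#'   \code{set_size} of their markers).
#' @param gene_ids Character vector: the gene universe to draw decoys from.
#' @param seed Integer seed for the decoy draws.
#' @return Named list of character vectors (a gene-set collection).
#' @export
simulate_genesets <- function(ground_truth, n_decoy_sets = 10L,
                              set_size = 50L, gene_ids, seed = 1L) {
  if (set_size > length(gene_ids)) {
    stop("set_size exceeds the gene universe")
  }
  set.seed(seed)
  planted <- lapply(ground_truth$marker_ids, function(g) {
    g[seq_len(min(set_size, length(g)))]
  })
  names(planted) <- ground_truth$enriched_set_ids
  decoys <- lapply(seq_len(n_decoy_sets), function(i) {
    sample(gene_ids, set_size)
  })
  if (n_decoy_sets > 0) {
    names(decoys) <- sprintf("DECOY_%03d", seq_len(n_decoy_sets))
  }
  c(planted, decoys)
}
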