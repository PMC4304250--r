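#' Run the full subtype-discovery pipeline
#'
#' Orchestrates the stages end to end: exponential scaling, consensus NMF
#' rank selection, subtype assignment, Kaplan-Meier / log-rank survival
#' comparison, clinicopathologic association tests, one-vs-rest SAM marker
#' selection, and (when gene sets are supplied) GSEA between the two
#' largest subtypes. All outputs are written under \code{outdir} as TSV /
#' JSON, and the run log records every seed and parameter.
#'
#' @param expression Log2 expression matrix (genes x samples) or path to a
#'   TSV readable by [read_expression()].
#' @param clinical Clinical data frame or path to a CSV readable by
#'   [read_clinical()]; must contain \code{sample_id}, \code{time_months},
#'   \code{event}, and any categorical covariates to test.
#' @param gene_sets Optional named list of gene sets (or GMT path); when
#'   absent the GSEA stage is skipped.
#' @param k_min,k_max Rank range for [select_rank()] (defaults 2 to 4).
#' @param n_runs NMF restarts per rank (default 30).
#' @param seed Base seed driving every stochastic stage.
#' @param covariates Character vector of clinical columns for the
#'   association battery (default: the binary columns the synthetic cohort
#'   carries).
#' @param top_n Markers kept per subtype (default 20).
#' @param n_perm Permutations for SAM and GSEA (default 1000).
#' @param outdir Output directory (created if missing); \code{NULL} skips
#'   writing.
#' @return Invisibly, a list bundle: \code{rank_selection}, \code{labels},
#'   \code{survival} (medians + pairwise and overall log-rank),
#'   \code{associations}, \code{markers} (per subtype), \code{enrichment}.
#' @export
run_full_pipeline <- function(expression, clinical, gene_sets = NULL,
                              k_min = 2L, k_max = 4L, n_runs = 30L,
                              seed = 1L,
                              covariates = c("r_status", "distant_met",
                                             "recurrence"),
                              top_n = 20L, n_perm = 1000L, outdir = NULL) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (!all(colnames(expression) %in% clinical$sample_id)) {
    stop("clustering stage: clinical table does not cover all samples")
  }
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ]

  A <- exponential_scale(expression)
  sel <- select_rank(A, k_min = k_min, k_max = k_max, n_runs = n_runs,
                     base_seed = seed)
  labels <- sel$results[[paste0("k", sel$k_star)]]$labels

  records <- data.frame(time = clinical$time_months, event = clinical$event,
                        group = labels)
  groups <- sort(unique(labels))
  medians <- vapply(groups, function(g) {
    median_survival(km_estimate(records[records$group == g, ]))
  }, numeric(1))
  pairs <- utils::combn(groups, 2)
  pairwise <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      logrank_test(records, pr[1], pr[2])$p_value
    })
  )
  overall <- multigroup_logrank(records)
  surv <- list(medians = stats::setNames(medians, paste0("subtype", groups)),
               pairwise = pairwise, overall = overall)

  assoc <- do.call(rbind, lapply(intersect(covariates, names(clinical)),
                                 function(cv) {
    ct <- crosstab(clinical, cv, labels)
    data.frame(covariate = cv, p_value = categorical_test(ct),
               stringsAsFactors = FALSE)
  }))

  markers <- lapply(groups, function(g) {
    tab <- sam_de(expression, labels, g, n_perm = n_perm, seed = seed + g)
    select_markers(tab, top_n = top_n)
  })
  names(markers) <- paste0("subtype", groups)

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    two <- groups[order(-table(labels)[as.character(groups)])][1:2]
    keep <- labels %in% two
    enrichment <- gsea_significance(expression[, keep, drop = FALSE],
                                    labels[keep], gene_sets,
                                    n_perm = n_perm, seed = seed)
  }

  bundle <- list(rank_selection = sel, labels = labels, survival = surv,
                 associations = assoc, markers = markers,
                 enrichment = enrichment)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(sample_id = names(labels),
                                  subtype = labels),
                       file.path(outdir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(sel$cophenetic),
                         file.path(outdir, "cophenetic.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(data.frame(subtype = names(surv$medians),
                                  median_months = unname(surv$medians)),
                       file.path(outdir, "km_medians.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pairwise, file.path(outdir, "logrank_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(assoc)) {
      utils::write.table(assoc, file.path(outdir, "association_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (nm in names(markers)) {
      utils::write.table(markers[[nm]],
                         file.path(outdir, paste0("markers_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed, k_min = k_min, k_max = k_max, n_runs = n_runs,
           n_perm = n_perm, top_n = top_n, k_star = sel$k_star),
      file.path(outdir, "run_log.json"), auto_unbox = TRUE)
  }
  invisible(bundle)
}

#' Validation clustering on a marker panel
#'
#' Re-clusters an (external) expression matrix restricted to a previously
#' discovered marker panel: the expression rows are subset to the union of
#' the marker gene ids, exponentially scaled, and consensus NMF rank
#' selection is rerun over the requested range. Marker ids missing from
#' the matrix are dropped with a message; an empty intersection is an
#' error.
#'
#' @param expression Log2 expression matrix of the validation cohort.
#' @param marker_ids Character vector (or list of vectors) of marker gene
#'   ids, e.g. the \code{gene_id} columns of [select_markers()] output.
#' @param k_min,k_max Rank range (defaults 2 to 4).
#' @param n_runs,seed Passed to [select_rank()].
#' @return The \code{"rank_selection"} object for the marker-restricted
#'   matrix.
#' @export
run_validation_clustering <- function(expression, marker_ids, k_min = 2L,
                                      k_max = 4L, n_runs = 30L, seed = 1L) {
  panel <- unique(unlist(marker_ids))
  found <- intersect(panel, rownames(expression))
  if (length(found) == 0) {
    stop("no marker gene ids found in the validation expression matrix")
  }
  if (length(found) < length(panel)) {
    message(sprintf("%d of %d marker ids present in the validation matrix",
                    length(found), length(panel)))
  }
  A <- exponential_scale(expression[found, , drop = FALSE])
  select_rank(A, k_min = k_min, k_max = k_max, n_runs = n_runs,
              base_seed = seed)
}
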