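#' Sample connectivity matrix from an NMF coefficient matrix
#'
#' Each sample (column of \code{H}) is assigned to its dominant metagene
#' (row with the largest coefficient; ties go to the lowest metagene index).
#' The connectivity matrix has entry 1 where two samples share a dominant
#' metagene, else 0. It is symmetric with unit diagonal.
#'
#' @param H Non-negative k x m coefficient matrix.
#' @return m x m binary matrix.
#' @export
connectivity_matrix <- function(H) {
  H <- as.matrix(H)
  if (min(H) < 0) stop("H must be non-negative")
  cs <- colSums(H)
  if (any(cs == 0)) {
    stop("H contains an all-zero column; sample has no metagene assignment")
  }
  assign <- max.col(t(H), ties.method = "first")
  out <- outer(assign, assign, "==") * 1
  dimnames(out) <- list(colnames(H), colnames(H))
  out
}

#' Consensus matrix over NMF restarts
#'
#' Elementwise mean of the connectivity matrices from repeated NMF runs.
#' Entry (i, j) is the fraction of restarts in which samples i and j were
#' assigned to the same metagene; values near 0 or 1 everywhere indicate a
#' stable clustering.
#'
#' @param connectivities List of at least two equal-sized binary matrices.
#' @return m x m matrix with entries in \code{[0, 1]}.
#' @export
consensus_matrix <- function(connectivities) {
  if (length(connectivities) < 2) {
    stop("need at least two connectivity matrices")
  }
  d <- dim(connectivities[[1]])
  if (!all(vapply(connectivities, function(x) identical(dim(x), d), logical(1)))) {
    stop("connectivity matrices have mismatched shapes")
  }
  Reduce(`+`, connectivities) / length(connectivities)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Measures how faithfully average-linkage hierarchical clustering of the
#' consensus-derived distances \code{Y = 1 - consensus} preserves those
#' distances: the Pearson correlation, over sample pairs i < j, between
#' Y_ij and the dendrogram-induced (cophenetic) distances Z_ij. A value
#' near 1 means the consensus structure is nearly ultrametric, i.e. the
#' clustering is stable across restarts; the rank maximizing this
#' coefficient is the selected number of subtypes.
#'
#' A consensus whose off-diagonal distances are all equal carries no
#' clustering signal to contradict the dendrogram; this degenerate case is
#' defined as perfect agreement (1) and flagged with a message.
#'
#' @param consensus Symmetric m x m consensus matrix with entries in
#'   \code{[0, 1]} and unit diagonal.
#' @return Scalar in \code{[-1, 1]}.
#' @export
cophenetic_coefficient <- function(consensus) {
  Y <- stats::as.dist(1 - as.matrix(consensus))
  if (stats::sd(Y) < .Machine$double.eps^0.5) {
    message("constant consensus distances; cophenetic coefficient defined as 1")
    return(1.0)
  }
  hc <- stats::hclust(Y, method = "average")
  Z <- stats::cophenetic(hc)
  if (stats::sd(Z) < .Machine$double.eps^0.5) {
    message("constant dendrogram distances; cophenetic coefficient defined as 1")
    return(1.0)
  }
  stats::cor(as.vector(Y), as.vector(Z))
}

#' Cut a consensus dendrogram into subtype labels
#'
#' Labels come from cutting the average-linkage dendrogram of
#' \code{1 - consensus} into k groups. Label ids are renumbered by
#' decreasing cluster size, so subtype 1 is always the largest cluster
#' (ties broken by first occurrence).
#'
#' @param consensus_result A \code{"consensus_result"} from [select_rank()],
#'   or a bare consensus matrix (then \code{k} must be given).
#' @param k Number of groups; defaults to the result's rank.
#' @return Integer vector of labels in \code{1..k}, named by sample id.
#' @export
assign_subtypes <- function(consensus_result, k = NULL) {
  if (inherits(consensus_result, "consensus_result")) {
    cons <- consensus_result$consensus
    hc <- consensus_result$dendrogram
    if (is.null(k)) k <- consensus_result$k
  } else {
    cons <- as.matrix(consensus_result)
    if (is.null(k)) stop("k must be supplied with a bare consensus matrix")
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  }
  if (k > ncol(cons)) stop("requested more clusters than samples")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  remap <- integer(length(sizes))
  remap[order(-as.integer(sizes), as.integer(names(sizes)))] <- seq_along(sizes)
  labels <- remap[raw]
  names(labels) <- colnames(cons)
  labels
}

.consensus_for_rank <- function(A, k, n_runs, seeds, max_iter, conv_check) {
  conns <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fit <- fit_nmf(A, k, seed = seeds[r], max_iter = max_iter,
                   conv_check = conv_check)
    conns[[r]] <- connectivity_matrix(fit$H)
  }
  cons <- consensus_matrix(conns)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  res <- structure(
    list(k = as.integer(k), consensus = cons,
         cophenetic = cophenetic_coefficient(cons),
         labels = NULL, n_runs = as.integer(n_runs), dendrogram = hc),
    class = "consensus_result"
  )
  res$labels <- assign_subtypes(res)
  res
}

#' Consensus NMF over a rank range with cophenetic rank selection
#'
#' For each rank k in \code{k_min:k_max}, runs [fit_nmf()] \code{n_runs}
#' times from distinct seeds derived from \code{base_seed}, averages the
#' run connectivities into a consensus matrix, computes its cophenetic
#' coefficient and cuts its dendrogram into k subtypes. The selected rank
#' is the one with the maximal cophenetic coefficient (ties go to the
#' smallest rank), following the rule that the peak of the cophenetic
#' curve marks the most robust number of clusters.
#'
#' @param A Non-negative expression matrix (genes x samples), typically the
#'   output of [exponential_scale()].
#' @param k_min,k_max Rank range (defaults 2 to 4).
#' @param n_runs NMF restarts per rank (default 30).
#' @param base_seed Base seed; run r at rank k uses seed
#'   \code{base_seed + 1000 * k + r}.
#' @param max_iter,conv_check Passed to [fit_nmf()].
#' @return Object of class \code{"rank_selection"}: list with \code{k_star},
#'   \code{cophenetic} (named vector over ranks), and \code{results}, a list
#'   of per-rank \code{"consensus_result"} objects (fields \code{k},
#'   \code{consensus}, \code{cophenetic}, \code{labels}, \code{n_runs},
#'   \code{dendrogram}).
#' @export
select_rank <- function(A, k_min = 2L, k_max = 4L, n_runs = 30L,
                        base_seed = 1L, max_iter = 1000L,
                        conv_check = list(interval = 10L, stop = 40L)) {
  if (k_min < 2 || k_max < k_min) stop("invalid rank range; need 2 <= k_min <= k_max")
  if (k_max > min(dim(A))) stop("k_max exceeds matrix dimensions")
  ranks <- seq.int(k_min, k_max)
  results <- lapply(ranks, function(k) {
    seeds <- base_seed + 1000L * k + seq_len(n_runs)
    .consensus_for_rank(A, k, n_runs, seeds, max_iter, conv_check)
  })
  names(results) <- paste0("k", ranks)
  coph <- vapply(results, `[[`, numeric(1), "cophenetic")
  k_star <- ranks[which.max(coph)]  # which.max takes the first (smallest k) on ties
  structure(list(k_star = as.integer(k_star), cophenetic = coph,
                 results = results),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("Consensus NMF rank selection\n")
  cat("  cophenetic:",
      paste(sprintf("%s=%.4f", names(x$cophenetic), x$cophenetic),
            collapse = ", "), "\n")
  cat(sprintf("  selected rank: %d\n", x$k_star))
  invisible(x)
}
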