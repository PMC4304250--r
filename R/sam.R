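# One-vs-rest SAM-style differential expression with permutation q-values.

# Pooled-standard-error d statistics for one or many case/rest splits.
# X: genes x samples (log2); M: samples x B 0/1 case indicator matrix.
# Returns list(d = genes x B, s = genes x B pooled SE).
.sam_d <- function(X, M, s0 = 0) {
  m <- ncol(X)
  n1 <- colSums(M)
  n2 <- m - n1
  S1 <- X %*% M
  Stot <- rowSums(X)
  S2 <- Stot - S1
  X2 <- X * X
  Q1 <- X2 %*% M
  Qtot <- rowSums(X2)
  SS <- sweep(-(S1^2), 2, n1, "/") + Qtot -
    sweep(S2^2, 2, n2, "/")
  num <- sweep(S1, 2, n1, "/") - sweep(S2, 2, n2, "/")
  s <- sqrt(sweep(pmax(SS, 0), 2, (1 / n1 + 1 / n2) / (n1 + n2 - 2), "*"))
  list(d = num / (s + s0), s = s)
}

#' SAM-style moderated difference statistic, one group versus the rest
#'
#' Per gene, d = (mean_case - mean_rest) / (s + s0), where s is the pooled
#' standard error of the mean difference and s0 a fudge factor that
#' stabilizes low-variance genes (default: the median of the per-gene s).
#'
#' @param X Numeric matrix, genes x samples, log2 scale.
#' @param case_mask Logical vector over samples marking the case group;
#'   both sides need at least 2 samples.
#' @param s0 Fudge factor; \code{NULL} (default) uses \code{median(s)}.
#' @return Named numeric vector of d statistics, with the resolved
#'   \code{s0} attached as attribute \code{"s0"}.
#' @export
sam_statistic <- function(X, case_mask, s0 = NULL) {
  X <- as.matrix(X)
  case_mask <- as.logical(case_mask)
  if (length(case_mask) != ncol(X)) stop("case_mask must match sample count")
  if (sum(case_mask) < 2 || sum(!case_mask) < 2) {
    stop("need at least 2 samples on each side")
  }
  n1 <- sum(case_mask); n2 <- sum(!case_mask)
  mu1 <- rowMeans(X[, case_mask, drop = FALSE])
  mu2 <- rowMeans(X[, !case_mask, drop = FALSE])
  ss <- rowSums((X[, case_mask, drop = FALSE] - mu1)^2) +
    rowSums((X[, !case_mask, drop = FALSE] - mu2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  d <- (mu1 - mu2) / (s + s0)
  names(d) <- rownames(X)
  attr(d, "s0") <- s0
  d
}

# draw or enumerate case-mask permutations; returns samples x B 0/1 matrix
.perm_masks <- function(m, n1, n_perm, seed) {
  n_distinct <- choose(m, n1)
  if (n_distinct < n_perm) {
    message(sprintf("only %d distinct case assignments; using full enumeration",
                    n_distinct))
    combos <- utils::combn(m, n1)
    M <- matrix(0, m, ncol(combos))
    M[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1
    return(M)
  }
  set.seed(seed)
  M <- matrix(0, m, n_perm)
  for (b in seq_len(n_perm)) M[sample(m, n1), b] <- 1
  M
}

#' Permutation FDR (q-values) for SAM statistics
#'
#' Permutes the case/rest assignment \code{n_perm} times and recomputes d
#' each time (with the s0 resolved on the observed data). For each gene,
#' the estimated FDR at threshold |d_i| is the median, over permutations,
#' of the number of permuted |d| at or above |d_i|, divided by the number
#' of observed |d| at or above |d_i|; q is then monotonized so that a
#' larger |d| never has a larger q. A gene reaches q = 0 when, in at least
#' half the permutations, no permuted statistic matches its |d|.
#'
#' When fewer than \code{n_perm} distinct assignments exist, all of them
#' are enumerated instead.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return Named numeric vector of q-values in \code{[0, 1]}.
#' @export
sam_qvalues <- function(X, case_mask, n_perm = 1000L, seed = 1L, s0 = NULL) {
  X <- as.matrix(X)
  case_mask <- as.logical(case_mask)
  if (n_perm < 100) stop("n_perm must be at least 100")
  d_obs <- sam_statistic(X, case_mask, s0 = s0)
  s0 <- attr(d_obs, "s0")
  m <- ncol(X)
  M <- .perm_masks(m, sum(case_mask), n_perm, seed)
  D <- .sam_d(X, M, s0 = s0)$d

  a_obs <- abs(d_obs)
  sorted_obs <- sort(a_obs)
  n_genes <- nrow(X)
  calls <- n_genes - findInterval(a_obs, sorted_obs, left.open = TRUE)
  false_counts <- matrix(0L, n_genes, ncol(M))
  for (b in seq_len(ncol(M))) {
    v <- sort(abs(D[, b]))
    false_counts[, b] <- n_genes - findInterval(a_obs, v, left.open = TRUE)
  }
  med_false <- apply(false_counts, 1, stats::median)
  q <- pmin(1, med_false / calls)
  ord <- order(-a_obs)
  q[ord] <- cummax(q[ord])
  names(q) <- rownames(X)
  q
}

#' One-vs-rest SAM marker table for a subtype
#'
#' Convenience wrapper combining [sam_statistic()], [sam_qvalues()] and the
#' linear-scale fold change (ratio of within-group means of \code{2^x}) into
#' one table per gene.
#'
#' @param expression Log2-scale matrix, genes x samples.
#' @param labels Subtype label per sample.
#' @param subtype The case subtype (compared against all others pooled).
#' @inheritParams sam_qvalues
#' @return Data frame with columns \code{gene_id}, \code{d_stat},
#'   \code{fold_change}, \code{q_value}, \code{subtype}.
#' @export
sam_de <- function(expression, labels, subtype, n_perm = 1000L, seed = 1L,
                   s0 = NULL) {
  mask <- labels == subtype
  if (!any(mask)) stop("subtype not present in labels")
  d <- sam_statistic(expression, mask, s0 = s0)
  q <- sam_qvalues(expression, mask, n_perm = n_perm, seed = seed,
                   s0 = attr(d, "s0"))
  lin <- 2^expression
  fc <- rowMeans(lin[, mask, drop = FALSE]) /
    rowMeans(lin[, !mask, drop = FALSE])
  data.frame(gene_id = rownames(expression), d_stat = unname(d),
             fold_change = unname(fc), q_value = unname(q),
             subtype = subtype, stringsAsFactors = FALSE)
}

#' Select top up-regulated markers at zero estimated FDR
#'
#' Applies the marker rule: keep genes with q-value exactly 0 and linear
#' fold change above 1 (up-regulated in the case subtype), order by fold
#' change descending, and keep the top \code{top_n}. When fewer genes
#' qualify, all of them are returned with a message.
#'
#' @param marker_table Output of [sam_de()].
#' @param top_n Number of markers to keep (default 20).
#' @return The filtered, ordered subset of \code{marker_table}.
#' @export
select_markers <- function(marker_table, top_n = 20L) {
  stopifnot(all(c("gene_id", "fold_change", "q_value") %in%
                  names(marker_table)))
  keep <- marker_table[marker_table$q_value == 0 &
                         marker_table$fold_change > 1, , drop = FALSE]
  keep <- keep[order(-keep$fold_change), , drop = FALSE]
  if (nrow(keep) < top_n) {
    message(sprintf("only %d genes qualify (q = 0, fold change > 1)",
                    nrow(keep)))
  }
  utils::head(keep, top_n)
}
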