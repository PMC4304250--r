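# Gene set enrichment: weighted running-sum ES, phenotype permutations,
# per-set sign-matched NES normalization, permutation FDR.

# signal-to-noise scores for one or many label assignments.
# X: genes x samples; M: samples x B indicator of class A membership.
.s2n <- function(X, M, sd_floor) {
  m <- ncol(X)
  n1 <- colSums(M)
  n2 <- m - n1
  S1 <- X %*% M
  S2 <- rowSums(X) - S1
  X2 <- X * X
  Q1 <- X2 %*% M
  Q2 <- rowSums(X2) - Q1
  mu1 <- sweep(S1, 2, n1, "/")
  mu2 <- sweep(S2, 2, n2, "/")
  v1 <- sweep(Q1 - sweep(mu1^2, 2, n1, "*"), 2, pmax(n1 - 1, 1), "/")
  v2 <- sweep(Q2 - sweep(mu2^2, 2, n2, "*"), 2, pmax(n2 - 1, 1), "/")
  sd1 <- pmax(sqrt(pmax(v1, 0)), sd_floor)
  sd2 <- pmax(sqrt(pmax(v2, 0)), sd_floor)
  (mu1 - mu2) / (sd1 + sd2)
}

#' Rank genes by signal-to-noise between two phenotype classes
#'
#' Per gene, (mean_A - mean_B) / (sd_A + sd_B), with each class sd floored
#' at \code{sd_floor} so near-constant genes cannot dominate. Genes are
#' returned sorted by score, largest (A-enriched) first. Class A is the
#' first level of \code{factor(labels)}.
#'
#' @param X Numeric matrix, genes x samples.
#' @param labels Two-class phenotype vector; each class needs >= 3 samples.
#' @param sd_floor Absolute floor on each class standard deviation
#'   (default 0.2).
#' @return Data frame with \code{gene_id} and \code{score}, sorted
#'   descending.
#' @export
rank_genes <- function(X, labels, sd_floor = 0.2) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two phenotype classes required")
  if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  M <- matrix(as.numeric(labels == levels(labels)[1]), ncol = 1)
  score <- .s2n(X, M, sd_floor)[, 1]
  ord <- order(-score)
  data.frame(gene_id = rownames(X)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked gene list accumulating a running sum: genes in the
#' set ("hits") add their |score|^p weight normalized by the total hit
#' weight; genes outside subtract 1 / (N - Nh). The enrichment score is the
#' running sum's signed extremum, always in \code{[-1, 1]}. A set
#' containing every ranked gene carries no enrichment information and is
#' defined to have ES = 0 with an all-zero running sum.
#'
#' @param ranked Data frame from [rank_genes()] (columns \code{gene_id},
#'   \code{score}, sorted), or a named score vector in ranked order.
#' @param gene_set Character vector of member gene ids.
#' @param weight_p Weighting exponent p (default 1, classic weighted ES).
#' @return List with \code{ES} and \code{running_sum}.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  if (is.data.frame(ranked)) {
    ids <- ranked$gene_id; scores <- ranked$score
  } else {
    ids <- names(ranked); scores <- unname(ranked)
  }
  hit <- ids %in% gene_set
  N <- length(ids); Nh <- sum(hit)
  if (Nh == 0) stop("gene set does not intersect the ranked list")
  if (Nh == N) {
    return(list(ES = 0, running_sum = numeric(N)))
  }
  w <- abs(scores)^weight_p
  wh <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (wh > 0) w[hit] / wh else 1 / Nh
  inc[!hit] <- -1 / (N - Nh)
  rs <- cumsum(inc)
  list(ES = rs[which.max(abs(rs))], running_sum = rs)
}

# ES for every set (columns of the hit matrix) against one ranked list.
.es_cols <- function(scores_ord, hits_ord, weight_p) {
  N <- length(scores_ord)
  w <- abs(scores_ord)^weight_p
  vapply(seq_len(ncol(hits_ord)), function(j) {
    h <- hits_ord[, j]
    Nh <- sum(h)
    if (Nh == N) return(0)
    wh <- sum(w[h])
    inc <- numeric(N)
    inc[h] <- if (wh > 0) w[h] / wh else 1 / Nh
    inc[!h] <- -1 / (N - Nh)
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }, numeric(1))
}

#' Gene set enrichment analysis with phenotype permutations
#'
#' Ranks genes by signal-to-noise between the two phenotype classes,
#' computes each set's weighted running-sum enrichment score, then permutes
#' the phenotype labels \code{n_perm} times, re-ranking and re-scoring each
#' time. Scores are normalized per set against the mean |permuted ES| of
#' the same sign (NES), and the FDR q of each set comes from the pooled
#' permuted NES distribution, in the standard two-sided-by-sign fashion.
#'
#' @param X Numeric matrix, genes x samples (log2 scale is fine; ranking is
#'   scale-dependent only through signal-to-noise).
#' @param labels Two-class phenotype vector (>= 3 samples per class).
#' @param collection Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Phenotype permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param weight_p ES weighting exponent (default 1).
#' @param set_min,set_max Size filter applied after intersecting each set
#'   with the rows of \code{X} (defaults 15 and 500).
#' @param sd_floor Passed to [rank_genes()].
#' @return Data frame of class \code{"enrichment_table"}: \code{set_name},
#'   \code{ES}, \code{NES}, \code{fdr_q}, \code{direction} (the phenotype
#'   class the set is enriched in), sorted by |NES| descending.
#' @export
gsea_significance <- function(X, labels, collection, n_perm = 1000L,
                              seed = 1L, weight_p = 1, set_min = 15L,
                              set_max = 500L, sd_floor = 0.2) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two phenotype classes required")
  if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
  if (n_perm < 100) stop("n_perm must be at least 100")

  universe <- rownames(X)
  kept <- lapply(collection, function(g) intersect(g, universe))
  sizes <- lengths(kept)
  kept <- kept[sizes >= set_min & sizes <= set_max]
  if (length(kept) == 0) {
    message("no gene set overlaps the expression matrix within the size filter")
    out <- data.frame(set_name = character(0), ES = numeric(0),
                      NES = numeric(0), fdr_q = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }

  class_a <- levels(labels)[1]
  class_b <- levels(labels)[2]
  is_a <- labels == class_a
  m <- ncol(X)

  hit_mat <- vapply(kept, function(g) universe %in% g,
                    logical(length(universe)))

  obs_scores <- .s2n(X, matrix(as.numeric(is_a), ncol = 1), sd_floor)[, 1]
  ord <- order(-obs_scores)
  es_obs <- .es_cols(obs_scores[ord], hit_mat[ord, , drop = FALSE], weight_p)

  set.seed(seed)
  n_a <- sum(is_a)
  Mall <- matrix(0, m, n_perm)
  for (b in seq_len(n_perm)) Mall[sample(m, n_a), b] <- 1
  SC <- .s2n(X, Mall, sd_floor)
  es_perm <- matrix(0, length(kept), n_perm)
  for (b in seq_len(n_perm)) {
    ob <- order(-SC[, b])
    es_perm[, b] <- .es_cols(SC[ob, b], hit_mat[ob, , drop = FALSE], weight_p)
  }

  # per-set sign-matched normalization
  norm_one <- function(es, ref) {
    pos <- mean(ref[ref > 0]); neg <- mean(abs(ref[ref < 0]))
    if (es >= 0) es / ifelse(is.finite(pos) && pos > 0, pos, 1)
    else es / ifelse(is.finite(neg) && neg > 0, neg, 1)
  }
  nes_obs <- vapply(seq_along(kept), function(i) {
    norm_one(es_obs[i], es_perm[i, ])
  }, numeric(1))
  nes_perm <- es_perm
  for (i in seq_along(kept)) {
    ref <- es_perm[i, ]
    pos <- mean(ref[ref > 0]); neg <- mean(abs(ref[ref < 0]))
    pn <- ifelse(is.finite(pos) && pos > 0, pos, 1)
    nn <- ifelse(is.finite(neg) && neg > 0, neg, 1)
    nes_perm[i, ] <- ifelse(ref >= 0, ref / pn, ref / nn)
  }

  pool <- as.vector(nes_perm)
  pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
  obs_pos <- nes_obs[nes_obs >= 0]; obs_neg <- nes_obs[nes_obs < 0]
  fdr_q <- vapply(nes_obs, function(nes) {
    if (nes >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes) else 0
      den <- mean(obs_pos >= nes)
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes) else 0
      den <- mean(obs_neg <= nes)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  out <- data.frame(set_name = names(kept), ES = es_obs, NES = nes_obs,
                    fdr_q = fdr_q,
                    direction = ifelse(nes_obs >= 0, class_a, class_b),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$NES)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
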