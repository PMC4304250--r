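#' Exponential scaling of a log2 expression matrix
#'
#' Transforms a log2-scale expression matrix elementwise by \code{2^x},
#' producing the strictly non-negative input that non-negative matrix
#' factorization requires. Negative log2 values map to fractions in (0, 1),
#' so non-negativity is guaranteed for any finite input.
#'
#' @param log2_matrix Numeric matrix on log2 scale (genes in rows, samples in
#'   columns). All entries must be finite.
#' @return A numeric matrix of the same dimensions and dimnames with entries
#'   \code{2^x}.
#' @examples
#' exponential_scale(matrix(c(0, 3, -1, 2), 2, 2))
#' @export
exponential_scale <- function(log2_matrix) {
  log2_matrix <- as.matrix(log2_matrix)
  if (!is.numeric(log2_matrix)) {
    stop("expression matrix must be numeric")
  }
  if (any(!is.finite(log2_matrix))) {
    stop("expression matrix contains non-finite entries; cannot scale")
  }
  2^log2_matrix
}

#' Kullback-Leibler divergence between a matrix and its factorization
#'
#' Computes D(A || WH) = sum_ij [ A_ij log(A_ij / (WH)_ij) - A_ij + (WH)_ij ]
#' with the convention 0 * log 0 = 0. This is the cost function minimized by
#' the multiplicative-update NMF in [fit_nmf()].
#'
#' @param A Non-negative matrix (n x m).
#' @param W Non-negative basis matrix (n x k).
#' @param H Non-negative coefficient matrix (k x m).
#' @return Non-negative scalar divergence; \code{Inf} when \code{(WH)_ij = 0}
#'   at a position where \code{A_ij > 0}.
#' @export
kl_divergence <- function(A, W, H) {
  A <- as.matrix(A); W <- as.matrix(W); H <- as.matrix(H)
  if (ncol(W) != nrow(H) || nrow(W) != nrow(A) || ncol(H) != ncol(A)) {
    stop("non-conforming shapes: A must be nrow(W) x ncol(H)")
  }
  if (min(A) < 0 || min(W) < 0 || min(H) < 0) {
    stop("all inputs must be non-negative")
  }
  .kl_div(A, W %*% H)
}

# divergence against a precomputed reconstruction; 0*log0 := 0
.kl_div <- function(A, WH) {
  pos <- A > 0
  sum(A[pos] * log(A[pos] / WH[pos])) - sum(A) + sum(WH)
}

#' One multiplicative-update sweep for KL-divergence NMF
#'
#' Applies the W update then, using the updated W, the H update:
#' \deqn{W_{ia} \leftarrow W_{ia} \frac{\sum_u H_{au} A_{iu}/(WH)_{iu}}{\sum_v H_{av}}}
#' \deqn{H_{au} \leftarrow H_{au} \frac{\sum_i W_{ia} A_{iu}/(WH)_{iu}}{\sum_k W_{ka}}}
#' Non-negativity is preserved and the divergence never increases.
#' Denominators are floored at \code{eps} so degenerate zero row/column sums
#' cannot produce 0/0.
#'
#' This pure-R sweep mirrors exactly the compiled loop used by [fit_nmf()];
#' it exists for inspection and for step-level verification at small sizes.
#'
#' @param A Non-negative target matrix.
#' @param W,H Current non-negative factors.
#' @param eps Denominator floor (default 1e-12).
#' @return List with updated \code{W} and \code{H}.
#' @export
nmf_update_step <- function(A, W, H, eps = 1e-12) {
  WH <- W %*% H
  R <- A / (WH + eps)
  W <- W * (R %*% t(H)) / (rep(1, nrow(W)) %o% rowSums(H) + eps)
  WH <- W %*% H
  R <- A / (WH + eps)
  H <- H * (t(W) %*% R) / (colSums(W) %o% rep(1, ncol(H)) + eps)
  list(W = W, H = H)
}

#' Fit a KL-divergence NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix \code{A} (genes x samples) as
#' \code{A ~ W \%*\% H} with \code{W} (n x k) and \code{H} (k x m)
#' non-negative, minimizing the KL divergence of [kl_divergence()] by the
#' multiplicative updates of [nmf_update_step()]. Both factors are
#' initialized from seeded uniform(0, 1] draws scaled to the magnitude of
#' \code{A}, so a given seed always reproduces the identical factorization.
#'
#' Iteration stops either at \code{max_iter} (default 1000) or when the
#' sample connectivity pattern -- the argmax metagene of each column of
#' \code{H} -- has remained unchanged over \code{conv_check$stop}
#' consecutive checks taken every \code{conv_check$interval} sweeps, the
#' standard consensus-clustering stopping rule. Pass \code{conv_check =
#' NULL} to always run the full \code{max_iter} sweeps.
#'
#' @param A Non-negative numeric matrix, genes in rows, samples in columns.
#' @param k Factorization rank, \code{1 <= k <= min(dim(A))}.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update sweeps (default 1000).
#' @param conv_check List with \code{interval} and \code{stop} controlling
#'   the connectivity-stability stopping rule, or \code{NULL} to disable.
#' @param eps Denominator/log floor (default 1e-12).
#' @return An object of class \code{"nmf_fit"}: list with \code{W}, \code{H},
#'   \code{k}, \code{divergence}, \code{n_iter}, \code{seed},
#'   \code{converged}.
#' @examples
#' A <- exponential_scale(matrix(rnorm(80, 8), 10, 8))
#' fit <- fit_nmf(A, k = 2, seed = 1)
#' fit$divergence
#' @export
fit_nmf <- function(A, k, seed = 1L, max_iter = 1000L,
                    conv_check = list(interval = 10L, stop = 40L),
                    eps = 1e-12) {
  A <- as.matrix(A)
  if (any(!is.finite(A)) || min(A) < 0) {
    stop("A must be finite and non-negative (apply exponential_scale first)")
  }
  if (k < 1 || k > min(dim(A))) {
    stop("rank k must satisfy 1 <= k <= min(n, m)")
  }
  if (is.null(conv_check)) {
    interval <- 0L; stop_conv <- 0L
  } else {
    interval <- as.integer(conv_check$interval)
    stop_conv <- as.integer(conv_check$stop)
  }

  set.seed(seed)
  scale0 <- sqrt(mean(A) / k)
  W0 <- matrix(scale0 * (1 - stats::runif(nrow(A) * k)), nrow(A), k)
  H0 <- matrix(scale0 * (1 - stats::runif(k * ncol(A))), k, ncol(A))

  res <- nmf_kl_engine(A, W0, H0, as.integer(max_iter), interval, stop_conv,
                       eps)
  rownames(res$W) <- rownames(A)
  colnames(res$H) <- colnames(A)
  structure(
    list(W = res$W, H = res$H, k = as.integer(k),
         divergence = res$divergence, n_iter = res$n_iter,
         seed = as.integer(seed), converged = res$converged),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("KL-NMF fit: rank %d, %d x %d, divergence %.6g after %d sweeps (%s)\n",
              x$k, nrow(x$W), ncol(x$H), x$divergence, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
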