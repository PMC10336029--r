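#' @name losses
#' @title Loss components of the alignment objective
#'
#' @description The objective minimized over the two linear maps is
#' \deqn{MMD(XW_x, YW_y)^2 + \lambda_1(pen(W_x) + pen(W_y)) +
#'       \lambda_2(dis(X, W_x) + dis(Y, W_y))}
#' where \eqn{pen(W) = \|W^\top W - I_d\|_F^2} keeps each map from collapsing
#' the embedding, and \eqn{dis(X, W) = \|XX^\top - XWW^\top X^\top\|_F^2}
#' keeps the embedding's induced similarity close to the input similarity.
#' In the dual, maps are parameterized by sample-space coefficients
#' \eqn{\alpha} with \eqn{W = X^\top\alpha}; substituting gives
#' \eqn{pen = \|\alpha^\top K\alpha - I\|_F^2} and
#' \eqn{dis = \|K - K\alpha\alpha^\top K\|_F^2} with \eqn{K = XX^\top}.
NULL

# --- Gaussian-kernel pair sums ------------------------------------------------
#
# .kernel_sums computes S = sum_{i,j} k(a_i, b_j) with
# k(a,b) = exp(-||a - b||^2 / (2 sigma^2)), and optionally
# dA = dS/dA, dB = dS/dB using dk/da = -((a - b)/sigma^2) k(a,b).
#
# The streaming path visits (row-block of A) x (row-block of B) tiles, so the
# largest allocation is block^2, never n1*n2. Value and gradient are
# accumulated in one pass over tiles.

.kernel_tile <- function(A, B, inv2s2) {
  # squared distances via the expansion ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 * inv2s2)
}

.kernel_sums <- function(A, B, sigma, streaming = FALSE, block_size = 4096L,
                         grad = FALSE) {
  if (sigma <= 0) stop("config error: sigma must be > 0")
  if (ncol(A) != ncol(B)) stop("shape error: embeddings must share the latent dimension")
  inv2s2 <- 1 / (2 * sigma^2)
  invs2 <- 1 / sigma^2
  n1 <- nrow(A); n2 <- nrow(B)
  if (!streaming) {
    K <- .kernel_tile(A, B, inv2s2)
    out <- list(sum = sum(K))
    if (grad) {
      # dS/da_i = -(1/s^2) sum_j (a_i - b_j) k_ij
      out$dA <- -invs2 * (A * rowSums(K) - K %*% B)
      out$dB <- -invs2 * (B * colSums(K) - crossprod(K, A))
    }
    return(out)
  }
  .kernel_sums_cpp(A, B, sigma, block_size, grad)
}

#' Squared maximum mean discrepancy between two embedded samples
#'
#' Computes the squared MMD between the empirical distributions of the rows
#' of \code{U} and \code{V} under the Gaussian kernel
#' \eqn{k(a,b) = \exp(-\|a-b\|^2 / (2\sigma^2))}. The default is the biased
#' V-statistic (self-pairs included), which is nonnegative by construction:
#' \deqn{\frac{1}{n_1^2}\sum_{ij} k(u_i,u_j) + \frac{1}{n_2^2}\sum_{ij} k(v_i,v_j)
#'       - \frac{2}{n_1 n_2}\sum_{ij} k(u_i,v_j).}
#'
#' With \code{streaming = TRUE} the kernel sums are accumulated over row
#' blocks of at most \code{block_size} rows per side, so memory stays
#' O(block_size^2 + n) and no n1-by-n2 array is ever allocated; the streaming
#' and naive paths are numerically identical (same summands, tile order only).
#'
#' @param U,V numeric matrices, n1 x d and n2 x d.
#' @param sigma kernel bandwidth, > 0.
#' @param streaming use the blockwise linear-memory path.
#' @param block_size rows per block when streaming.
#' @param biased if \code{FALSE}, return the unbiased U-statistic (within-set
#'   self-pairs excluded); it can be negative.
#' @return A single number, >= 0 for the biased estimator (up to float error).
#' @examples
#' U <- matrix(rnorm(20), 10, 2)
#' mmd2(U, U)                    # 0
#' mmd2(U, U + 1)                # > 0
#' @export
mmd2 <- function(U, V, sigma = 1, streaming = FALSE, block_size = 4096L,
                 biased = TRUE) {
  U <- as_modality_values(U); V <- as_modality_values(V)
  n1 <- nrow(U); n2 <- nrow(V)
  suu <- .kernel_sums(U, U, sigma, streaming, block_size)$sum
  svv <- .kernel_sums(V, V, sigma, streaming, block_size)$sum
  suv <- .kernel_sums(U, V, sigma, streaming, block_size)$sum
  if (biased) {
    suu / n1^2 + svv / n2^2 - 2 * suv / (n1 * n2)
  } else {
    if (n1 < 2L || n2 < 2L) stop("unbiased estimator needs at least two rows per sample")
    # k(u_i, u_i) = 1, so the diagonal sums are n1 and n2
    (suu - n1) / (n1 * (n1 - 1)) + (svv - n2) / (n2 * (n2 - 1)) -
      2 * suv / (n1 * n2)
  }
}

# value and gradient in a single pass over kernel tiles
.mmd2_with_grad <- function(U, V, sigma, streaming, block_size) {
  n1 <- nrow(U); n2 <- nrow(V)
  guu <- .kernel_sums(U, U, sigma, streaming, block_size, grad = TRUE)
  gvv <- .kernel_sums(V, V, sigma, streaming, block_size, grad = TRUE)
  guv <- .kernel_sums(U, V, sigma, streaming, block_size, grad = TRUE)
  list(value = guu$sum / n1^2 + gvv$sum / n2^2 - 2 * guv$sum / (n1 * n2),
       dU = (guu$dA + guu$dB) / n1^2 - 2 * guv$dA / (n1 * n2),
       dV = (gvv$dA + gvv$dB) / n2^2 - 2 * guv$dB / (n1 * n2))
}

#' Gradient of the squared MMD
#'
#' Analytic gradients of [mmd2()] (biased estimator) with respect to both
#' embeddings, honoring the same blockwise memory contract as the value.
#'
#' @inheritParams mmd2
#' @return list with elements \code{dU} (n1 x d) and \code{dV} (n2 x d).
#' @export
mmd2_grad <- function(U, V, sigma = 1, streaming = FALSE, block_size = 4096L) {
  U <- as_modality_values(U); V <- as_modality_values(V)
  n1 <- nrow(U); n2 <- nrow(V)
  guu <- .kernel_sums(U, U, sigma, streaming, block_size, grad = TRUE)
  gvv <- .kernel_sums(V, V, sigma, streaming, block_size, grad = TRUE)
  guv <- .kernel_sums(U, V, sigma, streaming, block_size, grad = TRUE)
  list(dU = (guu$dA + guu$dB) / n1^2 - 2 * guv$dA / (n1 * n2),
       dV = (gvv$dA + gvv$dB) / n2^2 - 2 * guv$dB / (n1 * n2))
}

#' Linear-time MMD estimator
#'
#' Unbiased streaming estimator that pairs consecutive rows: with
#' \eqn{h((u,v),(u',v')) = k(u,u') + k(v,v') - k(u,v') - k(u',v)}, returns the
#' average of \eqn{h} over the \eqn{\lfloor n/2 \rfloor} disjoint consecutive
#' pairs. Unbiased for the squared population MMD when rows are in random
#' order; the caller is responsible for shuffling.
#'
#' @param U,V numeric matrices with the same number of rows.
#' @param sigma kernel bandwidth.
#' @return A single number (can be negative).
#' @export
mmd_linear_time <- function(U, V, sigma = 1) {
  U <- as_modality_values(U); V <- as_modality_values(V)
  if (nrow(U) != nrow(V)) stop("shape error: linear-time estimator needs equal sample sizes")
  n <- nrow(U)
  if (n %% 2L == 1L) {
    warning("odd number of rows; last row dropped")
    U <- U[-n, , drop = FALSE]; V <- V[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 2L) stop("value error: need at least one pair of rows")
  odd <- seq(1L, n, by = 2L); even <- odd + 1L
  k <- function(A, B) exp(-rowSums((A - B)^2) / (2 * sigma^2))
  h <- k(U[odd, , drop = FALSE], U[even, , drop = FALSE]) +
    k(V[odd, , drop = FALSE], V[even, , drop = FALSE]) -
    k(U[odd, , drop = FALSE], V[even, , drop = FALSE]) -
    k(U[even, , drop = FALSE], V[odd, , drop = FALSE])
  mean(h)
}

# --- penalties and distortion -------------------------------------------------

#' Non-collapsing penalty (primal)
#'
#' \eqn{\|W^\top W - I_d\|_F^2}: zero iff the map has orthonormal columns,
#' so minimizing it prevents the embedding from collapsing to a point or a
#' lower-rank subspace.
#'
#' @param W p x d map.
#' @return scalar >= 0.
#' @export
penalty_primal <- function(W) {
  M <- crossprod(W)
  diag(M) <- diag(M) - 1
  sum(M * M)
}

#' Precompute Gram features of one modality
#'
#' Caches \eqn{C = X^\top X} (p x p) and \eqn{tr(C^2)}, the pieces needed to
#' evaluate the distortion penalty without ever forming the n x n similarity
#' matrix \eqn{XX^\top}.
#'
#' @param x modality matrix or numeric matrix.
#' @return list of class \code{"gram_features"} with \code{C} and \code{tr_C2}.
#' @export
gram_features <- function(x) {
  X <- as_modality_values(x)
  C <- crossprod(X)
  C <- (C + t(C)) / 2
  structure(list(C = C, tr_C2 = sum(C * C)), class = "gram_features")
}

#' Distortion penalty (primal)
#'
#' \eqn{dis(X, W) = \|XX^\top - XWW^\top X^\top\|_F^2}, the discrepancy
#' between the input similarity and the similarity induced by the embedding.
#' The efficient path expands the Frobenius norm into traces of p x p and
#' d x d matrices,
#' \eqn{tr(C^2) - 2\,tr(W^\top C^2 W) + tr((W^\top C W)^2)} with
#' \eqn{C = X^\top X}, avoiding any n x n intermediate; the naive path forms
#' both n x n similarities explicitly.
#'
#' @param x modality matrix, numeric matrix, or a [gram_features()] object
#'   (the naive method needs the full matrix).
#' @param W p x d map.
#' @param method \code{"efficient"} (default) or \code{"naive"}.
#' @return scalar >= 0.
#' @export
distortion_primal <- function(x, W, method = c("efficient", "naive")) {
  method <- match.arg(method)
  if (method == "naive") {
    if (inherits(x, "gram_features")) {
      stop("naive distortion needs the data matrix, not gram_features")
    }
    X <- as_modality_values(x)
    if (ncol(X) != nrow(W)) stop("shape error: ncol(X) != nrow(W)")
    E <- tcrossprod(X) - tcrossprod(X %*% W)
    return(sum(E * E))
  }
  gf <- if (inherits(x, "gram_features")) x else gram_features(x)
  if (ncol(gf$C) != nrow(W)) stop("shape error: feature dimension mismatch")
  CW <- gf$C %*% W
  M <- crossprod(W, CW)              # d x d, symmetric
  gf$tr_C2 - 2 * sum(CW * CW) + sum(M * M)
}

# check symmetry of a kernel matrix used by the dual forms
.check_sym <- function(K, tol = 1e-8) {
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > tol * max(1, max(abs(K)))) {
    stop("value error: K must be symmetric")
  }
}

#' Non-collapsing penalty (dual)
#'
#' \eqn{\|\alpha^\top K \alpha - I_d\|_F^2} with \eqn{K = XX^\top}. Equals
#' [penalty_primal()] of \eqn{W = X^\top \alpha} exactly.
#'
#' @param K n x n symmetric PSD kernel matrix.
#' @param alpha n x d dual coefficients.
#' @return scalar >= 0.
#' @export
penalty_dual <- function(K, alpha) {
  .check_sym(K)
  M <- crossprod(alpha, K %*% alpha)
  diag(M) <- diag(M) - 1
  sum(M * M)
}

#' Distortion penalty (dual)
#'
#' \eqn{\|K - K\alpha\alpha^\top K\|_F^2}; equals [distortion_primal()] of
#' \eqn{W = X^\top\alpha}. Evaluated via \eqn{B = K\alpha} as
#' \eqn{\|K\|_F^2 - 2\,tr(B^\top K B) + \|B^\top B\|_F^2}.
#'
#' @inheritParams penalty_dual
#' @return scalar >= 0.
#' @export
distortion_dual <- function(K, alpha) {
  .check_sym(K)
  B <- K %*% alpha
  M <- crossprod(B)
  sum(K * K) - 2 * sum(B * (K %*% B)) + sum(M * M)
}

# --- full objective -----------------------------------------------------------

#' Evaluate the full alignment objective
#'
#' Computes the five loss components and the weighted total for one parameter
#' state, in either parameterization. In the primal the embeddings are
#' \eqn{XW_x} and \eqn{YW_y}; in the dual they are \eqn{K_x\alpha_x} and
#' \eqn{K_y\alpha_y} with \eqn{K = XX^\top}.
#'
#' @param x,y modality matrices (or numeric matrices).
#' @param params_x,params_y the map parameters: p x d (primal) or n x d (dual).
#' @param hp hyperparameters from [mmdma_hyperparams()]; \code{sigma} must be
#'   numeric here.
#' @return list of class \code{"loss_breakdown"} with \code{mmd2},
#'   \code{pen_x}, \code{pen_y}, \code{dis_x}, \code{dis_y} and \code{total}
#'   \eqn{= mmd2 + \lambda_1(pen_x + pen_y) + \lambda_2(dis_x + dis_y)}.
#' @export
mmdma_loss <- function(x, y, params_x, params_y, hp = mmdma_hyperparams()) {
  X <- as_modality_values(x); Y <- as_modality_values(y)
  if (!is.numeric(hp$sigma)) stop("config error: sigma must be numeric here")
  if (hp$mode == "primal") {
    U <- X %*% params_x; V <- Y %*% params_y
    pen_x <- penalty_primal(params_x); pen_y <- penalty_primal(params_y)
    dis_x <- distortion_primal(X, params_x); dis_y <- distortion_primal(Y, params_y)
  } else {
    Kx <- tcrossprod(X); Ky <- tcrossprod(Y)
    U <- Kx %*% params_x; V <- Ky %*% params_y
    pen_x <- penalty_dual(Kx, params_x); pen_y <- penalty_dual(Ky, params_y)
    dis_x <- distortion_dual(Kx, params_x); dis_y <- distortion_dual(Ky, params_y)
  }
  m2 <- mmd2(U, V, sigma = hp$sigma, streaming = hp$streaming,
             block_size = hp$block_size)
  new_loss_breakdown(m2, pen_x, pen_y, dis_x, dis_y, hp$lambda1, hp$lambda2)
}

new_loss_breakdown <- function(mmd2, pen_x, pen_y, dis_x, dis_y, lambda1, lambda2) {
  structure(list(mmd2 = mmd2, pen_x = pen_x, pen_y = pen_y,
                 dis_x = dis_x, dis_y = dis_y,
                 total = mmd2 + lambda1 * (pen_x + pen_y) +
                   lambda2 * (dis_x + dis_y)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("mmd2=%.6g pen=(%.6g, %.6g) dis=(%.6g, %.6g) total=%.6g\n",
              x$mmd2, x$pen_x, x$pen_y, x$dis_x, x$dis_y, x$total))
  invisible(x)
}
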