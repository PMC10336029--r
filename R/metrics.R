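#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Given two embeddings of the same cells (row i of \code{U} is the known
#' match of row i of \code{V}), computes, for each cell and in each
#' direction, the fraction of opposite-modality cells strictly closer (in
#' Euclidean distance) than its true match, out of the n - 1 candidates.
#' The mean over both directions is 0 for a perfect alignment and 0.5 in
#' expectation for random placement. Ties do not count as closer.
#'
#' Distances are accumulated blockwise so memory stays O(block_size * n)
#' rather than n^2 for large n.
#'
#' @param U,V n x d embeddings with matching rows.
#' @param block_size rows per block.
#' @return An object of class \code{"foscttm"}: list with \code{mean},
#'   \code{per_cell_x_to_y} and \code{per_cell_y_to_x} (each in [0, 1]).
#' @examples
#' U <- matrix(rnorm(40), 20, 2)
#' foscttm(U, U)$mean                         # 0: every true match at distance 0
#' @export
foscttm <- function(U, V, block_size = 4096L) {
  U <- as_modality_values(U); V <- as_modality_values(V)
  if (nrow(U) != nrow(V)) stop("shape error: FOSCTTM needs equal cell counts")
  if (ncol(U) != ncol(V)) stop("shape error: embeddings must share the latent dimension")
  n <- nrow(U)
  if (n < 2L) stop("value error: FOSCTTM needs at least two cells")
  d_true <- sqrt(rowSums((U - V)^2))
  count_closer <- function(A, B, dtrue) {
    # for each row a_i of A: #{j != i: ||a_i - b_j|| < dtrue_i}
    cnt <- integer(n)
    rb <- rowSums(B * B)
    blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
    for (bi in blocks) {
      Ab <- A[bi, , drop = FALSE]
      d2 <- outer(rowSums(Ab * Ab), rb, "+") - 2 * tcrossprod(Ab, B)
      d2[d2 < 0] <- 0
      cnt[bi] <- rowSums(sweep(d2, 1L, dtrue[bi]^2, "<"))
      # subtract the true match itself when it satisfies the strict inequality
      # (it never does: d2[i, i] == dtrue^2), but guard float asymmetry
      self <- d2[cbind(seq_along(bi), bi)] < dtrue[bi]^2
      cnt[bi] <- cnt[bi] - as.integer(self)
    }
    cnt / (n - 1)
  }
  x_to_y <- count_closer(U, V, d_true)
  y_to_x <- count_closer(V, U, d_true)
  structure(list(mean = (mean(x_to_y) + mean(y_to_x)) / 2,
                 per_cell_x_to_y = x_to_y, per_cell_y_to_x = y_to_x),
            class = "foscttm")
}

#' @export
print.foscttm <- function(x, ...) {
  cat(sprintf("FOSCTTM: %.4f (x->y %.4f, y->x %.4f; 0 perfect, 0.5 random)\n",
              x$mean, mean(x$per_cell_x_to_y), mean(x$per_cell_y_to_x)))
  invisible(x)
}
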