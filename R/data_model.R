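#' Construct a modality matrix
#'
#' A modality matrix is one single-cell measurement modality: a numeric
#' cell-by-feature matrix together with ordered, unique cell and feature
#' identifiers. Rows are cells and columns are features; use
#' \code{transpose = TRUE} when the source file stores features in rows.
#'
#' Sparse matrices (any \pkg{Matrix} class) are accepted and densified: the
#' solver works in the primal with small feature dimension, so dense storage
#' is the right internal representation. A warning is emitted when the dense
#' copy would exceed \code{max_dense_gb}.
#'
#' @param values numeric matrix (dense or a \pkg{Matrix} sparse matrix),
#'   cells in rows after any transposition.
#' @param cell_ids character vector of unique cell identifiers, length
#'   \code{nrow(values)}; generated (\code{"cell_0001"}, ...) when \code{NULL}.
#' @param feature_ids character vector of unique feature identifiers, length
#'   \code{ncol(values)}; generated when \code{NULL}.
#' @param transpose flip rows and columns before anything else.
#' @param max_dense_gb warn when densifying a sparse input above this size.
#' @return An object of class \code{"modality_matrix"}: a list with elements
#'   \code{values}, \code{cell_ids}, \code{feature_ids}.
#' @examples
#' m <- modality_matrix(matrix(rnorm(12), 4, 3))
#' dim(m$values)
#' @export
modality_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                            transpose = FALSE, max_dense_gb = 4) {
  if (inherits(values, "Matrix")) {
    est_gb <- prod(dim(values)) * 8 / 1024^3
    if (est_gb > max_dense_gb) {
      warning(sprintf("densifying sparse input (~%.1f GB dense)", est_gb))
    }
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  if (transpose) values <- t(values)
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 1L) stop("modality matrix must have at least one cell and one feature")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at cell %d, feature %d", bad[1L], bad[2L]))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- sprintf("feat_%04d", seq_len(p))
  }
  cell_ids <- as.character(cell_ids); feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != n) stop("cell_ids length does not match number of rows")
  if (length(feature_ids) != p) stop("feature_ids length does not match number of columns")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  dimnames(values) <- NULL
  structure(list(values = values, cell_ids = cell_ids, feature_ids = feature_ids),
            class = "modality_matrix")
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("modality matrix: %d cells x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

# Accept either a modality_matrix or a bare numeric matrix.
as_modality_values <- function(x) {
  if (inherits(x, "modality_matrix")) return(x$values)
  if (inherits(x, "Matrix")) return(as.matrix(x))
  if (is.matrix(x) && is.numeric(x)) {
    x <- unname(x); storage.mode(x) <- "double"; return(x)
  }
  stop("expected a modality_matrix or numeric matrix")
}

#' Assemble and validate hyperparameters
#'
#' Collects every tunable of the alignment into one validated record.
#'
#' @param d latent dimension of the shared space.
#' @param lambda1 weight of the non-collapsing penalties (>= 0).
#' @param lambda2 weight of the distortion penalties (>= 0).
#' @param sigma Gaussian kernel bandwidth (> 0), or \code{"median"} to use the
#'   median pairwise distance of the initial embeddings (computed once, on a
#'   subsample of at most 2000 cells).
#' @param n_iter number of full-batch iterations.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and any subsampling.
#' @param mode \code{"primal"} (feature-space maps W, p x d) or \code{"dual"}
#'   (sample-space coefficients alpha, n x d).
#' @param streaming evaluate the MMD term and gradient blockwise so that no
#'   array with n1*n2 entries is ever allocated.
#' @param block_size rows per block in streaming reductions.
#' @param eval_interval iterations between trace records.
#' @return A list of class \code{"mmdma_hyperparams"}.
#' @export
mmdma_hyperparams <- function(d = 10L, lambda1 = 0.1, lambda2 = 1e-6,
                              sigma = 1, n_iter = 500L, learning_rate = 0.05,
                              seed = 0L, mode = c("primal", "dual"),
                              streaming = TRUE, block_size = 4096L,
                              eval_interval = 10L) {
  mode <- match.arg(mode)
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("config error: d must be a positive integer")
  if (lambda1 < 0 || lambda2 < 0) stop("config error: lambda1 and lambda2 must be >= 0")
  sigma_median <- identical(sigma, "median")
  if (!sigma_median && (!is.numeric(sigma) || sigma <= 0)) {
    stop("config error: sigma must be > 0 or \"median\"")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 0L) stop("config error: n_iter must be >= 0")
  if (learning_rate <= 0) stop("config error: learning_rate must be > 0")
  block_size <- as.integer(block_size)
  eval_interval <- as.integer(eval_interval)
  if (block_size < 1L) stop("config error: block_size must be >= 1")
  if (eval_interval < 1L) stop("config error: eval_interval must be >= 1")
  structure(list(d = d, lambda1 = lambda1, lambda2 = lambda2, sigma = sigma,
                 n_iter = n_iter, learning_rate = learning_rate,
                 seed = as.integer(seed), mode = mode, streaming = isTRUE(streaming),
                 block_size = block_size, eval_interval = eval_interval),
            class = "mmdma_hyperparams")
}

#' Validate a pair of modalities against the hyperparameters
#'
#' Checks both matrices for finite entries and consistent shapes, decides
#' whether row-wise correspondence evaluation is possible (it requires equal
#' cell counts), and warns when the latent dimension exceeds a feature
#' dimension.
#'
#' @param x,y modality matrices (or numeric matrices).
#' @param hp hyperparameters from [mmdma_hyperparams()], or a latent dimension.
#' @return Invisibly, a list with the two (possibly wrapped) modalities and
#'   \code{correspondence_possible}.
#' @export
validate_pair <- function(x, y, hp = mmdma_hyperparams()) {
  if (is.numeric(hp) && length(hp) == 1L) hp <- mmdma_hyperparams(d = hp)
  if (!inherits(x, "modality_matrix")) x <- modality_matrix(as_modality_values(x))
  if (!inherits(y, "modality_matrix")) y <- modality_matrix(as_modality_values(y))
  if (hp$d > min(ncol(x$values), ncol(y$values))) {
    warning(sprintf("latent dimension d=%d exceeds min(px, py)=%d",
                    hp$d, min(ncol(x$values), ncol(y$values))))
  }
  invisible(list(x = x, y = y,
                 correspondence_possible = nrow(x$values) == nrow(y$values)))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
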