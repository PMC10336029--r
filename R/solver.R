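#' Initialize map parameters
#'
#' Draws i.i.d. Normal(0, 1/m) entries where m is the leading dimension
#' (p for primal maps, n for dual coefficients), so initial embeddings have
#' unit-order scale regardless of dimension. Deterministic given the seed;
#' the caller's RNG stream is left untouched.
#'
#' @param m leading dimension (features for primal, cells for dual).
#' @param d latent dimension.
#' @param seed integer seed.
#' @return m x d numeric matrix.
#' @export
init_projection <- function(m, d, seed = 0L) {
  with_local_seed(seed, matrix(rnorm(m * d, sd = 1 / sqrt(m)), m, d))
}

# Full loss with gradients w.r.t. both parameter matrices, one evaluation.
# ctx carries per-run caches: X, Y and either gram features (primal) or the
# kernel matrices (dual).
.loss_and_grad <- function(ctx, params_x, params_y, hp, sigma) {
  if (hp$mode == "primal") {
    U <- ctx$X %*% params_x
    V <- ctx$Y %*% params_y
    g <- .mmd2_with_grad(U, V, sigma, hp$streaming, hp$block_size)
    m2 <- g$value
    gx <- crossprod(ctx$X, g$dU)
    gy <- crossprod(ctx$Y, g$dV)
    Px <- crossprod(params_x); diag(Px) <- diag(Px) - 1
    Py <- crossprod(params_y); diag(Py) <- diag(Py) - 1
    pen_x <- sum(Px * Px); pen_y <- sum(Py * Py)
    gpx <- 4 * params_x %*% Px
    gpy <- 4 * params_y %*% Py
    CWx <- ctx$gx$C %*% params_x
    CWy <- ctx$gy$C %*% params_y
    Mx <- crossprod(params_x, CWx)
    My <- crossprod(params_y, CWy)
    dis_x <- ctx$gx$tr_C2 - 2 * sum(CWx * CWx) + sum(Mx * Mx)
    dis_y <- ctx$gy$tr_C2 - 2 * sum(CWy * CWy) + sum(My * My)
    gdx <- 4 * (CWx %*% Mx - ctx$gx$C %*% CWx)
    gdy <- 4 * (CWy %*% My - ctx$gy$C %*% CWy)
  } else {
    U <- ctx$Kx %*% params_x
    V <- ctx$Ky %*% params_y
    g <- .mmd2_with_grad(U, V, sigma, hp$streaming, hp$block_size)
    m2 <- g$value
    gx <- ctx$Kx %*% g$dU
    gy <- ctx$Ky %*% g$dV
    Px <- crossprod(params_x, U); diag(Px) <- diag(Px) - 1
    Py <- crossprod(params_y, V); diag(Py) <- diag(Py) - 1
    pen_x <- sum(Px * Px); pen_y <- sum(Py * Py)
    gpx <- 4 * U %*% Px
    gpy <- 4 * V %*% Py
    # dis = ||K - BB^T||_F^2 with B = K alpha; d dis/d alpha = -4 K (KB - B B^T B)
    Mx <- crossprod(U)
    My <- crossprod(V)
    dis_x <- sum(ctx$Kx * ctx$Kx) - 2 * sum(U * (ctx$Kx %*% U)) + sum(Mx * Mx)
    dis_y <- sum(ctx$Ky * ctx$Ky) - 2 * sum(V * (ctx$Ky %*% V)) + sum(My * My)
    gdx <- -4 * (ctx$Kx %*% (ctx$Kx %*% U - U %*% Mx))
    gdy <- -4 * (ctx$Ky %*% (ctx$Ky %*% V - V %*% My))
  }
  list(loss = new_loss_breakdown(m2, pen_x, pen_y, dis_x, dis_y,
                                 hp$lambda1, hp$lambda2),
       grad_x = gx + hp$lambda1 * gpx + hp$lambda2 * gdx,
       grad_y = gy + hp$lambda1 * gpy + hp$lambda2 * gdy,
       U = U, V = V)
}

.check_finite_loss <- function(lb, iter) {
  for (comp in c("mmd2", "pen_x", "pen_y", "dis_x", "dis_y", "total")) {
    if (!is.finite(lb[[comp]])) {
      stop(sprintf("non-finite loss component '%s' at iteration %d", comp, iter))
    }
  }
}

# median pairwise Euclidean distance of the pooled initial embeddings,
# on at most max_n rows
.median_bandwidth <- function(U, V, seed, max_n = 2000L) {
  Z <- rbind(U, V)
  if (nrow(Z) > max_n) {
    idx <- with_local_seed(seed, sample.int(nrow(Z), max_n))
    Z <- Z[idx, , drop = FALSE]
  }
  s <- stats::median(stats::dist(Z))
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Align two single-cell modalities into a shared latent space
#'
#' Learns a linear map per modality into a common d-dimensional space by
#' full-batch Adam minimization of the squared-MMD matching loss plus
#' non-collapsing and distortion penalties (see [mmdma_loss()]). In
#' \code{mode = "primal"} the maps are feature-space matrices W (p x d) and
#' nothing quadratic in the cell count is ever formed when
#' \code{streaming = TRUE}; \code{mode = "dual"} optimizes sample-space
#' coefficients alpha (n x d) through the n x n linear kernel matrices, the
#' classical formulation, useful when p is very large.
#'
#' An "iteration" is one full-batch gradient step on both maps jointly. The
#' loss breakdown is recorded at iteration 0, every \code{eval_interval}
#' iterations and at the last iteration; when the two modalities have equal
#' cell counts and \code{correspondence = TRUE}, FOSCTTM (see [foscttm()]) is
#' recorded alongside, on a subsample of at most \code{foscttm_subsample}
#' cells during training and on all cells at the end.
#'
#' @param x,y the two modalities: [modality_matrix()] objects or numeric
#'   cell-by-feature matrices.
#' @param d latent dimension of the shared space.
#' @param lambda1 weight of the non-collapsing penalties.
#' @param lambda2 weight of the distortion penalties. The penalties are
#'   unnormalized Frobenius norms, so their scale grows with n and the data
#'   scale; lambda2 must absorb that (see the package vignette).
#' @param sigma Gaussian kernel bandwidth, or \code{"median"} for the median
#'   pairwise distance of the initial embeddings.
#' @param n_iter number of Adam iterations.
#' @param learning_rate Adam step size.
#' @param seed controls initialization and subsampling; two runs with the
#'   same inputs and seed produce identical traces.
#' @param mode \code{"primal"} or \code{"dual"}.
#' @param streaming blockwise MMD evaluation (no n1 x n2 allocation).
#' @param block_size rows per streaming block.
#' @param eval_interval iterations between trace records.
#' @param correspondence record FOSCTTM during training assuming row i of x
#'   matches row i of y; default: yes whenever cell counts are equal.
#' @param foscttm_subsample cap on cells used for FOSCTTM during training.
#' @param n_restarts number of random restarts. The matching term is
#'   non-convex and a single run can converge to a mismatched local minimum
#'   (e.g. with branches of a trajectory paired wrongly across modalities);
#'   with \code{n_restarts > 1} each restart is run for \code{screen_iter}
#'   iterations, the restart with the lowest total loss — an entirely
#'   unsupervised criterion — is selected, and rerun in full with its trace
#'   and FOSCTTM recorded. The returned object keeps the screening table.
#' @param screen_iter screening iterations per restart; \code{NULL} (default)
#'   screens at the full \code{n_iter}, which ranks basins most reliably
#'   (mismatched minima can sit within ~10\% of the global total, so early
#'   totals are not always conclusive).
#' @param init_x,init_y optional initial parameter matrices (override the
#'   seeded Gaussian initialization); used e.g. to start the dual solver at a
#'   state equivalent to a primal one.
#' @param verbose print the loss breakdown at every record.
#' @return An object of class \code{"mmdma"}: list with \code{params_x},
#'   \code{params_y}, \code{embedding_x}, \code{embedding_y}, \code{trace}
#'   (data frame: iteration, mmd2, pen_x, pen_y, dis_x, dis_y, total,
#'   foscttm), \code{hp_used}, \code{sigma_used}, \code{cell_ids_x},
#'   \code{cell_ids_y}, and the training matrices (needed by
#'   \code{predict} in dual mode).
#' @seealso [foscttm()], [simulate_branch_pair()], [mmdma_loss()]
#' @examples
#' pair <- simulate_branch_pair(n = 80, px = 12, py = 9, seed = 1)
#' fit <- mmdma(pair$x, pair$y, d = 3, n_iter = 50, seed = 1)
#' fit
#' @export
mmdma <- function(x, y, d = 10L, lambda1 = 0.1, lambda2 = 1e-6,
                  sigma = "median", n_iter = 500L, learning_rate = 0.05,
                  seed = 0L, mode = c("primal", "dual"), streaming = TRUE,
                  block_size = 4096L, eval_interval = 10L,
                  correspondence = NULL, foscttm_subsample = 1000L,
                  n_restarts = 1L, screen_iter = NULL,
                  init_x = NULL, init_y = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  n_restarts <- as.integer(n_restarts)
  if (n_restarts > 1L && is.null(init_x) && is.null(init_y)) {
    if (is.null(screen_iter)) screen_iter <- n_iter
    seeds <- as.integer(seed) + (seq_len(n_restarts) - 1L) * 17L
    totals <- vapply(seeds, function(s) {
      sf <- mmdma(x, y, d = d, lambda1 = lambda1, lambda2 = lambda2,
                  sigma = sigma, n_iter = screen_iter,
                  learning_rate = learning_rate, seed = s, mode = mode,
                  streaming = streaming, block_size = block_size,
                  eval_interval = max(1L, as.integer(screen_iter)),
                  correspondence = FALSE, n_restarts = 1L)
      sf$trace$total[nrow(sf$trace)]
    }, 0)
    best <- seeds[which.min(totals)]
    if (verbose) {
      message(sprintf("restart screening: selected seed %d (total %.6g)",
                      best, min(totals)))
    }
    fit <- mmdma(x, y, d = d, lambda1 = lambda1, lambda2 = lambda2,
                 sigma = sigma, n_iter = n_iter,
                 learning_rate = learning_rate, seed = best, mode = mode,
                 streaming = streaming, block_size = block_size,
                 eval_interval = eval_interval, correspondence = correspondence,
                 foscttm_subsample = foscttm_subsample, n_restarts = 1L,
                 verbose = verbose)
    fit$screening <- data.frame(restart = seq_len(n_restarts), seed = seeds,
                                total = totals)
    fit$call <- match.call()
    return(fit)
  }
  hp <- mmdma_hyperparams(d = d, lambda1 = lambda1, lambda2 = lambda2,
                          sigma = sigma, n_iter = n_iter,
                          learning_rate = learning_rate, seed = seed,
                          mode = mode, streaming = streaming,
                          block_size = block_size, eval_interval = eval_interval)
  pair <- validate_pair(x, y, hp)
  x <- pair$x; y <- pair$y
  if (is.null(correspondence)) correspondence <- pair$correspondence_possible
  if (correspondence && !pair$correspondence_possible) {
    stop("correspondence evaluation requires equal cell counts")
  }

  X <- x$values; Y <- y$values
  nx <- nrow(X); ny <- nrow(Y)

  ctx <- list(X = X, Y = Y)
  if (mode == "primal") {
    ctx$gx <- gram_features(X); ctx$gy <- gram_features(Y)
    mx <- ncol(X); my <- ncol(Y)
  } else {
    ctx$Kx <- tcrossprod(X); ctx$Ky <- tcrossprod(Y)
    mx <- nx; my <- ny
  }
  params_x <- if (is.null(init_x)) init_projection(mx, hp$d, seed) else init_x
  params_y <- if (is.null(init_y)) init_projection(my, hp$d, seed + 1L) else init_y
  if (nrow(params_x) != mx || ncol(params_x) != hp$d) stop("shape error: init_x")
  if (nrow(params_y) != my || ncol(params_y) != hp$d) stop("shape error: init_y")

  embed0 <- function(px, py) {
    if (mode == "primal") list(U = X %*% px, V = Y %*% py)
    else list(U = ctx$Kx %*% px, V = ctx$Ky %*% py)
  }
  sigma_used <- if (identical(hp$sigma, "median")) {
    e0 <- embed0(params_x, params_y)
    .median_bandwidth(e0$U, e0$V, seed + 2L)
  } else hp$sigma

  fos_idx <- NULL
  if (correspondence && nx > foscttm_subsample) {
    fos_idx <- with_local_seed(seed + 3L, sort(sample.int(nx, foscttm_subsample)))
  }
  record_fos <- function(U, V, full = FALSE) {
    if (!correspondence) return(NA_real_)
    if (!full && !is.null(fos_idx)) {
      U <- U[fos_idx, , drop = FALSE]; V <- V[fos_idx, , drop = FALSE]
    }
    foscttm(U, V, block_size = hp$block_size)$mean
  }

  # Adam state (both maps updated jointly each step)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m_x <- v_x <- params_x * 0
  m_y <- v_y <- params_y * 0

  rec_iter <- integer(0); rec_loss <- list(); rec_fos <- numeric(0)
  push <- function(it, lb, fos) {
    rec_iter[[length(rec_iter) + 1L]] <<- it
    rec_loss[[length(rec_loss) + 1L]] <<- lb
    rec_fos[[length(rec_fos) + 1L]] <<- fos
    if (verbose) {
      message(sprintf("iter %d: total=%.6g mmd2=%.6g foscttm=%s", it, lb$total,
                      lb$mmd2, ifelse(is.na(fos), "-", sprintf("%.4f", fos))))
    }
  }

  for (t in seq_len(hp$n_iter)) {
    lg <- .loss_and_grad(ctx, params_x, params_y, hp, sigma_used)
    .check_finite_loss(lg$loss, t - 1L)
    if ((t - 1L) %% hp$eval_interval == 0L) {
      push(t - 1L, lg$loss, record_fos(lg$U, lg$V))
    }
    # Adam update
    m_x <- b1 * m_x + (1 - b1) * lg$grad_x
    v_x <- b2 * v_x + (1 - b2) * lg$grad_x^2
    m_y <- b1 * m_y + (1 - b1) * lg$grad_y
    v_y <- b2 * v_y + (1 - b2) * lg$grad_y^2
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    params_x <- params_x - hp$learning_rate * (m_x / corr1) /
      (sqrt(v_x / corr2) + eps)
    params_y <- params_y - hp$learning_rate * (m_y / corr1) /
      (sqrt(v_y / corr2) + eps)
  }
  efin <- embed0(params_x, params_y)
  lb_fin <- mmdma_loss(X, Y, params_x, params_y,
                       within_sigma(hp, sigma_used))
  .check_finite_loss(lb_fin, hp$n_iter)
  push(hp$n_iter, lb_fin, record_fos(efin$U, efin$V, full = TRUE))

  trace <- data.frame(
    iteration = unlist(rec_iter),
    mmd2 = vapply(rec_loss, `[[`, 0, "mmd2"),
    pen_x = vapply(rec_loss, `[[`, 0, "pen_x"),
    pen_y = vapply(rec_loss, `[[`, 0, "pen_y"),
    dis_x = vapply(rec_loss, `[[`, 0, "dis_x"),
    dis_y = vapply(rec_loss, `[[`, 0, "dis_y"),
    total = vapply(rec_loss, `[[`, 0, "total"),
    foscttm = rec_fos
  )
  structure(list(params_x = params_x, params_y = params_y,
                 embedding_x = efin$U, embedding_y = efin$V,
                 trace = trace, hp_used = hp, sigma_used = sigma_used,
                 mode = mode, correspondence = correspondence,
                 cell_ids_x = x$cell_ids, cell_ids_y = y$cell_ids,
                 data_x = X, data_y = Y, call = match.call()),
            class = "mmdma")
}

# hp copy with a resolved numeric sigma
within_sigma <- function(hp, sigma) { hp$sigma <- sigma; hp }

#' Embed a modality with fitted parameters
#'
#' Applies a learned map: \code{X \%*\% W} in the primal, or
#' \code{XX^T \%*\% alpha} in the dual (which equals the primal embedding at
#' \code{W = X^T alpha}).
#'
#' @param x modality matrix or numeric matrix.
#' @param params p x d (primal) or n x d (dual) parameters.
#' @param mode parameterization the parameters live in.
#' @return n x d embedding.
#' @export
embed_modality <- function(x, params, mode = c("primal", "dual")) {
  mode <- match.arg(mode)
  X <- as_modality_values(x)
  if (mode == "primal") {
    if (ncol(X) != nrow(params)) stop("shape error: ncol(X) != nrow(W)")
    X %*% params
  } else {
    if (nrow(X) != nrow(params)) stop("shape error: nrow(X) != nrow(alpha)")
    tcrossprod(X) %*% params
  }
}

#' @export
print.mmdma <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("mmdma fit (%s mode): %d x-cells, %d y-cells -> d=%d\n",
              x$mode, nrow(x$embedding_x), nrow(x$embedding_y), x$hp_used$d))
  cat(sprintf("  %d iterations, sigma=%.4g, total loss %.6g -> %.6g\n",
              x$hp_used$n_iter, x$sigma_used, tr$total[1L],
              tr$total[nrow(tr)]))
  if (x$correspondence) {
    cat(sprintf("  final FOSCTTM: %.4f (0 = perfect, 0.5 = random)\n",
                tr$foscttm[nrow(tr)]))
  }
  invisible(x)
}

#' @export
summary.mmdma <- function(object, ...) {
  tr <- object$trace
  last <- tr[nrow(tr), ]
  cat("Multimodal alignment fit\n")
  cat(sprintf("  mode: %s   streaming: %s   d: %d\n", object$mode,
              object$hp_used$streaming, object$hp_used$d))
  cat(sprintf("  lambda1: %g   lambda2: %g   sigma: %.4g   lr: %g\n",
              object$hp_used$lambda1, object$hp_used$lambda2,
              object$sigma_used, object$hp_used$learning_rate))
  cat(sprintf("  iterations: %d (trace records: %d)\n",
              object$hp_used$n_iter, nrow(tr)))
  cat("  final losses:\n")
  cat(sprintf("    mmd2: %.6g   pen: %.6g + %.6g   dis: %.6g + %.6g\n",
              last$mmd2, last$pen_x, last$pen_y, last$dis_x, last$dis_y))
  cat(sprintf("    total: %.6g (initial %.6g)\n", last$total, tr$total[1L]))
  if (object$correspondence) {
    cat(sprintf("  FOSCTTM: %.4f -> %.4f\n", tr$foscttm[1L], last$foscttm))
  }
  invisible(object)
}

#' @export
coef.mmdma <- function(object, ...) {
  list(x = object$params_x, y = object$params_y)
}

#' @export
fitted.mmdma <- function(object, ...) {
  list(x = object$embedding_x, y = object$embedding_y)
}

#' Embed new cells with a fitted alignment
#'
#' @param object a fitted [mmdma()] object.
#' @param newdata modality matrix or numeric matrix in the feature space of
#'   the chosen modality. In dual mode new cells are embedded through the
#'   cross-kernel with the training cells,
#'   \code{X_new \%*\% t(X_train) \%*\% alpha}.
#' @param modality which modality's map to apply.
#' @param ... unused.
#' @return n x d embedding of \code{newdata}.
#' @export
predict.mmdma <- function(object, newdata = NULL, modality = c("x", "y"), ...) {
  modality <- match.arg(modality)
  if (is.null(newdata)) {
    return(if (modality == "x") object$embedding_x else object$embedding_y)
  }
  Xn <- as_modality_values(newdata)
  params <- if (modality == "x") object$params_x else object$params_y
  if (object$mode == "primal") {
    if (ncol(Xn) != nrow(params)) stop("shape error: feature dimension mismatch")
    Xn %*% params
  } else {
    Xtr <- if (modality == "x") object$data_x else object$data_y
    if (ncol(Xn) != ncol(Xtr)) stop("shape error: feature dimension mismatch")
    Xn %*% crossprod(Xtr, params)
  }
}

#' Plot a fitted alignment
#'
#' \code{which = "trace"} draws the total loss and the MMD component against
#' iteration (log scale), plus FOSCTTM when recorded; \code{which =
#' "embedding"} scatters the first two shared dimensions of both modalities.
#'
#' @param x a fitted [mmdma()] object.
#' @param which \code{"trace"} or \code{"embedding"}.
#' @param ... passed to the underlying plot call.
#' @return invisibly, \code{x}.
#' @export
plot.mmdma <- function(x, which = c("trace", "embedding"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (which == "trace") {
    has_fos <- x$correspondence && any(is.finite(tr$foscttm))
    if (has_fos) {
      op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    }
    graphics::plot(tr$iteration, tr$total, type = "l", log = "y",
                   xlab = "iteration", ylab = "loss", ...)
    graphics::lines(tr$iteration, pmax(tr$mmd2, .Machine$double.xmin),
                    col = "grey40", lty = 2)
    graphics::legend("topright", c("total", "mmd2"), lty = c(1, 2),
                     col = c("black", "grey40"), bty = "n")
    if (has_fos) {
      graphics::plot(tr$iteration, tr$foscttm, type = "l", ylim = c(0, 0.6),
                     xlab = "iteration", ylab = "FOSCTTM")
      graphics::abline(h = 0.5, lty = 3)
    }
  } else {
    U <- x$embedding_x; V <- x$embedding_y
    if (ncol(U) < 2L) stop("embedding plot needs d >= 2")
    graphics::plot(rbind(U[, 1:2], V[, 1:2]), type = "n",
                   xlab = "dim 1", ylab = "dim 2", ...)
    graphics::points(U[, 1:2], col = grDevices::adjustcolor("#1b6ca8", 0.6),
                     pch = 16, cex = 0.6)
    graphics::points(V[, 1:2], col = grDevices::adjustcolor("#c0392b", 0.6),
                     pch = 17, cex = 0.6)
    graphics::legend("topright", c("modality x", "modality y"),
                     col = c("#1b6ca8", "#c0392b"), pch = c(16, 17), bty = "n")
  }
  invisible(x)
}
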