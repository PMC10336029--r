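#' Branch-shaped latent space
#'
#' Samples cells on a branching trajectory: \code{n_branches} unit directions
#' drawn at random from the origin, cells assigned to branches near-uniformly,
#' position along the branch uniform on [0, 1], plus isotropic Gaussian
#' jitter. This is the latent geometry a developmental trajectory produces
#' after dimension reduction, and the structure both simulated modalities
#' share.
#'
#' @param n number of cells.
#' @param d_latent latent dimension.
#' @param n_branches number of branches from the origin.
#' @param noise_sd standard deviation of the isotropic jitter.
#' @param seed integer seed; output is a deterministic function of it.
#' @return list with \code{latent} (n x d_latent) and \code{branch_labels}
#'   (integers in 0..n_branches-1).
#' @export
generate_branch_latent <- function(n, d_latent = 5L, n_branches = 3L,
                                   noise_sd = 0.02, seed = 0L) {
  if (n < 1L) stop("config error: n must be >= 1")
  if (d_latent < 1L) stop("config error: d_latent must be >= 1")
  if (n_branches < 1L) stop("config error: n_branches must be >= 1")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  with_local_seed(seed, {
    dirs <- matrix(rnorm(n_branches * d_latent), n_branches, d_latent)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # near-uniform assignment: sizes differ by at most one
    labels <- rep(seq_len(n_branches) - 1L, length.out = n)
    t_pos <- runif(n)
    latent <- t_pos * dirs[labels + 1L, , drop = FALSE]
    if (noise_sd > 0) {
      latent <- latent + matrix(rnorm(n * d_latent, sd = noise_sd), n, d_latent)
    }
    list(latent = latent, branch_labels = labels)
  })
}

#' Observe a latent space through one modality
#'
#' Projects the shared latent coordinates into a p-dimensional feature space
#' through a random linear map with i.i.d. standard normal entries, then adds
#' i.i.d. Gaussian measurement noise. Row order is preserved, so the cell
#' correspondence across modalities is the row index.
#'
#' @param latent n x d_latent matrix.
#' @param p number of observed features (>= d_latent).
#' @param noise_sd standard deviation of the measurement noise.
#' @param seed seed for the map and the noise (use different seeds per
#'   modality).
#' @param id_prefix prefix for generated feature ids.
#' @return a [modality_matrix()] (n cells x p features).
#' @export
project_modality <- function(latent, p, noise_sd = 0.1, seed = 0L,
                             id_prefix = "feat") {
  if (p < ncol(latent)) stop("config error: p must be >= d_latent")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  n <- nrow(latent)
  values <- with_local_seed(seed, {
    A <- matrix(rnorm(p * ncol(latent)), p, ncol(latent))
    M <- latent %*% t(A)
    if (noise_sd > 0) M <- M + matrix(rnorm(n * p, sd = noise_sd), n, p)
    M
  })
  modality_matrix(values,
                  cell_ids = sprintf("cell_%04d", seq_len(n)),
                  feature_ids = sprintf("%s_%04d", id_prefix, seq_len(p)))
}

#' Simulate a matched pair of modalities
#'
#' Generates a branch-shaped latent space and observes it through two
#' independent random linear maps with modality-specific noise. Row i of the
#' two modalities is the same cell, giving ground-truth correspondence for
#' FOSCTTM. The latent geometry and the two projections use separate derived
#' seeds so either can be varied holding the other fixed.
#'
#' Defaults describe a moderate-noise regime: jitter of 0.02 around branches
#' of unit length, and measurement noise of 0.1 against feature values whose
#' scale is about 0.5.
#'
#' @param n cells per modality.
#' @param d_latent latent dimension.
#' @param n_branches branches from the origin.
#' @param px,py feature counts of the two modalities.
#' @param latent_noise_sd jitter around the branch skeleton.
#' @param noise_sd_x,noise_sd_y measurement noise per modality.
#' @param seed master seed; latent and the two projections use
#'   \code{seed}, \code{seed + 1}, \code{seed + 2}.
#' @return An object of class \code{"synthetic_pair"}: list with \code{x},
#'   \code{y} ([modality_matrix()]s), \code{latent}, \code{branch_labels} and
#'   \code{gen_params} (every knob plus the seed, for provenance).
#' @examples
#' pair <- simulate_branch_pair(n = 100, seed = 7)
#' dim(pair$x)
#' @export
simulate_branch_pair <- function(n = 300L, d_latent = 5L, n_branches = 3L,
                                 px = 50L, py = 40L, latent_noise_sd = 0.02,
                                 noise_sd_x = 0.1, noise_sd_y = 0.1,
                                 seed = 0L) {
  lat <- generate_branch_latent(n, d_latent, n_branches, latent_noise_sd, seed)
  x <- project_modality(lat$latent, px, noise_sd_x, seed + 1L, id_prefix = "gene")
  y <- project_modality(lat$latent, py, noise_sd_y, seed + 2L, id_prefix = "prot")
  structure(list(x = x, y = y, latent = lat$latent,
                 branch_labels = lat$branch_labels,
                 gen_params = list(n = n, d_latent = d_latent,
                                   n_branches = n_branches, px = px, py = py,
                                   latent_noise_sd = latent_noise_sd,
                                   noise_sd_x = noise_sd_x,
                                   noise_sd_y = noise_sd_y, seed = seed)),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  gp <- x$gen_params
  cat(sprintf(
    "synthetic pair: %d cells, %d branches in %d latent dims -> %d + %d features\n",
    gp$n, gp$n_branches, gp$d_latent, gp$px, gp$py))
  invisible(x)
}
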