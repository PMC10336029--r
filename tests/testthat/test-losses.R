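test_that("squared MMD matches hand-computed and brute-force values", {
  # identical samples: exactly zero signal
  set.seed(1)
  U <- matrix(rnorm(20), 10, 2)
  expect_lt(abs(mmd2(U, U, sigma = 1)), 1e-12)

  # 1x1 case evaluated by hand: 1 + 1 - 2 exp(-1/2)
  expect_equal(mmd2(matrix(0), matrix(1), sigma = 1), 2 - 2 * exp(-0.5),
               tolerance = 1e-14)

  # arbitrary samples against the double-loop oracle, several shapes/sigmas
  for (case in list(c(7, 5, 2, 1), c(12, 8, 3, 0.7), c(5, 9, 1, 2.5))) {
    set.seed(case[1] + case[2])
    A <- matrix(rnorm(case[1] * case[3]), case[1], case[3])
    B <- matrix(rnorm(case[2] * case[3]), case[2], case[3]) + 0.5
    got <- mmd2(A, B, sigma = case[4])
    expect_equal(got, mmd2_oracle(A, B, case[4]), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_equal(mmd2(A, B, sigma = case[4], biased = FALSE),
                 mmd2_unbiased_oracle(A, B, case[4]), tolerance = 1e-12)
  }
})

test_that("streaming and naive MMD paths agree for all block sizes", {
  set.seed(7)
  U <- matrix(rnorm(53 * 4), 53, 4)
  V <- matrix(rnorm(47 * 4), 47, 4) + 0.3
  v0 <- mmd2(U, V, sigma = 0.8, streaming = FALSE)
  g0 <- mmd2_grad(U, V, sigma = 0.8, streaming = FALSE)
  for (bs in c(1L, 7L, 53L, 3L * 53L)) {
    expect_lt(rel_diff(mmd2(U, V, 0.8, streaming = TRUE, block_size = bs), v0),
              1e-10)
    g1 <- mmd2_grad(U, V, 0.8, streaming = TRUE, block_size = bs)
    expect_lt(rel_diff(g1$dU, g0$dU), 1e-10)
    expect_lt(rel_diff(g1$dV, g0$dV), 1e-10)
  }
})

test_that("MMD is invariant to a joint rigid rotation and shrinks to 0 as sigma grows", {
  set.seed(11)
  U <- matrix(rnorm(30 * 3), 30, 3); V <- matrix(rnorm(25 * 3), 25, 3)
  R <- random_rotation(3, 5)
  expect_equal(mmd2(U %*% R, V %*% R, 1.1), mmd2(U, V, 1.1), tolerance = 1e-12)
  g <- mmd2_grad(U, V, sigma = 1e6)
  expect_lt(max(abs(g$dU)), 1e-10)
  expect_lt(max(abs(g$dV)), 1e-10)
})

test_that("MMD gradient matches central finite differences", {
  set.seed(3)
  U <- matrix(rnorm(10), 5, 2); V <- matrix(rnorm(8), 4, 2)
  g <- mmd2_grad(U, V, sigma = 1)
  fdU <- finite_diff(function(M) mmd2(M, V, 1), U)
  fdV <- finite_diff(function(M) mmd2(U, M, 1), V)
  expect_lt(rel_diff(g$dU, fdU), 1e-5)
  expect_lt(rel_diff(g$dV, fdV), 1e-5)
})

test_that("linear-time estimator: termwise zero at identity, hand sum at n=6, unbiasedness", {
  set.seed(9)
  U <- matrix(rnorm(12), 6, 2)
  expect_identical(mmd_linear_time(U, U, 1), 0)

  V <- matrix(rnorm(12), 6, 2)
  # hand-summed h over the 3 consecutive disjoint pairs
  k <- function(a, b) exp(-sum((a - b)^2) / 2)
  hsum <- 0
  for (i in c(1, 3, 5)) {
    hsum <- hsum + k(U[i, ], U[i + 1, ]) + k(V[i, ], V[i + 1, ]) -
      k(U[i, ], V[i + 1, ]) - k(U[i + 1, ], V[i, ])
  }
  expect_equal(mmd_linear_time(U, V, 1), hsum / 3, tolerance = 1e-12)

  expect_warning(mmd_linear_time(U[1:5, ], V[1:5, ], 1), "odd")
  expect_error(mmd_linear_time(U, V[1:4, ], 1), "shape error")

  # mean over shuffles approximates the full estimator (n=200)
  set.seed(21)
  n <- 200
  A <- matrix(rnorm(n * 2), n, 2); B <- matrix(rnorm(n * 2), n, 2) + 0.4
  vals <- replicate(200, {
    idx <- sample.int(n)
    mmd_linear_time(A[idx, ], B[idx, ], 1)
  })
  full_biased <- mmd2(A, B, 1)
  se <- sd(vals) / sqrt(length(vals))
  offset_bound <- 2 / n   # |biased - unbiased| <= 2/n for this kernel
  expect_lt(abs(mean(vals) - full_biased), 3 * se + offset_bound)
})

test_that("non-collapsing penalty has its closed-form values", {
  Q <- qr.Q(qr(matrix(rnorm(15), 5, 3)))      # orthonormal columns
  expect_lt(penalty_primal(Q), 1e-20)
  expect_equal(penalty_primal(2 * Q), 27, tolerance = 1e-12)  # ||4I-I||^2 = 9*3
  expect_identical(penalty_primal(matrix(0, 5, 3)), 3)        # ||-I||^2 = d
})

test_that("distortion: efficient trace formula equals explicit n x n evaluation", {
  set.seed(13)
  X <- matrix(rnorm(20 * 4), 20, 4)
  W <- matrix(rnorm(8), 4, 2)
  expect_lt(rel_diff(distortion_primal(X, W, "efficient"),
                     distortion_primal(X, W, "naive")), 1e-8)
  # zero map leaves the full similarity: tr(C^2)
  gf <- gram_features(X)
  expect_equal(distortion_primal(X, matrix(0, 4, 2)), gf$tr_C2,
               tolerance = 1e-12)
  expect_equal(distortion_primal(gf, W), distortion_primal(X, W, "naive"),
               tolerance = 1e-8)
  # perfect reconstruction: X = I, W orthonormal square
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_lt(distortion_primal(diag(3), Q), 1e-20)
})

test_that("dual forms equal primal forms at W = X^T alpha", {
  inst <- small_instance(2)
  K <- tcrossprod(inst$X)
  W <- crossprod(inst$X, inst$ax)
  expect_lt(rel_diff(penalty_dual(K, inst$ax), penalty_primal(W)), 1e-8)
  expect_lt(rel_diff(distortion_dual(K, inst$ax),
                     distortion_primal(inst$X, W, "naive")), 1e-8)
  Kbad <- K; Kbad[1, 2] <- Kbad[1, 2] + 1
  expect_error(penalty_dual(Kbad, inst$ax), "symmetric")
})

test_that("every loss component agrees across primal and dual parameterizations", {
  for (seed in 1:3) {
    inst <- small_instance(seed)
    hp_p <- mmdma_hyperparams(d = 3, lambda1 = 0.5, lambda2 = 2, sigma = 1.3,
                              mode = "primal", streaming = FALSE)
    hp_d <- mmdma_hyperparams(d = 3, lambda1 = 0.5, lambda2 = 2, sigma = 1.3,
                              mode = "dual", streaming = FALSE)
    lp <- mmdma_loss(inst$X, inst$Y, crossprod(inst$X, inst$ax),
                     crossprod(inst$Y, inst$ay), hp_p)
    ld <- mmdma_loss(inst$X, inst$Y, inst$ax, inst$ay, hp_d)
    for (comp in c("mmd2", "pen_x", "pen_y", "dis_x", "dis_y", "total")) {
      expect_lt(rel_diff(lp[[comp]], ld[[comp]]), 1e-8)
    }
  }
})

test_that("full-loss gradients (primal and dual) match finite differences", {
  inst <- small_instance(6, n = 10, px = 3, py = 3, d = 2)
  hp <- mmdma_hyperparams(d = 2, lambda1 = 0.4, lambda2 = 0.9, sigma = 1.1,
                          streaming = FALSE)
  Wx <- crossprod(inst$X, inst$ax[, 1:2]); Wy <- crossprod(inst$Y, inst$ay[, 1:2])
  ctx <- list(X = inst$X, Y = inst$Y,
              gx = gram_features(inst$X), gy = gram_features(inst$Y))
  lg <- mmdma:::.loss_and_grad(ctx, Wx, Wy, hp, 1.1)
  fdx <- finite_diff(function(M) mmdma_loss(inst$X, inst$Y, M, Wy, hp)$total, Wx)
  fdy <- finite_diff(function(M) mmdma_loss(inst$X, inst$Y, Wx, M, hp)$total, Wy)
  expect_lt(rel_diff(lg$grad_x, fdx), 1e-5)
  expect_lt(rel_diff(lg$grad_y, fdy), 1e-5)

  hp_d <- mmdma_hyperparams(d = 2, lambda1 = 0.4, lambda2 = 0.9, sigma = 1.1,
                            mode = "dual", streaming = FALSE)
  ax <- inst$ax[, 1:2]; ay <- inst$ay[, 1:2]
  ctx_d <- list(X = inst$X, Y = inst$Y,
                Kx = tcrossprod(inst$X), Ky = tcrossprod(inst$Y))
  lgd <- mmdma:::.loss_and_grad(ctx_d, ax, ay, hp_d, 1.1)
  fdax <- finite_diff(function(M) mmdma_loss(inst$X, inst$Y, M, ay, hp_d)$total, ax)
  expect_lt(rel_diff(lgd$grad_x, fdax), 1e-5)
})

test_that("pen/dis gradient closed forms hold", {
  set.seed(17)
  W <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(40), 10, 4)
  C <- crossprod(X)
  # d pen / d W = 4 W (W^T W - I)
  fd_pen <- finite_diff(penalty_primal, W)
  expect_lt(rel_diff(fd_pen, 4 * W %*% (crossprod(W) - diag(3))), 1e-5)
  # d dis / d W = -4 C^2 W + 4 C W (W^T C W)
  fd_dis <- finite_diff(function(M) distortion_primal(X, M, "naive"), W, h = 1e-6)
  an_dis <- -4 * C %*% (C %*% W) + 4 * C %*% W %*% (crossprod(W, C %*% W))
  expect_lt(rel_diff(fd_dis, an_dis), 1e-4)
})
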