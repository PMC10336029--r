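test_that("initialization is seeded, reproducible and has the stated scale", {
  W1 <- init_projection(100, 10, seed = 0)
  W2 <- init_projection(100, 10, seed = 0)
  expect_identical(W1, W2)
  expect_false(identical(W1, init_projection(100, 10, seed = 1)))
  # empirical entry variance within 3 SE of 1/100 (var of var ~ 2 sigma^4 / n)
  v <- var(as.vector(W1))
  se <- sqrt(2 / (100 * 10 - 1)) * (1 / 100)
  expect_lt(abs(v - 1 / 100), 3 * se)
})

test_that("embedding operator matches its definition in both modes", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4)
  expect_equal(embed_modality(X, diag(4)), X, ignore_attr = TRUE)
  expect_identical(embed_modality(X, matrix(0, 4, 2)), matrix(0, 15, 2))
  alpha <- matrix(rnorm(30), 15, 2)
  expect_equal(embed_modality(X, alpha, mode = "dual"),
               embed_modality(X, crossprod(X, alpha)), tolerance = 1e-12)
  expect_error(embed_modality(X, matrix(0, 3, 2)), "shape error")
})

test_that("fitting descends on a symmetric instance and is bit-reproducible", {
  set.seed(10)
  X <- matrix(rnorm(60 * 6), 60, 6)
  f1 <- mmdma(X, X, d = 2, lambda1 = 0, lambda2 = 0, sigma = 1, n_iter = 60,
              learning_rate = 0.01, seed = 4, eval_interval = 20,
              correspondence = FALSE)
  tr <- f1$trace
  expect_lt(tr$mmd2[nrow(tr)], tr$mmd2[1L])
  expect_lt(tr$total[nrow(tr)], tr$total[1L])
  f2 <- mmdma(X, X, d = 2, lambda1 = 0, lambda2 = 0, sigma = 1, n_iter = 60,
              learning_rate = 0.01, seed = 4, eval_interval = 20,
              correspondence = FALSE)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params_x, f2$params_x)
  # embedding is exactly X W at the returned parameters
  expect_identical(f1$embedding_x, X %*% f1$params_x)
})

test_that("streaming and naive fits produce identical traces in both modes", {
  set.seed(20)
  X <- matrix(rnorm(50 * 5), 50, 5)
  Y <- matrix(rnorm(50 * 4), 50, 4)
  for (mode in c("primal", "dual")) {
    args <- list(x = X, y = Y, d = 3, lambda1 = 0.1, lambda2 = 1e-4,
                 sigma = 1, n_iter = 10, learning_rate = 0.01, seed = 1,
                 mode = mode, eval_interval = 1, correspondence = FALSE)
    f_str <- do.call(mmdma, c(args, streaming = TRUE, block_size = 16L))
    f_nai <- do.call(mmdma, c(args, streaming = FALSE))
    expect_lt(rel_diff(f_str$trace$total, f_nai$trace$total), 1e-6)
    expect_lt(rel_diff(f_str$params_x, f_nai$params_x), 1e-6)
  }
})

test_that("primal and dual losses coincide at equivalent parameters", {
  set.seed(30)
  X <- matrix(rnorm(50 * 5), 50, 5)
  Y <- matrix(rnorm(50 * 4), 50, 4)
  a0x <- init_projection(50, 3, seed = 7)
  a0y <- init_projection(50, 3, seed = 8)
  fp <- mmdma(X, Y, d = 3, lambda1 = 0.2, lambda2 = 1e-4, sigma = 1,
              n_iter = 0, seed = 1, eval_interval = 1, correspondence = FALSE,
              init_x = crossprod(X, a0x), init_y = crossprod(Y, a0y))
  fd <- mmdma(X, Y, d = 3, lambda1 = 0.2, lambda2 = 1e-4, sigma = 1,
              n_iter = 0, seed = 1, mode = "dual", eval_interval = 1,
              correspondence = FALSE, init_x = a0x, init_y = a0y)
  expect_lt(rel_diff(fp$trace$total[1], fd$trace$total[1]), 1e-8)
  expect_lt(rel_diff(fp$embedding_x, fd$embedding_x), 1e-8)
})

test_that("fit records FOSCTTM when correspondence holds and errors when it cannot", {
  pair <- simulate_branch_pair(n = 60, px = 10, py = 8, seed = 3)
  f <- mmdma(pair$x, pair$y, d = 2, n_iter = 5, sigma = 1, seed = 1,
             eval_interval = 5)
  expect_true(all(is.finite(f$trace$foscttm)))
  expect_true(all(f$trace$foscttm >= 0 & f$trace$foscttm <= 1))
  expect_error(
    mmdma(matrix(rnorm(40), 10, 4), matrix(rnorm(36, ), 12, 3), d = 2,
          n_iter = 2, sigma = 1, correspondence = TRUE),
    "equal cell counts")
})

test_that("restart screening selects by total loss and stays reproducible", {
  pair <- simulate_branch_pair(n = 80, px = 12, py = 10, seed = 5)
  f <- mmdma(pair$x, pair$y, d = 3, lambda1 = 0.1, lambda2 = 1e-6,
             sigma = "median", n_iter = 40, seed = 2, eval_interval = 40,
             n_restarts = 3)
  expect_s3_class(f, "mmdma")
  expect_equal(nrow(f$screening), 3L)
  # the selected restart attains the screening minimum
  expect_equal(f$trace$total[nrow(f$trace)], min(f$screening$total),
               tolerance = 1e-9)
  f2 <- mmdma(pair$x, pair$y, d = 3, lambda1 = 0.1, lambda2 = 1e-6,
              sigma = "median", n_iter = 40, seed = 2, eval_interval = 40,
              n_restarts = 3)
  expect_identical(f$trace, f2$trace)
})

test_that("S3 methods expose coefficients, fitted embeddings and predictions", {
  pair <- simulate_branch_pair(n = 50, px = 8, py = 6, seed = 9)
  f <- mmdma(pair$x, pair$y, d = 2, n_iter = 5, sigma = 1, seed = 1,
             eval_interval = 5)
  co <- coef(f)
  expect_equal(dim(co$x), c(8L, 2L))
  expect_identical(fitted(f)$x, f$embedding_x)
  expect_equal(predict(f, pair$x), f$embedding_x, ignore_attr = TRUE)
  expect_identical(predict(f, modality = "y"), f$embedding_y)
  expect_output(print(f), "mmdma fit")
  expect_output(summary(f), "final losses")

  fd <- mmdma(pair$x, pair$y, d = 2, n_iter = 3, sigma = 1, seed = 1,
              mode = "dual", eval_interval = 3)
  expect_equal(predict(fd, pair$x), fd$embedding_x, ignore_attr = TRUE)
})

test_that("non-finite losses abort with a named component and iteration", {
  set.seed(40)
  X <- matrix(rnorm(30 * 3), 30, 3) * 1e150   # overflow the distortion term
  expect_error(
    mmdma(X, X, d = 2, lambda1 = 0, lambda2 = 1, sigma = 1, n_iter = 3,
          correspondence = FALSE),
    "non-finite loss component '(dis|total)")
})
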