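# Independent oracles used across the suite. These deliberately use plain
# double loops / explicit n x n algebra so they share no code with the
# implementation they check.

# biased squared-MMD by explicit double loops over all pairs
mmd2_oracle <- function(U, V, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  n1 <- nrow(U); n2 <- nrow(V)
  suu <- svv <- suv <- 0
  for (i in seq_len(n1)) for (j in seq_len(n1)) suu <- suu + k(U[i, ], U[j, ])
  for (i in seq_len(n2)) for (j in seq_len(n2)) svv <- svv + k(V[i, ], V[j, ])
  for (i in seq_len(n1)) for (j in seq_len(n2)) suv <- suv + k(U[i, ], V[j, ])
  suu / n1^2 + svv / n2^2 - 2 * suv / (n1 * n2)
}

# unbiased U-statistic, double loops, self-pairs excluded
mmd2_unbiased_oracle <- function(U, V, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  n1 <- nrow(U); n2 <- nrow(V)
  suu <- svv <- suv <- 0
  for (i in seq_len(n1)) for (j in seq_len(n1)) {
    if (i != j) suu <- suu + k(U[i, ], U[j, ])
  }
  for (i in seq_len(n2)) for (j in seq_len(n2)) {
    if (i != j) svv <- svv + k(V[i, ], V[j, ])
  }
  for (i in seq_len(n1)) for (j in seq_len(n2)) suv <- suv + k(U[i, ], V[j, ])
  suu / (n1 * (n1 - 1)) + svv / (n2 * (n2 - 1)) - 2 * suv / (n1 * n2)
}

# central finite differences of f at M, elementwise
finite_diff <- function(f, M, h = 1e-5) {
  G <- M * 0
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      Mp <- M; Mp[i, j] <- M[i, j] + h
      Mm <- M; Mm[i, j] <- M[i, j] - h
      G[i, j] <- (f(Mp) - f(Mm)) / (2 * h)
    }
  }
  G
}

# FOSCTTM by exhaustive enumeration of every cross-modality comparison
foscttm_oracle <- function(U, V) {
  n <- nrow(U)
  dmat <- function(A, B) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
    D
  }
  D <- dmat(U, V)
  fx <- fy <- numeric(n)
  for (i in seq_len(n)) {
    fx[i] <- sum(D[i, -i] < D[i, i]) / (n - 1)
    fy[i] <- sum(D[-i, i] < D[i, i]) / (n - 1)
  }
  (mean(fx) + mean(fy)) / 2
}

rel_diff <- function(a, b) {
  denom <- max(abs(a), abs(b), .Machine$double.eps)
  max(abs(a - b)) / denom
}

random_rotation <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

small_instance <- function(seed = 1, n = 30, px = 5, py = 4, d = 3) {
  set.seed(seed)
  list(X = matrix(rnorm(n * px), n, px),
       Y = matrix(rnorm(n * py), n, py),
       ax = matrix(rnorm(n * d), n, d),
       ay = matrix(rnorm(n * d), n, d))
}
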