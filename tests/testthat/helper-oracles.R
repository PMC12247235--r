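# Independent brute-force oracles: plain-loop recomputations of the WEAT
# quantities, kept deliberately free of the package's vectorized code paths.

oracle_cosine <- function(u, v) {
  num <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  num / (sqrt(nu) * sqrt(nv))
}

oracle_association <- function(w, A, B) {
  sa <- 0
  for (a in A) sa <- sa + oracle_cosine(w, a)
  sb <- 0
  for (b in B) sb <- sb + oracle_cosine(w, b)
  sa / length(A) - sb / length(B)
}

oracle_statistic <- function(X, Y, A, B) {
  s <- 0
  for (x in X) s <- s + oracle_association(x, A, B)
  for (y in Y) s <- s - oracle_association(y, A, B)
  s
}

oracle_effect_size <- function(X, Y, A, B) {
  sX <- vapply(X, oracle_association, numeric(1), A = A, B = B)
  sY <- vapply(Y, oracle_association, numeric(1), A = A, B = B)
  all_s <- c(sX, sY)
  sigma <- sqrt(sum((all_s - mean(all_s))^2) / length(all_s))
  (mean(sX) - mean(sY)) / sigma
}

# exhaustive one-sided permutation p by direct enumeration of all
# choose(2n, n) subsets, recomputing S from scratch for each partition
oracle_perm_p <- function(X, Y, A, B) {
  W <- c(X, Y)
  n <- length(X)
  S_obs <- oracle_statistic(X, Y, A, B)
  subsets <- utils::combn(length(W), n, simplify = FALSE)
  greater <- 0
  for (sub in subsets) {
    Sp <- oracle_statistic(W[sub], W[-sub], A, B)
    if (Sp > S_obs + 1e-12 * max(1, abs(S_obs))) greater <- greater + 1
  }
  greater / length(subsets)
}

# a random weat_inputs-shaped problem as plain lists of vectors
random_instance <- function(n, dim = 10, n_attr = 3) {
  list(X = replicate(n, stats::rnorm(dim), simplify = FALSE),
       Y = replicate(n, stats::rnorm(dim), simplify = FALSE),
       A = replicate(n_attr, stats::rnorm(dim), simplify = FALSE),
       B = replicate(n_attr, stats::rnorm(dim), simplify = FALSE))
}

# random orthogonal matrix via QR with positive-diagonal correction
random_rotation <- function(dim) {
  qr_out <- qr(matrix(stats::rnorm(dim * dim), dim))
  Q <- qr.Q(qr_out)
  Q %*% diag(sign(diag(qr.R(qr_out))))
}

# tiny embedding table covering given tokens with random unit vectors
random_table <- function(tokens, dim = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(length(tokens) * dim), nrow = length(tokens),
              dimnames = list(tokens, NULL))
  embedding_table(m / sqrt(rowSums(m^2)), name = "random")
}
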