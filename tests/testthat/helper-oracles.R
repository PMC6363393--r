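# Independent brute-force oracles used to pin down the tensor primitives
# and update rules.  These deliberately use naive loops / materialized
# matrices and must stay independent of the package internals.

oracle_reconstruct <- function(W, H) {
  d <- dim(W); N <- d[1]; K <- d[2]; L <- d[3]; T <- ncol(H)
  out <- matrix(0, N, T)
  for (n in 1:N) for (t in 1:T) for (k in 1:K) for (l in 0:(L - 1))
    if (t - l >= 1) out[n, t] <- out[n, t] + W[n, k, l + 1] * H[k, t - l]
  out
}

oracle_transconv <- function(W, X) {
  d <- dim(W); N <- d[1]; K <- d[2]; L <- d[3]; T <- ncol(X)
  out <- matrix(0, K, T)
  for (k in 1:K) for (t in 1:T) for (l in 0:(L - 1)) for (n in 1:N)
    if (t + l <= T) out[k, t] <- out[k, t] + W[n, k, l + 1] * X[n, t + l]
  out
}

# materialized T x T smoothing matrix S_ij = 1 iff |i - j| < L
oracle_S <- function(T, L) {
  S <- matrix(0, T, T)
  for (i in 1:T) for (j in 1:T) if (abs(i - j) < L) S[i, j] <- 1
  S
}

oracle_smooth <- function(A, L) A %*% oracle_S(ncol(A), L)

oracle_xortho <- function(W, H, X, L, lam) {
  C <- oracle_transconv(W, X) %*% oracle_S(ncol(X), L) %*% t(H)
  lam * (sum(abs(C)) - sum(abs(diag(C))))
}

oracle_skewness <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  m3 / m2^1.5 * sqrt(n * (n - 1)) / (n - 2)
}

rand_model <- function(N, K, L, T, seed) {
  set.seed(seed)
  factor_model(array(runif(N * K * L), c(N, K, L)),
               matrix(runif(K * T), K, T))
}

rand_X <- function(N, T, seed) {
  set.seed(seed)
  matrix(runif(N * T), N, T)
}

# small shared synthetic fixture, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

small_seq_data <- function(n_sequences = 3, T = 1500, seed = 101) {
  key <- paste(n_sequences, T, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      make_sequences(sequence_spec(n_sequences = n_sequences, T = T,
                                   target_instances_per_seq = round(T / 100),
                                   seed = seed))
  .fixture_cache[[key]]
}
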