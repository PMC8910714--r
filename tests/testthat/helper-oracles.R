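# Independent dense-algebra oracles for the GP equations and random-case
# generators. These deliberately use naive loops, explicit inverses and
# determinants so they share no code path with the package implementation.

oracle_kernel <- function(a, b, h) {
  h$nu * exp(-0.5 * sum(h$omegas * (a - b)^2)) + h$bias
}

oracle_cov <- function(X, h) {
  M <- ncol(X)
  C <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      C[i, j] <- oracle_kernel(X[, i], X[, j], h)
    }
  }
  C + diag(1 / h$beta, M)
}

oracle_lml <- function(h, X, t) {
  C <- oracle_cov(X, h)
  M <- length(t)
  drop(-0.5 * t %*% solve(C) %*% t - 0.5 * log(det(C)) - 0.5 * M * log(2 * pi))
}

oracle_predict <- function(h, X, t, xs, noisy = TRUE) {
  C <- oracle_cov(X, h)
  k <- vapply(seq_len(ncol(X)), function(m) oracle_kernel(X[, m], xs, h),
              numeric(1))
  Ci <- solve(C)
  cc <- oracle_kernel(xs, xs, h) + if (noisy) 1 / h$beta else 0
  list(mean = drop(k %*% Ci %*% t), var = drop(cc - k %*% Ci %*% k))
}

rand_hyper <- function(d) {
  gp_hyper(nu = runif(1, 0.5, 3), omegas = runif(d, 0.3, 3),
           bias = runif(1, 0, 0.5), beta = runif(1, 0.5, 5))
}

rand_instance <- function(M, d) {
  list(h = rand_hyper(d),
       X = matrix(runif(d * M, -2, 2), d, M),
       t = rnorm(M, 0, 2))
}

# small low-rank cohort used across pipeline tests
small_cohort <- function(seed = 1, M = 120, N = 10, rank = 3,
                         noise_sd = 0.01, outliers = FALSE) {
  generate_cohort(cohort_config(
    n_patients = M, n_indicators = N, latent_rank = rank,
    noise_sd = noise_sd, n_constant_like = if (N >= 8) 1L else 0L,
    n_wild = if (outliers) 1L else 0L,
    outlier_rate = if (outliers) 0.05 else 0, seed = seed))
}
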