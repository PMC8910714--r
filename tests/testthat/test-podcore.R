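test_that("snapshot assembly maps patients to columns and validates input", {
  coh <- build_snapshot_matrix(list(c(1, 2, 3), c(4, 5, 6)), c(100, 120))
  expect_equal(dim(coh$U), c(3L, 2L))
  expect_equal(coh$U[, 2], c(4, 5, 6), ignore_attr = TRUE)
  expect_equal(coh$ages_months, c(100, 120))
  expect_equal(coh$indicator_names, c("X01", "X02", "X03"))

  expect_error(build_snapshot_matrix(list(c(1, 2), c(1, 2, 3)), c(1, 2)),
               "ragged")
  bad <- matrix(c(1, NA, 3, 4), 2)
  expect_error(build_snapshot_matrix(bad, c(10, 20)), "row 2.*column 1")
  expect_error(build_snapshot_matrix(matrix(1:4, 2), c(-1, 5)), "positive")
  expect_error(build_snapshot_matrix(matrix(1:4, 2), c(1, 2),
                                     patient_ids = c("a", "a")), "duplicate")

  # study-scale shape contract
  big <- build_snapshot_matrix(matrix(runif(619 * 21), nrow = 619),
                               rep(100, 619))
  expect_equal(dim(big$U), c(21L, 619L))
})

test_that("POD eigenpairs match closed forms on tiny matrices", {
  b <- compute_pod_basis(matrix(c(2, 0, 0, 1), 2))
  expect_equal(b$eigenvalues, c(4, 1))
  expect_equal(b$vectors, diag(2), ignore_attr = TRUE)

  b1 <- compute_pod_basis(matrix(c(1, 2), ncol = 1))
  expect_equal(b1$eigenvalues, c(5, 0), tolerance = 1e-12)
  expect_equal(b1$vectors[, 1], c(1, 2) / sqrt(5), ignore_attr = TRUE)

  expect_error(compute_pod_basis(matrix(c(1, Inf), 1)), "finite")
})

test_that("POD agrees with an independent SVD oracle on random matrices", {
  set.seed(42)
  for (dims in list(c(5, 20), c(21, 200), c(21, 619))) {
    U <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    b <- compute_pod_basis(U)
    sv <- svd(U)
    expect_equal(b$eigenvalues, sv$d^2, tolerance = 1e-8)
    # orthonormality
    expect_lt(max(abs(crossprod(b$vectors) - diag(dims[1]))), 1e-10)
    # same subspaces: columns match left singular vectors up to sign
    expect_equal(abs(b$vectors), abs(sv$u), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # sign convention: largest-|.| component positive
    for (j in seq_len(dims[1])) {
      expect_gt(b$vectors[which.max(abs(b$vectors[, j])), j], 0)
    }
  }
})

test_that("cumulative energy follows the eigenvalue partial sums", {
  b <- compute_pod_basis(matrix(c(2, 0, 0, 1), 2))
  expect_equal(cumulative_energy(b, 1), 80)
  expect_equal(cumulative_energy(b, 2), 100)

  # hand arithmetic on a raw spectrum: 100 * 5/6
  expect_equal(cumulative_energy(c(3, 2, 1), 2), 500 / 6, tolerance = 1e-12)
  expect_equal(cumulative_energy(c(5, 0, 0), 1), 100)

  set.seed(7)
  b <- compute_pod_basis(matrix(rnorm(21 * 50), 21))
  r <- cumulative_energy(b, 1:21)
  expect_true(all(diff(r) >= -1e-12))
  expect_equal(r[21], 100, tolerance = 1e-9)
  expect_true(all(r >= 0 & r <= 100 + 1e-9))
  expect_error(cumulative_energy(b, 22), "k must be")
  expect_error(cumulative_energy(b, 0), "k must be")
})

test_that("truncation keeps the leading modes and preserves eigendata", {
  set.seed(3)
  b <- compute_pod_basis(matrix(rnorm(21 * 60), 21))
  b7 <- truncate_basis(b, 7)
  expect_equal(dim(b7$Omega), c(21L, 7L))
  expect_equal(b7$Omega, b$vectors[, 1:7])
  expect_equal(b7$eigenvalues, b$eigenvalues)
  bN <- truncate_basis(b, 21)
  expect_equal(bN$Omega, b$vectors)
  b1 <- truncate_basis(b, 1)
  expect_equal(ncol(b1$Omega), 1L)
  expect_error(truncate_basis(b, 0), "k must be")
  expect_error(truncate_basis(b, 22), "k must be")
})

test_that("projection and reconstruction obey the subspace identities", {
  set.seed(11)
  U <- matrix(rnorm(6 * 30), 6, 30)
  b <- compute_pod_basis(U)

  # full rank: X = Phi' U recovers U exactly
  X <- pod_project(b, U)
  expect_lt(norm(pod_reconstruct(b, X) - U, "F"), 1e-9)

  # snapshot already in the span of a truncated basis is reproduced
  b3 <- truncate_basis(b, 3)
  u_in <- b3$Omega %*% c(1, -2, 0.5)
  expect_lt(max(abs(pod_reconstruct(b3, pod_project(b3, u_in)) - u_in)), 1e-10)

  # zero amplitudes reconstruct the zero matrix
  expect_equal(pod_reconstruct(b3, matrix(0, 3, 4)), matrix(0, 6, 4))

  # Frobenius error^2 at every k equals the discarded eigenvalue tail
  for (k in 1:6) {
    bk <- truncate_basis(b, k)
    err2 <- norm(U - pod_reconstruct(bk, pod_project(bk, U)), "F")^2
    tail <- sum(b$eigenvalues[-seq_len(k)])
    expect_equal(err2, tail, tolerance = 1e-6 * max(tail, 1e-12))
  }

  expect_error(pod_project(b, matrix(0, 5, 2)), "rows")
  expect_error(pod_reconstruct(b3, matrix(0, 4, 2)), "rows")
})

test_that("truncation level selection scans the energy curve", {
  lam <- read.csv(system.file("extdata", "reference_eigenvalues.csv",
                              package = "podgp"))$eigenvalue
  # independent scan of partial sums
  expected <- which(100 * cumsum(lam) / sum(lam) >= 99.8)[1]
  expect_identical(expected, 5L)
  b <- structure(list(eigenvalues = lam, n_modes = 21L), class = "pod_basis")
  expect_identical(select_truncation_level(b, 99.8), 5L)
  expect_identical(select_truncation_level(b, 100), 21L)

  b2 <- compute_pod_basis(matrix(c(1, 0), 2))
  expect_identical(select_truncation_level(b2, 50), 1L)
  expect_error(select_truncation_level(b, 0), "threshold")
})

test_that("results do not depend on patient column order", {
  set.seed(5)
  U <- matrix(rnorm(8 * 40), 8, 40)
  perm <- sample(40)
  b1 <- compute_pod_basis(U)
  b2 <- compute_pod_basis(U[, perm])
  expect_equal(b1$eigenvalues, b2$eigenvalues, tolerance = 1e-10)
  # no degenerate eigenvalues here, so modes agree after the sign fix
  expect_equal(b1$vectors, b2$vectors, tolerance = 1e-8, ignore_attr = TRUE)
  X1 <- pod_project(b1, U)
  X2 <- pod_project(b2, U[, perm])
  expect_equal(X1[, perm], X2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("optional centering subtracts and restores the mean snapshot", {
  set.seed(9)
  U <- matrix(rnorm(4 * 25, mean = 10), 4, 25)
  b <- compute_pod_basis(U, center = TRUE)
  expect_equal(b$center, rowMeans(U), ignore_attr = TRUE)
  X <- pod_project(b, U)
  expect_lt(norm(pod_reconstruct(b, X) - U, "F"), 1e-9)
  # projection of the mean snapshot itself is ~0 after centering
  expect_lt(max(abs(pod_project(b, matrix(rowMeans(U))))), 1e-10)
})
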