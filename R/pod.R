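#' Proper orthogonal decomposition of a snapshot matrix
#'
#' Eigendecomposes the N x N Gram matrix `D = U %*% t(U)` of the snapshot
#' matrix (N indicators x M patients) to obtain the POD basis: orthonormal
#' modes `Phi` ordered by descending eigenvalue. The eigenvalues of `D`
#' equal the squared singular values of `U`, so the leading modes capture
#' the directions of greatest indicator variation across the cohort.
#'
#' Snapshots are not mean-centred by default; set `center = TRUE` to
#' subtract the mean snapshot before forming `D` (classical PCA-style POD).
#' A deterministic sign convention is applied: each eigenvector is flipped
#' so that its largest-magnitude component is positive, which makes
#' amplitudes reproducible across linear-algebra backends.
#'
#' @param U A `snapshot_cohort` or an N x M numeric matrix (columns =
#'   snapshots).
#' @param center Logical; subtract the mean snapshot before decomposition.
#'   Default `FALSE`.
#'
#' @return An object of class `pod_basis`: list with `eigenvalues`
#'   (length N, descending, tiny negatives clamped to 0), `vectors`
#'   (N x N orthonormal matrix `Phi`), `truncation_level` (initialised to
#'   N), `Omega` (the truncated basis, initially all of `Phi`), `center`
#'   (the subtracted mean snapshot, or `NULL`), and `n_modes`.
#'
#' @seealso [truncate_basis()], [cumulative_energy()], [pod_project()]
#' @examples
#' b <- compute_pod_basis(matrix(c(2, 0, 0, 1), 2))
#' b$eigenvalues  # 4, 1
#' @export
compute_pod_basis <- function(U, center = FALSE) {
  U <- as_snapshot_matrix(U)
  mu <- NULL
  if (isTRUE(center)) {
    mu <- rowMeans(U)
    U <- U - mu
  }
  D <- tcrossprod(U)                     # N x N, symmetric PSD
  e <- eigen(D, symmetric = TRUE)        # eigenvalues already descending
  lam <- e$values
  # clamp round-off negatives; D is PSD by construction
  tol <- 1e-10 * max(lam[1L], .Machine$double.eps)
  lam[lam < tol & lam < 0] <- 0
  lam[lam < 0] <- 0
  Phi <- e$vectors
  # sign convention: largest-|.| component of each mode is positive
  for (j in seq_len(ncol(Phi))) {
    i <- which.max(abs(Phi[, j]))
    if (Phi[i, j] < 0) Phi[, j] <- -Phi[, j]
  }
  rownames(Phi) <- rownames(U)
  structure(
    list(eigenvalues = lam, vectors = Phi,
         truncation_level = nrow(U), Omega = Phi,
         center = mu, n_modes = nrow(U)),
    class = "pod_basis"
  )
}

#' @export
print.pod_basis <- function(x, ...) {
  cat("POD basis: ", x$n_modes, " modes, truncated to ",
      x$truncation_level, "\n", sep = "")
  k <- x$truncation_level
  cat("  retained energy: ",
      format(cumulative_energy(x, k), digits = 6), "%\n", sep = "")
  invisible(x)
}

#' Cumulative eigenvalue energy of the leading POD modes
#'
#' Percentage of the total eigenvalue sum captured by the first `k`
#' modes: `100 * sum(lambda[1:k]) / sum(lambda)`. This is the criterion
#' used to choose how many amplitudes to retain.
#'
#' @param basis A `pod_basis`, or directly a numeric vector of descending
#'   eigenvalues (e.g. a published spectrum).
#' @param k Number of leading modes, `1 <= k <= N`. May be a vector.
#' @return Cumulative energy in percent, in `[0, 100]`; exactly 100 at
#'   `k = N`.
#' @export
cumulative_energy <- function(basis, k) {
  lam <- if (inherits(basis, "pod_basis")) basis$eigenvalues
         else if (is.numeric(basis)) basis
         else stop("basis must be a pod_basis or a numeric eigenvalue vector")
  if (is.unsorted(rev(lam))) stop("eigenvalues must be in descending order")
  if (any(lam < 0)) stop("eigenvalues must be nonnegative")
  N <- length(lam)
  if (any(k < 1L) || any(k > N) || any(k != floor(k))) {
    stop("k must be an integer in [1, ", N, "]")
  }
  total <- sum(lam)
  if (total <= 0) return(rep(100, length(k)))  # degenerate all-zero matrix
  100 * cumsum(lam)[k] / total
}

#' Truncate a POD basis to its leading modes
#'
#' Keeps the `k` leading eigenvectors as the reduced basis `Omega`
#' (N x k). The full eigen-data are preserved so the basis can be
#' re-truncated at any level.
#'
#' @param basis A `pod_basis`.
#' @param k Truncation level, `1 <= k <= N`.
#' @return The `pod_basis` with `truncation_level = k` and `Omega` set to
#'   the first `k` columns of `Phi`.
#' @export
truncate_basis <- function(basis, k) {
  stopifnot(inherits(basis, "pod_basis"))
  if (length(k) != 1L || k < 1L || k > basis$n_modes || k != floor(k)) {
    stop("k must be a single integer in [1, ", basis$n_modes, "]")
  }
  basis$truncation_level <- as.integer(k)
  basis$Omega <- basis$vectors[, seq_len(k), drop = FALSE]
  basis
}

#' Project snapshots onto the truncated POD basis
#'
#' Computes the amplitude matrix `X = t(Omega) %*% snapshots` (k x m): the
#' coordinates of each snapshot in the reduced basis. Works for a single
#' new-patient column as well as whole cohorts. If the basis was centred,
#' the stored mean snapshot is subtracted first.
#'
#' @param basis A `pod_basis`.
#' @param snapshots N x m numeric matrix (or length-N vector) of snapshots.
#' @return k x m amplitude matrix.
#' @export
pod_project <- function(basis, snapshots) {
  stopifnot(inherits(basis, "pod_basis"))
  if (is.null(dim(snapshots))) snapshots <- matrix(snapshots, ncol = 1L)
  snapshots <- as.matrix(snapshots)
  if (nrow(snapshots) != basis$n_modes) {
    stop("snapshots have ", nrow(snapshots), " rows; basis expects ",
         basis$n_modes)
  }
  if (!is.null(basis$center)) snapshots <- snapshots - basis$center
  crossprod(basis$Omega, snapshots)
}

#' Reconstruct snapshots from amplitude vectors
#'
#' Inverse of [pod_project()] on the retained subspace:
#' `Omega %*% amplitudes` (plus the stored mean snapshot if the basis was
#' centred). At full truncation level this recovers the original
#' snapshots exactly; at level k the squared Frobenius reconstruction
#' error over the training set equals the discarded eigenvalue tail
#' `sum(lambda[(k+1):N])`.
#'
#' @param basis A `pod_basis`.
#' @param amplitudes k x m amplitude matrix (or length-k vector).
#' @return N x m matrix of reconstructed snapshots.
#' @export
pod_reconstruct <- function(basis, amplitudes) {
  stopifnot(inherits(basis, "pod_basis"))
  if (is.null(dim(amplitudes))) amplitudes <- matrix(amplitudes, ncol = 1L)
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != basis$truncation_level) {
    stop("amplitudes have ", nrow(amplitudes), " rows; truncation level is ",
         basis$truncation_level)
  }
  out <- basis$Omega %*% amplitudes
  if (!is.null(basis$center)) out <- out + basis$center
  out
}

#' Smallest truncation level reaching an energy threshold
#'
#' Scans the cumulative eigenvalue energy and returns the smallest `k`
#' whose retained energy meets or exceeds `energy_threshold` percent.
#' `k = N` always satisfies 100 percent, so a result always exists.
#'
#' @param basis A `pod_basis`.
#' @param energy_threshold Percent in `(0, 100]`.
#' @return Integer truncation level.
#' @export
select_truncation_level <- function(basis, energy_threshold) {
  stopifnot(inherits(basis, "pod_basis"))
  if (energy_threshold <= 0 || energy_threshold > 100) {
    stop("energy_threshold must be in (0, 100]")
  }
  r <- cumulative_energy(basis, seq_len(basis$n_modes))
  as.integer(which(r >= energy_threshold - 1e-9)[1L])
}
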