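#' Gaussian-process hyperparameters for the ARD squared-exponential kernel
#'
#' The kernel is
#' `k(x, x') = nu * exp(-0.5 * sum_i omega_i * (x_i - x'_i)^2) + b`
#' and observations carry Gaussian noise with precision `beta`, so the
#' covariance of the noisy targets is `C = K + I / beta`. The per-dimension
#' weights `omega_i` are inverse squared length-scales: a large `omega_i`
#' means the output varies quickly along dimension `i` (the dimension is
#' relevant), a small one means the dimension is effectively ignored —
#' this is the automatic relevance determination (ARD) mechanism used for
#' sensitivity ranking.
#'
#' @param nu Vertical scale of the process, `>= 0` (units: squared target).
#' @param omegas Numeric vector of per-dimension weights, all `>= 0`.
#' @param bias Constant kernel offset `b >= 0` (squared-target units).
#' @param beta Noise precision `> 0`; the noise variance is `1 / beta`.
#' @return An object of class `gp_hyper`.
#' @export
gp_hyper <- function(nu, omegas, bias, beta) {
  omegas <- as.numeric(omegas)
  if (length(nu) != 1L || !is.finite(nu) || nu < 0) stop("nu must be a single finite value >= 0")
  if (any(!is.finite(omegas)) || any(omegas < 0)) stop("omegas must be finite and >= 0")
  if (length(bias) != 1L || !is.finite(bias) || bias < 0) stop("bias must be a single finite value >= 0")
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) stop("beta must be a single finite value > 0")
  structure(list(nu = as.numeric(nu), omegas = omegas,
                 bias = as.numeric(bias), beta = as.numeric(beta)),
            class = "gp_hyper")
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat("GP hyperparameters (ARD squared-exponential + bias):\n")
  cat("  nu   =", format(x$nu, digits = 5),
      " bias =", format(x$bias, digits = 5),
      " noise var (1/beta) =", format(1 / x$beta, digits = 5), "\n")
  cat("  omegas:", paste(format(x$omegas, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate the ARD squared-exponential kernel for one pair of inputs
#'
#' @param x,x2 Numeric vectors of equal length (the input dimension).
#' @param hyper A [gp_hyper()] object with `omegas` of matching length.
#' @return Kernel value, in `[bias, nu + bias]`.
#' @export
gp_kernel <- function(x, x2, hyper) {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (length(x) != length(x2)) stop("x and x2 have different lengths")
  if (length(x) != length(hyper$omegas)) {
    stop("input dimension ", length(x), " does not match length of omegas (",
         length(hyper$omegas), ")")
  }
  hyper$nu * exp(-0.5 * sum(hyper$omegas * (x - x2)^2)) + hyper$bias
}

# Kernel matrix between the columns of X1 (d x m1) and X2 (d x m2).
kernel_matrix <- function(X1, X2, hyper) {
  w <- sqrt(hyper$omegas)
  A <- X1 * w
  B <- X2 * w
  S <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
  S[S < 0] <- 0
  hyper$nu * exp(-0.5 * S) + hyper$bias
}

#' Covariance matrix of the noisy training targets
#'
#' `C = K + I / beta` where `K` is the ARD squared-exponential kernel
#' matrix of the training inputs. The diagonal entries are
#' `nu + bias + 1/beta`.
#'
#' @param X d x M numeric matrix of inputs, one column per training point.
#' @param hyper A [gp_hyper()] with `omegas` of length d.
#' @return M x M symmetric covariance matrix (no jitter added; jitter is an
#'   internal device of the Cholesky factorization).
#' @export
gp_covariance <- function(X, hyper) {
  X <- as_input_matrix(X, hyper)
  K <- kernel_matrix(X, X, hyper)
  K + diag(1 / hyper$beta, ncol(X))
}

as_input_matrix <- function(X, hyper = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = length(X))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("inputs contain non-finite values")
  if (!is.null(hyper) && nrow(X) != length(hyper$omegas)) {
    stop("input dimension ", nrow(X), " does not match length of omegas (",
         length(hyper$omegas), ")")
  }
  X
}

# Cholesky with escalating diagonal jitter. Returns list(L = upper factor,
# jitter). Starts at 1e-10 * mean diagonal, escalates x10 up to 1e-4 * mean.
chol_jitter <- function(C) {
  mdiag <- mean(diag(C))
  R <- tryCatch(chol(C), error = function(e) NULL)
  jit <- 0
  if (is.null(R)) {
    jit <- 1e-10 * mdiag
    while (jit <= 1e-4 * mdiag) {
      R <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
      if (!is.null(R)) break
      jit <- jit * 10
    }
  }
  if (is.null(R)) {
    stop("covariance matrix is not positive definite even after jitter up to ",
         format(1e-4 * mdiag), " (mean diagonal ", format(mdiag), ")")
  }
  list(R = R, jitter = jit)
}

#' Log marginal likelihood of the targets under the GP prior
#'
#' Computes `-0.5 * t' C^-1 t - 0.5 * log|C| - (M/2) * log(2*pi)` with
#' `C = K + I/beta`, via a Cholesky factorization (log-determinant as twice
#' the log-diagonal sum of the factor). This is the objective maximized
#' during hyperparameter training.
#'
#' @param hyper A [gp_hyper()].
#' @param X d x M input matrix (columns = points).
#' @param t Numeric target vector of length M.
#' @return The log marginal likelihood (a finite scalar).
#' @export
gp_log_marginal_likelihood <- function(hyper, X, t) {
  X <- as_input_matrix(X, hyper)
  M <- ncol(X)
  if (length(t) != M) stop("length of t does not match number of input columns")
  C <- gp_covariance(X, hyper)
  ch <- chol_jitter(C)
  a <- backsolve(ch$R, backsolve(ch$R, t, transpose = TRUE))
  -0.5 * sum(t * a) - sum(log(diag(ch$R))) - 0.5 * M * log(2 * pi)
}

# Build a gp_model from data and fixed hyperparameters: factorizes C and
# caches alpha = C^-1 (t - t_center). t_center is the constant mean added
# back at prediction time (0 = no centering).
gp_fit <- function(X, t, hyper, t_center = 0) {
  stopifnot(inherits(hyper, "gp_hyper"))
  X <- as_input_matrix(X, hyper)
  M <- ncol(X)
  if (length(t) != M) stop("length of t does not match number of input columns")
  t <- as.numeric(t)
  C <- gp_covariance(X, hyper)
  ch <- chol_jitter(C)
  tc <- t - t_center
  alpha <- backsolve(ch$R, backsolve(ch$R, tc, transpose = TRUE))
  lml <- -0.5 * sum(tc * alpha) - sum(log(diag(ch$R))) - 0.5 * M * log(2 * pi)
  structure(
    list(hyper = hyper, X = X, t = t, t_center = t_center,
         chol_C = ch$R, jitter = ch$jitter, alpha = alpha,
         log_marginal_likelihood = lml, optimizer_report = NULL),
    class = "gp_model"
  )
}

#' @export
print.gp_model <- function(x, ...) {
  cat("GP regression model: ", nrow(x$X), "-dimensional inputs, ",
      ncol(x$X), " training points\n", sep = "")
  cat("  log marginal likelihood:", format(x$log_marginal_likelihood, digits = 8), "\n")
  if (!is.null(x$optimizer_report)) {
    r <- x$optimizer_report
    cat("  training: ", r$n_restarts, " restart(s), best restart ",
        r$best_restart, ", converged: ", r$converged, "\n", sep = "")
  }
  invisible(x)
}

# Default initialization of the hyperparameters from the data: nu and bias
# from the target variance, omegas from median squared pairwise distances
# per dimension (1 for zero-variance dimensions).
gp_init_hyper <- function(X, t) {
  vt <- stats::var(t)
  if (!is.finite(vt) || vt <= 0) vt <- 1
  d <- nrow(X)
  om <- vapply(seq_len(d), function(i) {
    xi <- X[i, ]
    dd <- as.numeric(stats::dist(xi))^2
    m <- stats::median(dd)
    if (!is.finite(m) || m <= 0) 1 else 1 / m
  }, numeric(1))
  gp_hyper(nu = vt, omegas = om, bias = 0.01 * vt, beta = 1 / (0.1 * vt))
}

# negative log marginal likelihood and its gradient in log-parameter space
# theta = c(log nu, log omegas, log(bias + eps), log beta); Dsq is the list
# of per-dimension squared-difference matrices.
make_nll <- function(Dsq, t, M, d, eps = 1e-12) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evaluate <- function(theta) {
    nu <- exp(theta[1L])
    om <- exp(theta[2L:(d + 1L)])
    b <- max(exp(theta[d + 2L]) - eps, 0)
    beta <- exp(theta[d + 3L])
    S <- matrix(0, M, M)
    for (i in seq_len(d)) S <- S + om[i] * Dsq[[i]]
    E <- nu * exp(-0.5 * S)
    C <- E + b + diag(1 / beta, M)
    ch <- tryCatch(chol_jitter(C), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, d + 3L)))
    R <- ch$R
    alpha <- backsolve(R, backsolve(R, t, transpose = TRUE))
    nll <- 0.5 * sum(t * alpha) + sum(log(diag(R))) + 0.5 * M * log(2 * pi)
    Cinv <- chol2inv(R)
    W <- tcrossprod(alpha) - Cinv      # d lml / d theta_j = 0.5 tr(W dC/dtheta_j)
    g <- numeric(d + 3L)
    g[1L] <- 0.5 * sum(W * E)
    for (i in seq_len(d)) {
      g[1L + i] <- 0.5 * sum(W * (E * (-0.5 * om[i] * Dsq[[i]])))
    }
    g[d + 2L] <- 0.5 * sum(W) * (b + eps)
    g[d + 3L] <- -0.5 * sum(diag(W)) / beta
    list(value = nll, grad = -g)
  }
  fn <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      cache$res <- evaluate(theta)
      cache$theta <- theta
    }
    cache$res$value
  }
  gr <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      cache$res <- evaluate(theta)
      cache$theta <- theta
    }
    cache$res$grad
  }
  list(fn = fn, gr = gr)
}

#' Train a Gaussian process by marginal-likelihood maximization
#'
#' Maximizes the log marginal likelihood over the kernel hyperparameters
#' `(nu, omega_1..d, bias, beta)` with a quasi-Newton optimizer (L-BFGS-B)
#' in log-parameter space (which enforces positivity), using analytic
#' gradients. Several restarts are run from a data-driven initialization
#' plus seeded Gaussian perturbations of the log-parameters; the restart
#' with the highest marginal likelihood wins.
#'
#' By default the targets are centred by their mean during training and the
#' mean is added back at prediction time; this is transparent to the
#' caller (the model stores and reports raw-month targets).
#'
#' @param X d x M numeric matrix of training inputs (columns = points),
#'   e.g. truncated POD amplitude vectors.
#' @param t Numeric vector of M training targets (age in months).
#' @param n_restarts Number of optimizer restarts (default 5).
#' @param max_iter Maximum optimizer iterations per restart (default 500).
#' @param tol Convergence tolerance on the objective change (default 1e-6).
#' @param seed Integer seed for the restart perturbations; `NULL` leaves
#'   the RNG state alone.
#' @param center Centre targets by their mean during training (default
#'   `TRUE`).
#' @param init Optional [gp_hyper()] overriding the data-driven
#'   initialization of the first restart.
#' @return A `gp_model`: the fitted hyperparameters, cached Cholesky
#'   factor and `alpha = C^-1 (t - mean)`, the log marginal likelihood at
#'   the optimum, and an `optimizer_report` (restarts, convergence codes,
#'   iteration counts).
#' @export
train_gp <- function(X, t, n_restarts = 5, max_iter = 500, tol = 1e-6,
                     seed = NULL, center = TRUE, init = NULL) {
  X <- as_input_matrix(X)
  M <- ncol(X)
  d <- nrow(X)
  if (M < 2L) stop("need at least 2 training points")
  if (length(t) != M) stop("length of t does not match number of input columns")
  t <- as.numeric(t)
  t_center <- if (isTRUE(center)) mean(t) else 0
  tc <- t - t_center

  h0 <- if (is.null(init)) gp_init_hyper(X, tc) else init
  eps <- 1e-12
  theta0 <- c(log(h0$nu), log(pmax(h0$omegas, 1e-300)),
              log(h0$bias + eps), log(h0$beta))

  Dsq <- lapply(seq_len(d), function(i) outer(X[i, ], X[i, ], "-")^2)
  obj <- make_nll(Dsq, tc, M, d, eps)

  perturb <- matrix(0, d + 3L, n_restarts)
  if (n_restarts > 1L) {
    perturb[, -1L] <- with_local_seed(seed, {
      matrix(stats::rnorm((d + 3L) * (n_restarts - 1L)), d + 3L)
    })
  }

  best <- NULL
  codes <- integer(n_restarts)
  iters <- integer(n_restarts)
  fails <- character(0)
  # stop on a small projected gradient; the objective-change criterion is
  # kept far tighter than the gradient one so it does not fire first
  factr <- max(tol * 1e9, 10)
  pgtol <- max(10 * tol, 1e-8)
  for (r in seq_len(n_restarts)) {
    th <- theta0 + perturb[, r]
    fit <- tryCatch(
      stats::optim(th, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                   lower = rep(-25, d + 3L), upper = rep(25, d + 3L),
                   control = list(maxit = max_iter, factr = factr,
                                  pgtol = pgtol)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
      codes[r] <- NA_integer_
      next
    }
    codes[r] <- fit$convergence
    iters[r] <- fit$counts[1L]
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_r <- r
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restart(s) failed: ",
         paste(unique(fails), collapse = "; "))
  }

  th <- best$par
  hyper <- gp_hyper(nu = exp(th[1L]), omegas = exp(th[2L:(d + 1L)]),
                    bias = max(exp(th[d + 2L]) - eps, 0), beta = exp(th[d + 3L]))
  model <- gp_fit(X, t, hyper, t_center = t_center)
  model$optimizer_report <- list(
    n_restarts = n_restarts, best_restart = best_r,
    convergence_codes = codes, iterations = iters,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    failed_restarts = fails, seed = seed,
    max_iter = max_iter, tol = tol
  )
  model
}

#' Predict age for new amplitude vectors
#'
#' Gaussian-process posterior prediction: mean `k' C^-1 t` and variance
#' `c - k' C^-1 k` for each query column, where `k` is the kernel vector
#' between the query and the training inputs. With `type = "noisy"`
#' (default) `c = k(x*, x*) + 1/beta`, the predictive variance of a new
#' noisy observation; with `type = "latent"` `c = k(x*, x*)`, the variance
#' of the noise-free latent function.
#'
#' @param model A `gp_model` from [train_gp()] or `gp_fit`-style
#'   construction.
#' @param x_star d-vector or d x m matrix of query inputs (columns =
#'   patients).
#' @param type `"noisy"` (default) or `"latent"` predictive variance.
#' @return A data frame of class `age_prediction` with columns
#'   `mean_months`, `std_months`, `variance_months2`, one row per query
#'   column. Round-off negatives in the variance are clamped to zero with
#'   a warning.
#' @export
gp_predict <- function(model, x_star, type = c("noisy", "latent")) {
  stopifnot(inherits(model, "gp_model"))
  type <- match.arg(type)
  Xs <- as_input_matrix(x_star, model$hyper)
  h <- model$hyper
  Ks <- kernel_matrix(model$X, Xs, h)          # M x m
  mu <- model$t_center + drop(crossprod(Ks, model$alpha))
  v <- backsolve(model$chol_C, Ks, transpose = TRUE)
  c0 <- h$nu + h$bias + if (type == "noisy") 1 / h$beta else 0
  var <- c0 - colSums(v^2)
  if (any(var < 0)) {
    if (any(var < -1e-8 * c0)) {
      warning("negative predictive variance clamped to zero (round-off)")
    }
    var[var < 0] <- 0
  }
  structure(
    data.frame(mean_months = mu, std_months = sqrt(var),
               variance_months2 = var),
    class = c("age_prediction", "data.frame")
  )
}

#' ARD sensitivity ranking of the input dimensions
#'
#' Ranks the input dimensions of a trained GP by their fitted ARD weight
#' `omega_i` (inverse squared length-scale). Large weights mark the
#' dimensions the model's output is most sensitive to; near-zero weights
#' mark inputs the model effectively ignores.
#'
#' @param model A trained `gp_model`.
#' @param names Optional character labels for the input dimensions.
#' @return A data frame sorted by descending `omega`: columns `dimension`
#'   (original index), `name`, `omega` (raw weight), `omega_rel`
#'   (normalized to the maximum).
#' @export
gp_sensitivity <- function(model, names = NULL) {
  stopifnot(inherits(model, "gp_model"))
  om <- model$hyper$omegas
  d <- length(om)
  if (is.null(names)) names <- paste0("dim", seq_len(d))
  ord <- order(om, decreasing = TRUE)
  mx <- max(om)
  data.frame(dimension = ord, name = names[ord], omega = om[ord],
             omega_rel = if (mx > 0) om[ord] / mx else rep(0, d),
             row.names = NULL)
}

#' Penalized least-squares (ridge) baseline over fixed basis functions
#'
#' The weight-space counterpart of the GP: a linear model
#' `y(x) = sum_j w_j phi_j(x)` fitted by ridge-regularized least squares,
#' `w = (Theta' Theta + alpha I)^-1 Theta' t`, where `Theta` is the design
#' matrix with rows `phi(x_m)`.
#'
#' @param X d x M matrix of inputs (columns = points).
#' @param t Length-M target vector.
#' @param basis Basis functions: `"linear"` (`phi(x) = x`), `"affine"`
#'   (intercept plus `x`), or a function mapping a d-vector to a numeric
#'   feature vector.
#' @param alpha Ridge regularization `>= 0`.
#' @return A `pls_model` with `weights`, `alpha`, the basis descriptor and
#'   the design matrix. Predict with [predict.pls_model()].
#' @export
fit_penalized_least_squares <- function(X, t, basis = "linear", alpha = 0) {
  X <- as_input_matrix(X)
  M <- ncol(X)
  if (length(t) != M) stop("length of t does not match number of input columns")
  if (alpha < 0) stop("alpha must be >= 0")
  bfn <- pls_basis_fn(basis)
  Theta <- t(apply(X, 2L, bfn))
  if (nrow(Theta) != M) Theta <- matrix(Theta, nrow = M)  # 1-feature case
  J <- ncol(Theta)
  A <- crossprod(Theta) + diag(alpha, J)
  w <- tryCatch(solve(A, crossprod(Theta, t)),
                error = function(e) {
                  stop("normal equations are singular; use alpha > 0 ",
                       "(regularization) for rank-deficient designs")
                })
  structure(list(weights = drop(w), alpha = alpha, basis = basis,
                 design_matrix = Theta),
            class = "pls_model")
}

pls_basis_fn <- function(basis) {
  if (is.function(basis)) return(basis)
  switch(basis,
         linear = function(x) as.numeric(x),
         affine = function(x) c(1, as.numeric(x)),
         stop("unknown basis descriptor: ", basis))
}

#' Predict from a penalized least-squares baseline model
#'
#' @param object A `pls_model`.
#' @param x_star d-vector or d x m matrix of query inputs.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, x_star, ...) {
  if (is.null(dim(x_star))) x_star <- matrix(x_star, ncol = 1L)
  bfn <- pls_basis_fn(object$basis)
  Theta <- t(apply(x_star, 2L, bfn))
  if (nrow(Theta) != ncol(x_star)) Theta <- matrix(Theta, nrow = ncol(x_star))
  drop(Theta %*% object$weights)
}
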