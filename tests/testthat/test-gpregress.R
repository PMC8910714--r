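test_that("kernel matches hand evaluations and is bounded and symmetric", {
  h <- gp_hyper(nu = 2, omegas = 1, bias = 0.5, beta = 1)
  expect_equal(gp_kernel(0, 0, h), 2.5)                 # zero distance: nu + b
  expect_equal(gp_kernel(0, 2, h), 2 * exp(-2) + 0.5)   # hand evaluation
  h0 <- gp_hyper(nu = 0, omegas = c(1, 2), bias = 0.3, beta = 1)
  expect_equal(gp_kernel(c(1, 4), c(-2, 0), h0), 0.3)   # nu = 0 collapses to b

  set.seed(1)
  h <- rand_hyper(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    v <- gp_kernel(a, b, h)
    expect_equal(v, gp_kernel(b, a, h))
    expect_gte(v, h$bias)
    expect_lte(v, h$nu + h$bias + 1e-12)
  }
  expect_error(gp_kernel(c(1, 2), c(1, 2, 3), h), "length")
  expect_error(gp_hyper(1, c(1, -1), 0, 1), "omegas")
  expect_error(gp_hyper(1, 1, 0, 0), "beta")
})

test_that("covariance matrix matches the elementwise kernel oracle", {
  h <- gp_hyper(nu = 1.5, omegas = c(1, 0.5), bias = 0.2, beta = 4)
  C1 <- gp_covariance(matrix(c(0.3, -1), 2, 1), h)
  expect_equal(C1, matrix(1.5 + 0.2 + 0.25), ignore_attr = TRUE)

  # duplicated points: noise separates the diagonal
  Xd <- matrix(c(1, 2, 1, 2), 2, 2)
  Cd <- gp_covariance(Xd, h)
  expect_equal(Cd[1, 2], 1.7)
  expect_equal(Cd[1, 1], 1.7 + 0.25)

  set.seed(2)
  inst <- rand_instance(10, 3)
  C <- gp_covariance(inst$X, inst$h)
  expect_equal(C, oracle_cov(inst$X, inst$h), tolerance = 1e-12)
  expect_equal(C, t(C))
})

test_that("log marginal likelihood matches closed form and dense oracle", {
  h <- gp_hyper(nu = 2, omegas = 1, bias = 0.5, beta = 2)
  cc <- 2 + 0.5 + 0.5
  t1 <- 1.7
  expect_equal(gp_log_marginal_likelihood(h, matrix(0.4), t1),
               -0.5 * log(2 * pi * cc) - t1^2 / (2 * cc))

  set.seed(3)
  inst <- rand_instance(5, 2)
  expect_equal(gp_log_marginal_likelihood(inst$h, inst$X, inst$t),
               oracle_lml(inst$h, inst$X, inst$t), tolerance = 1e-8)

  # zero targets: only the normalization terms remain
  z <- rep(0, 5)
  C <- oracle_cov(inst$X, inst$h)
  expect_equal(gp_log_marginal_likelihood(inst$h, inst$X, z),
               -0.5 * log(det(C)) - 2.5 * log(2 * pi), tolerance = 1e-8)
})

test_that("predictions match scalar algebra and the dense oracle", {
  h <- gp_hyper(nu = 1.2, omegas = 0.8, bias = 0.1, beta = 3)
  m1 <- podgp:::gp_fit(matrix(0.5), 2.4, h)
  p <- gp_predict(m1, 1.1)
  kk <- gp_kernel(0.5, 1.1, h)
  expect_equal(p$mean_months, kk * 2.4 / (1.2 + 0.1 + 1 / 3))

  # far query with b = 0: mean -> 0, noisy variance -> nu + 1/beta
  hb0 <- gp_hyper(nu = 1.2, omegas = 0.8, bias = 0, beta = 3)
  mfar <- podgp:::gp_fit(matrix(0.5), 2.4, hb0)
  pfar <- gp_predict(mfar, 1e4)
  expect_equal(pfar$mean_months, 0, tolerance = 1e-12)
  expect_equal(pfar$variance_months2, 1.2 + 1 / 3, tolerance = 1e-10)

  set.seed(4)
  inst <- rand_instance(8, 3)
  m <- podgp:::gp_fit(inst$X, inst$t, inst$h)
  for (noisy in c(TRUE, FALSE)) {
    xs <- runif(3, -2, 2)
    o <- oracle_predict(inst$h, inst$X, inst$t, xs, noisy = noisy)
    p <- gp_predict(m, xs, type = if (noisy) "noisy" else "latent")
    expect_equal(p$mean_months, o$mean, tolerance = 1e-8)
    expect_equal(p$variance_months2, o$var, tolerance = 1e-8)
    expect_equal(p$std_months, sqrt(p$variance_months2))
  }
  expect_error(gp_predict(m, c(1, 2)), "dimension")
})

test_that("predictive variance is nonnegative and bounded by the prior", {
  set.seed(5)
  inst <- rand_instance(30, 2)
  m <- podgp:::gp_fit(inst$X, inst$t, inst$h)
  p <- gp_predict(m, matrix(runif(2 * 50, -3, 3), 2))
  top <- inst$h$nu + inst$h$bias + 1 / inst$h$beta
  expect_true(all(p$variance_months2 >= 0))
  expect_true(all(p$variance_months2 <= top + 1e-10))
})

test_that("noise-free limit interpolates the training targets", {
  set.seed(6)
  X <- matrix(runif(20, -1, 1), 1)
  t <- sin(3 * X[1, ])
  dev <- vapply(c(1e2, 1e4, 1e6), function(beta) {
    h <- gp_hyper(nu = 1, omegas = 5, bias = 0.1, beta = beta)
    m <- podgp:::gp_fit(X, t, h)
    max(abs(gp_predict(m, X)$mean_months - t))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-3)
})

test_that("training improves on its initialization and reaches a flat point", {
  tb <- generate_gp_testbed(60, 2, gp_hyper(2, c(3, 0.5), 0.1, 5), seed = 8)
  m <- train_gp(tb$X, tb$t, n_restarts = 3, seed = 1, center = FALSE)
  init <- podgp:::gp_init_hyper(tb$X, tb$t)
  expect_gte(m$log_marginal_likelihood,
             gp_log_marginal_likelihood(init, tb$X, tb$t))
  expect_equal(m$optimizer_report$n_restarts, 3)

  # finite-difference gradient of the objective in log space is ~0 at the
  # returned optimum (coordinates away from the optimizer box bounds)
  h <- m$hyper
  th <- c(log(h$nu), log(h$omegas), log(h$bias + 1e-12), log(h$beta))
  f <- function(v) {
    hh <- gp_hyper(exp(v[1]), exp(v[2:3]), max(exp(v[4]) - 1e-12, 0), exp(v[5]))
    gp_log_marginal_likelihood(hh, tb$X, tb$t)
  }
  eps <- 1e-5
  for (j in seq_along(th)) {
    if (abs(th[j]) > 24.5) next
    e <- rep(0, 5); e[j] <- eps
    g <- (f(th + e) - f(th - e)) / (2 * eps)
    expect_lt(abs(g), 1e-3)
  }
})

test_that("training is deterministic and insensitive to point order", {
  tb <- generate_gp_testbed(40, 2, gp_hyper(1, c(2, 1), 0.1, 4), seed = 3)
  m1 <- train_gp(tb$X, tb$t, n_restarts = 2, seed = 7)
  m2 <- train_gp(tb$X, tb$t, n_restarts = 2, seed = 7)
  expect_identical(m1$hyper, m2$hyper)

  perm <- sample(40)
  m3 <- train_gp(tb$X[, perm], tb$t[perm], n_restarts = 2, seed = 7)
  xs <- matrix(runif(2 * 5, -1, 1), 2)
  expect_equal(gp_predict(m1, xs)$mean_months,
               gp_predict(m3, xs)$mean_months, tolerance = 1e-6)
})

test_that("recovered optimum is no worse than the generating truth", {
  truth <- gp_hyper(2, c(4, 0.5, 0.05), 0.1, 10)
  tb <- generate_gp_testbed(150, 3, truth, seed = 21)
  m <- train_gp(tb$X, tb$t, n_restarts = 3, seed = 2, center = FALSE)
  expect_gte(m$log_marginal_likelihood + 1e-6,
             gp_log_marginal_likelihood(truth, tb$X, tb$t))
})

test_that("ARD sensitivity ranks planted relevance above noise", {
  set.seed(31)
  X <- rbind(runif(120, -1, 1), runif(120, -1, 1), rep(0.7, 120))
  t <- sin(2.5 * X[1, ]) + rnorm(120, 0, 0.05)   # dim 1 drives, 2 is noise,
  m <- train_gp(X, t, n_restarts = 2, seed = 4)  # 3 is constant
  sens <- gp_sensitivity(m, names = c("driver", "noise", "flat"))
  expect_identical(sens$name[1], "driver")
  expect_equal(sens$omega_rel[1], 1)
  om <- m$hyper$omegas
  expect_gt(om[1], om[2])
  expect_lte(om[3], om[1])

  m1 <- train_gp(X[1, , drop = FALSE], t, n_restarts = 1, seed = 4)
  expect_equal(nrow(gp_sensitivity(m1)), 1L)
})

test_that("penalized least squares solves the regularized normal equations", {
  # square invertible design at alpha = 0 interpolates exactly
  X <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  t <- c(2, -1, 4)
  m <- fit_penalized_least_squares(X, t, basis = "linear", alpha = 0)
  expect_equal(predict(m, X), t, tolerance = 1e-10)

  # heavy ridge shrinks the weights toward zero
  set.seed(8)
  X <- matrix(runif(40, -1, 1), 2)
  t <- rnorm(20)
  m_big <- fit_penalized_least_squares(X, t, alpha = 1e8)
  expect_lt(max(abs(m_big$weights)), 1e-5)

  # rank-deficient design without regularization is rejected with advice
  Xdef <- rbind(1:5, 2 * (1:5))
  expect_error(fit_penalized_least_squares(Xdef, rnorm(5), alpha = 0),
               "alpha > 0")
})

test_that("ridge and its function-space (GP) dual give the same predictions", {
  set.seed(9)
  X <- matrix(runif(30, -1, 1), 2)
  t <- rnorm(15)
  alpha <- 0.7
  m <- fit_penalized_least_squares(X, t, basis = "linear", alpha = alpha)
  # dual form: y(x*) = x*' Theta' (Theta Theta' + alpha I)^-1 t
  Theta <- t(X)
  xs <- matrix(runif(6, -1, 1), 2)
  dual <- t(xs) %*% t(Theta) %*% solve(Theta %*% t(Theta) + alpha * diag(15), t)
  expect_equal(predict(m, xs), drop(dual), tolerance = 1e-6)
})
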