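#' Min-max normalization of indicators fitted on the training split
#'
#' Scales each indicator (row of the snapshot matrix) to `[0, 1]` using the
#' minimum and range observed on the *training* columns only; any other
#' matrix is transformed with the same parameters, so its values may fall
#' outside `[0, 1]` (extrapolation is permitted). A zero-range indicator is
#' mapped to 0 with a warning.
#'
#' @param U_train N x M_train training snapshot matrix.
#' @param U_other Optional N x m matrix transformed with the training
#'   parameters.
#' @return List with `train`, `other` (or `NULL`), and `params`
#'   (`min`, `range` per indicator).
#' @export
normalize_indicators <- function(U_train, U_other = NULL) {
  U_train <- as_snapshot_matrix(U_train)
  mins <- apply(U_train, 1L, min)
  rng <- apply(U_train, 1L, max) - mins
  if (any(rng == 0)) {
    warning("zero-range indicator(s) ",
            paste(which(rng == 0), collapse = ", "),
            " mapped to 0")
  }
  params <- list(min = mins, range = rng)
  out <- list(train = apply_normalization(U_train, params),
              other = if (!is.null(U_other)) {
                apply_normalization(as_snapshot_matrix(U_other), params)
              },
              params = params)
  out
}

apply_normalization <- function(U, params) {
  safe_rng <- ifelse(params$range == 0, 1, params$range)
  V <- (U - params$min) / safe_rng
  V[params$range == 0, ] <- 0
  V
}

#' Seeded random train/test split
#'
#' Draws `round(M * test_fraction)` test indices uniformly without
#' replacement; the remainder trains the model. Reproducible from the
#' seed. Rounding (rather than truncation) makes complementary fractions
#' complementary in size: with M = 619, fraction 1/18 yields 34 test
#' patients and fraction 17/18 yields the complementary 585.
#'
#' @param M Number of patients.
#' @param test_fraction Fraction in `(0, 1)` assigned to the test set.
#' @param seed Integer seed.
#' @return List of class `split_spec`: `train_indices`, `test_indices`
#'   (sorted, disjoint, covering `1:M`), `test_fraction`, `seed`, `M`.
#' @export
split_data <- function(M, test_fraction, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  n_test <- round(M * test_fraction)
  if (n_test < 1L) stop("test_fraction yields an empty test set")
  if (n_test >= M) stop("test_fraction yields an empty training set")
  test <- with_local_seed(seed, sort(sample.int(M, n_test)))
  structure(list(train_indices = setdiff(seq_len(M), test),
                 test_indices = test,
                 test_fraction = test_fraction, seed = seed, M = M),
            class = "split_spec")
}

#' Default configuration for metamodel training
#'
#' @param normalize Min-max normalize indicators before POD (default
#'   `FALSE`: raw indicators enter the decomposition).
#' @param center_pod Mean-centre snapshots before POD (default `FALSE`).
#' @param n_restarts,max_iter,tol GP optimizer settings (see [train_gp()]).
#' @param seed Base seed for GP training (sweeps derive per-level seeds
#'   from it).
#' @param variance_type `"noisy"` (default) or `"latent"` predictive
#'   variance (see [gp_predict()]).
#' @return List of class `metamodel_config`.
#' @export
metamodel_config <- function(normalize = FALSE, center_pod = FALSE,
                             n_restarts = 5, max_iter = 500, tol = 1e-6,
                             seed = 1, variance_type = "noisy") {
  structure(list(normalize = isTRUE(normalize),
                 center_pod = isTRUE(center_pod),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 tol = as.numeric(tol), seed = as.integer(seed),
                 variance_type = match.arg(variance_type,
                                           c("noisy", "latent"))),
            class = "metamodel_config")
}

#' Train the POD-GP metamodel on one train/test split
#'
#' Fits the whole surrogate on the training columns only — optional
#' min-max normalization, POD basis, truncation to `k` modes, GP
#' regression of age on the truncated amplitudes — then evaluates SMAE,
#' MAE and R-squared on both splits. No statistic of the test columns
#' leaks into normalization or the basis.
#'
#' @param cohort A `snapshot_cohort` ([build_snapshot_matrix()] /
#'   [read_cohort()]).
#' @param split A [split_data()] result for the cohort's M patients.
#' @param k Truncation level (number of retained POD amplitudes).
#' @param config A [metamodel_config()].
#' @return List with `metamodel` (class `podgp_metamodel`),
#'   `train_metrics`, `test_metrics` (each a [metrics_report()]).
#' @export
train_metamodel <- function(cohort, split, k, config = metamodel_config()) {
  stopifnot(inherits(cohort, "snapshot_cohort"),
            inherits(split, "split_spec"))
  if (split$M != cohort$n_patients) stop("split does not match cohort size")
  if (k > cohort$n_indicators) {
    stop("k exceeds the number of indicators (", cohort$n_indicators, ")")
  }
  U <- cohort$U
  t <- cohort$ages_months
  tr <- split$train_indices
  te <- split$test_indices

  norm_params <- NULL
  U_train <- U[, tr, drop = FALSE]
  U_test <- U[, te, drop = FALSE]
  if (config$normalize) {
    nz <- normalize_indicators(U_train, U_test)
    U_train <- nz$train
    U_test <- nz$other
    norm_params <- nz$params
  }

  basis <- compute_pod_basis(U_train, center = config$center_pod)
  basis <- truncate_basis(basis, k)
  X_train <- pod_project(basis, U_train)
  X_test <- pod_project(basis, U_test)

  gp <- train_gp(X_train, t[tr], n_restarts = config$n_restarts,
                 max_iter = config$max_iter, tol = config$tol,
                 seed = config$seed)

  pred_tr <- gp_predict(gp, X_train, type = config$variance_type)
  pred_te <- gp_predict(gp, X_test, type = config$variance_type)

  metamodel <- structure(
    list(normalization = norm_params, pod_basis = basis, gp_model = gp,
         truncation_level = as.integer(k),
         indicator_names = cohort$indicator_names,
         config = config, split_seed = split$seed),
    class = "podgp_metamodel"
  )
  list(metamodel = metamodel,
       train_metrics = metrics_report(t[tr], pred_tr$mean_months),
       test_metrics = metrics_report(t[te], pred_te$mean_months))
}

#' @export
print.podgp_metamodel <- function(x, ...) {
  cat("POD-GP metamodel: ", length(x$indicator_names), " indicators -> ",
      x$truncation_level, " amplitudes -> age (months)\n", sep = "")
  cat("  normalization: ", if (is.null(x$normalization)) "off" else "min-max",
      "; POD centering: ", if (is.null(x$pod_basis$center)) "off" else "on",
      "\n", sep = "")
  print(x$gp_model)
  invisible(x)
}

#' Sweep the POD truncation level
#'
#' Re-trains the GP at every truncation level in `k_range` on one shared
#' train/test split (normalization and the POD basis are fitted once on
#' the training columns), reporting per level the eigenvalue, cumulative
#' energy, and train/test SMAE and MAE. The "best" level is the one with
#' minimal testing MAE, ties resolved toward fewer modes.
#'
#' @param cohort A `snapshot_cohort`.
#' @param split A [split_data()] result.
#' @param k_range Integer vector of truncation levels (default all of
#'   `1:N`).
#' @param config A [metamodel_config()]; GP seeds are derived per level as
#'   `seed + k`.
#' @return A data frame of class `sweep_report` with columns `k`,
#'   `eigenvalue`, `cum_energy_pct`, `smae_train_pct`, `smae_test_pct`,
#'   `mae_train_months`, `mae_test_months`; attributes `best_k` and
#'   `split`.
#' @export
sweep_truncation <- function(cohort, split, k_range = NULL,
                             config = metamodel_config()) {
  stopifnot(inherits(cohort, "snapshot_cohort"),
            inherits(split, "split_spec"))
  N <- cohort$n_indicators
  if (is.null(k_range)) k_range <- seq_len(N)
  if (any(k_range < 1L) || any(k_range > N)) stop("k_range must lie in [1, ", N, "]")
  k_range <- sort(unique(as.integer(k_range)))

  U <- cohort$U
  t <- cohort$ages_months
  tr <- split$train_indices
  te <- split$test_indices
  U_train <- U[, tr, drop = FALSE]
  U_test <- U[, te, drop = FALSE]
  if (config$normalize) {
    nz <- normalize_indicators(U_train, U_test)
    U_train <- nz$train
    U_test <- nz$other
  }
  basis <- compute_pod_basis(U_train, center = config$center_pod)
  A_train <- pod_project(basis, U_train)   # full-rank amplitudes, sliced per k
  A_test <- pod_project(basis, U_test)

  rows <- lapply(k_range, function(k) {
    Xtr <- A_train[seq_len(k), , drop = FALSE]
    Xte <- A_test[seq_len(k), , drop = FALSE]
    gp <- train_gp(Xtr, t[tr], n_restarts = config$n_restarts,
                   max_iter = config$max_iter, tol = config$tol,
                   seed = config$seed + k)
    ptr <- gp_predict(gp, Xtr, type = config$variance_type)
    pte <- gp_predict(gp, Xte, type = config$variance_type)
    data.frame(k = k,
               eigenvalue = basis$eigenvalues[k],
               cum_energy_pct = cumulative_energy(basis, k),
               smae_train_pct = smae(t[tr], ptr$mean_months),
               smae_test_pct = smae(t[te], pte$mean_months),
               mae_train_months = mae(t[tr], ptr$mean_months),
               mae_test_months = mae(t[te], pte$mean_months))
  })
  report <- do.call(rbind, rows)
  best <- report$k[which.min(report$mae_test_months)]  # which.min: first = smallest k
  structure(report, best_k = best, split = split,
            class = c("sweep_report", "data.frame"))
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Truncation sweep (", nrow(x), " levels); best k by testing MAE: ",
      attr(x, "best_k"), "\n", sep = "")
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], function(v) round(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predict age for new patients from raw indicator vectors
#'
#' The deployment path of the metamodel: the stored normalization (if any)
#' is applied to the raw indicator vector, the vector is projected onto
#' the prepared orthogonal basis, the amplitudes are truncated to the
#' model's level, and the GP returns the age estimate with its predictive
#' standard deviation.
#'
#' @param metamodel A `podgp_metamodel` from [train_metamodel()].
#' @param raw_indicators Length-N vector (one patient) or N x m matrix
#'   (columns = patients) of raw indicator values.
#' @return An `age_prediction` data frame (`mean_months`, `std_months`,
#'   `variance_months2`), one row per patient, in input order.
#' @export
predict_age <- function(metamodel, raw_indicators) {
  stopifnot(inherits(metamodel, "podgp_metamodel"))
  N <- length(metamodel$indicator_names)
  if (is.null(dim(raw_indicators))) {
    raw_indicators <- matrix(raw_indicators, ncol = 1L)
  }
  raw_indicators <- as.matrix(raw_indicators)
  if (nrow(raw_indicators) != N) {
    stop("expected ", N, " indicators per patient, got ", nrow(raw_indicators))
  }
  bad <- which(!is.finite(raw_indicators), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite indicator value(s): ",
         paste(unique(metamodel$indicator_names[bad[, 1L]]), collapse = ", "))
  }
  U <- raw_indicators
  if (!is.null(metamodel$normalization)) {
    U <- apply_normalization(U, metamodel$normalization)
  }
  x <- pod_project(metamodel$pod_basis, U)
  gp_predict(metamodel$gp_model, x, type = metamodel$config$variance_type)
}

#' Study of error versus train/test ratio
#'
#' Re-trains the metamodel at a fixed truncation level over a grid of test
#' fractions (default `i/18, i = 1..17`) and several split seeds,
#' reporting train and test MAE per run and aggregated mean and sd across
#' seeds per fraction.
#'
#' @param cohort A `snapshot_cohort`.
#' @param fractions Numeric vector of test fractions in `(0, 1)`.
#' @param k Truncation level.
#' @param seeds Integer vector of split seeds.
#' @param config A [metamodel_config()].
#' @return List of class `ratio_study` with `runs` (one row per fraction x
#'   seed: `test_fraction`, `seed`, `n_test`, `mae_train_months`,
#'   `mae_test_months`, `smae_train_pct`, `smae_test_pct`) and `summary`
#'   (per fraction: mean and sd of test MAE across seeds).
#' @export
run_ratio_study <- function(cohort, fractions = (1:17) / 18, k = 7,
                            seeds = 1:3, config = metamodel_config()) {
  stopifnot(inherits(cohort, "snapshot_cohort"))
  runs <- do.call(rbind, lapply(fractions, function(f) {
    do.call(rbind, lapply(seeds, function(s) {
      sp <- split_data(cohort$n_patients, f, seed = s)
      fit <- train_metamodel(cohort, sp, k, config)
      data.frame(test_fraction = f, seed = s,
                 n_test = length(sp$test_indices),
                 mae_train_months = fit$train_metrics$mae_months,
                 mae_test_months = fit$test_metrics$mae_months,
                 smae_train_pct = fit$train_metrics$smae_percent,
                 smae_test_pct = fit$test_metrics$smae_percent)
    }))
  }))
  agg <- do.call(rbind, lapply(split(runs, runs$test_fraction), function(g) {
    data.frame(test_fraction = g$test_fraction[1L],
               n_seeds = nrow(g),
               mae_test_mean = mean(g$mae_test_months),
               mae_test_sd = if (nrow(g) > 1L) stats::sd(g$mae_test_months) else NA_real_,
               mae_train_mean = mean(g$mae_train_months))
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg), class = "ratio_study")
}

#' @export
print.ratio_study <- function(x, ...) {
  cat("Train/test ratio study (", nrow(x$runs), " runs)\n", sep = "")
  df <- x$summary
  df[-(1:2)] <- lapply(df[-(1:2)], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
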