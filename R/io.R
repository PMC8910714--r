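#' Read a cohort CSV of indicators and ages
#'
#' Expected schema: columns `patient_id`, optional `sex` (carried but
#' unused by the model), `age_months`, and indicator columns `X01`, `X02`,
#' ... (zero-padded, any count). UTF-8, '.' decimal separator.
#'
#' @param path Path to the CSV file.
#' @param require_age Require the `age_months` column (default `TRUE`).
#'   Prediction inputs for new patients may omit it.
#' @return A `snapshot_cohort` (with `ages_months = NA` for age-free
#'   prediction input).
#' @export
read_cohort <- function(path, require_age = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"patient_id" %in% names(df)) stop("missing required column: patient_id")
  ind_cols <- grep("^X[0-9]+$", names(df), value = TRUE)
  if (length(ind_cols) == 0L) stop("no indicator columns (X01, X02, ...) found")
  ind_cols <- ind_cols[order(as.integer(sub("^X", "", ind_cols)))]
  expected <- sprintf("X%02d", seq_along(ind_cols))
  missing <- setdiff(expected, ind_cols)
  if (length(missing) > 0L) {
    stop("indicator columns are not contiguous; missing: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    dup <- which(duplicated(df$patient_id))[1L]
    stop("duplicate patient_id '", df$patient_id[dup], "' at row ", dup)
  }
  for (cn in ind_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("unparseable or non-finite value in column ", cn, " at row ", bad[1L])
    }
    df[[cn]] <- v
  }
  have_age <- "age_months" %in% names(df)
  if (require_age && !have_age) stop("missing required column: age_months")
  ages <- if (have_age) {
    v <- suppressWarnings(as.numeric(df$age_months))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L) stop("invalid age_months at row ", bad[1L])
    v
  } else {
    rep(NA_real_, nrow(df))
  }
  if (have_age) {
    build_snapshot_matrix(as.matrix(df[ind_cols]), ages,
                          indicator_names = ind_cols,
                          patient_ids = df$patient_id)
  } else {
    # bypass the positive-age check for prediction-only input
    coh <- build_snapshot_matrix(as.matrix(df[ind_cols]), rep(1, nrow(df)),
                                 indicator_names = ind_cols,
                                 patient_ids = df$patient_id)
    coh$ages_months <- ages
    coh
  }
}

#' Write a cohort to the standard CSV schema
#'
#' @param cohort A `snapshot_cohort`.
#' @param path Output CSV path.
#' @param sex Optional character vector of per-patient sex labels, written
#'   for realism but ignored by the model.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, sex = NULL) {
  stopifnot(inherits(cohort, "snapshot_cohort"))
  df <- data.frame(patient_id = cohort$patient_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- sex
  df$age_months <- cohort$ages_months
  ind <- as.data.frame(t(cohort$U))
  names(ind) <- cohort$indicator_names
  df <- cbind(df, ind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Save a trained metamodel to a versioned JSON file
#'
#' Serializes everything needed to reproduce predictions: normalization
#' parameters, POD eigenvalues and truncated basis, GP hyperparameters,
#' training amplitudes and targets, and seeds. The Cholesky factor is
#' deliberately omitted and recomputed (and verified) on load.
#'
#' @param metamodel A `podgp_metamodel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_model <- function(metamodel, path) {
  stopifnot(inherits(metamodel, "podgp_metamodel"))
  b <- metamodel$pod_basis
  g <- metamodel$gp_model
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    indicator_names = metamodel$indicator_names,
    normalization = if (!is.null(metamodel$normalization)) {
      list(min = metamodel$normalization$min,
           range = metamodel$normalization$range)
    },
    pod = list(eigenvalues = b$eigenvalues,
               omega = b$Omega,           # N x k truncated basis
               truncation_level = b$truncation_level,
               center = b$center),
    gp = list(hyper = list(nu = g$hyper$nu, omegas = g$hyper$omegas,
                           bias = g$hyper$bias, beta = g$hyper$beta),
              training_inputs = g$X,
              training_targets = g$t,
              t_center = g$t_center,
              log_marginal_likelihood = g$log_marginal_likelihood),
    config = unclass(metamodel$config),
    split_seed = metamodel$split_seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a metamodel saved by [save_model()]
#'
#' Validates the format version, rebuilds the GP factorization from the
#' stored hyperparameters and training data, and verifies that the
#' covariance is positive definite and that `alpha` solves `C a = t` to
#' 1e-8 relative residual. Corrupted hyperparameters or arrays are
#' rejected.
#'
#' @param path Path to the model JSON.
#' @return A `podgp_metamodel`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) ||
      !identical(doc$format_version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format_version '", doc$format_version,
         "'; this build reads version ", MODEL_FORMAT_VERSION)
  }
  Omega <- as.matrix(doc$pod$omega)
  k <- as.integer(doc$pod$truncation_level)
  if (ncol(Omega) != k) stop("corrupted model: basis width != truncation level")
  basis <- structure(
    list(eigenvalues = as.numeric(doc$pod$eigenvalues),
         vectors = NULL,                 # full basis not persisted
         truncation_level = k, Omega = Omega,
         center = if (!is.null(doc$pod$center)) as.numeric(doc$pod$center),
         n_modes = nrow(Omega)),
    class = "pod_basis"
  )
  h <- doc$gp$hyper
  hyper <- gp_hyper(h$nu, h$omegas, h$bias, h$beta)   # validates positivity
  X <- as.matrix(doc$gp$training_inputs)
  t <- as.numeric(doc$gp$training_targets)
  gp <- gp_fit(X, t, hyper, t_center = as.numeric(doc$gp$t_center))
  resid <- gp_covariance(X, hyper) %*% gp$alpha +
    gp$jitter * gp$alpha - (t - gp$t_center)
  if (sqrt(sum(resid^2)) > 1e-8 * max(1, sqrt(sum((t - gp$t_center)^2)))) {
    stop("integrity check failed: alpha does not solve the covariance system")
  }
  norm <- NULL
  if (!is.null(doc$normalization)) {
    norm <- list(min = as.numeric(doc$normalization$min),
                 range = as.numeric(doc$normalization$range))
  }
  cfg <- doc$config
  config <- metamodel_config(normalize = isTRUE(cfg$normalize),
                             center_pod = isTRUE(cfg$center_pod),
                             n_restarts = cfg$n_restarts,
                             max_iter = cfg$max_iter, tol = cfg$tol,
                             seed = cfg$seed,
                             variance_type = cfg$variance_type)
  structure(
    list(normalization = norm, pod_basis = basis, gp_model = gp,
         truncation_level = k,
         indicator_names = as.character(doc$indicator_names),
         config = config, split_seed = doc$split_seed),
    class = "podgp_metamodel"
  )
}

#' Write a sweep report to CSV
#'
#' Columns: `k, eigenvalue, cum_energy_pct, smae_train_pct, smae_test_pct,
#' mae_train_months, mae_test_months`.
#'
#' @param report A `sweep_report` from [sweep_truncation()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sweep_report <- function(report, path) {
  stopifnot(inherits(report, "sweep_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
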