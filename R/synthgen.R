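#' Configuration for a synthetic tooth-indicator cohort
#'
#' The generator emulates the statistical structure the metamodel assumes
#' in a paediatric dental cohort: ages between 52 and 214 months with most
#' mass between 80 and 150 months; positive indicators whose joint
#' variation is low-rank and driven by smooth, monotone, saturating
#' functions of age (like mineralization-stage ratios); a few
#' near-constant indicators; and a few "wild" indicators occasionally
#' corrupted by heavy-tailed multiplicative outliers (mimicking indicators
#' measured on not-yet-formed teeth, whose observed ranges can span three
#' orders of magnitude).
#'
#' @param n_patients Number of patients M (default 619).
#' @param n_indicators Number of indicators N (default 21).
#' @param latent_rank Number of age-driven latent modes (default 5).
#' @param age_range_months Length-2 vector, default `c(52, 214)`.
#' @param age_mode_months Mode of the triangular age distribution, inside
#'   the range (default 115 — the centre of the 80-150 month bulk).
#' @param noise_sd Observation noise, as a fraction of each indicator's
#'   typical magnitude (default 0.01).
#' @param n_constant_like Number of near-constant indicators (default 4,
#'   like the four low-variability indicators of a 21-panel).
#' @param n_wild Number of outlier-prone indicators (default 3).
#' @param outlier_rate Per-entry probability of an outlier in wild rows
#'   (default 0.05).
#' @param outlier_scale Magnitude scale of the multiplicative outliers
#'   (default 100: entries are scaled by `outlier_scale^(+/- u)`,
#'   `u ~ U(0.5, 1.5)`).
#' @param seed Integer seed; every draw of the cohort flows from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 619, n_indicators = 21,
                          latent_rank = 5,
                          age_range_months = c(52, 214),
                          age_mode_months = 115,
                          noise_sd = 0.01,
                          n_constant_like = 4, n_wild = 3,
                          outlier_rate = 0.05, outlier_scale = 100,
                          seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_indicators = as.integer(n_indicators),
              latent_rank = as.integer(latent_rank),
              age_range_months = as.numeric(age_range_months),
              age_mode_months = as.numeric(age_mode_months),
              noise_sd = as.numeric(noise_sd),
              n_constant_like = as.integer(n_constant_like),
              n_wild = as.integer(n_wild),
              outlier_rate = as.numeric(outlier_rate),
              outlier_scale = as.numeric(outlier_scale),
              seed = as.integer(seed))
  if (cfg$n_patients < 1L || cfg$n_indicators < 1L) {
    stop("n_patients and n_indicators must be >= 1")
  }
  if (cfg$latent_rank < 1L || cfg$latent_rank > cfg$n_indicators) {
    stop("latent_rank must be in [1, n_indicators]")
  }
  if (cfg$n_constant_like + cfg$n_wild > cfg$n_indicators) {
    stop("n_constant_like + n_wild exceeds n_indicators")
  }
  if (length(cfg$age_range_months) != 2L ||
      cfg$age_range_months[1L] >= cfg$age_range_months[2L]) {
    stop("age_range_months must be an increasing pair")
  }
  if (cfg$age_mode_months <= cfg$age_range_months[1L] ||
      cfg$age_mode_months >= cfg$age_range_months[2L]) {
    stop("age_mode_months must lie strictly inside age_range_months")
  }
  if (cfg$noise_sd < 0 || cfg$outlier_rate < 0 || cfg$outlier_rate > 1 ||
      cfg$outlier_scale <= 1) {
    stop("noise_sd >= 0, outlier_rate in [0,1], outlier_scale > 1 required")
  }
  structure(cfg, class = "cohort_config")
}

# Triangular(lo, mode, hi) sampler by inverse CDF.
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  f <- (mode - lo) / (hi - lo)
  ifelse(u < f,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Generate a synthetic cohort of tooth-geometry indicators and ages
#'
#' Draws ages from a triangular distribution on the configured range, then
#' builds indicators as `U = L %*% Z + noise`, where the latent matrix `Z`
#' holds `latent_rank` scaled logistic functions of age (inflection ages
#' spread over 60-200 months, so each mode "saturates" at a different
#' developmental stage) and `L` is a positive random loading matrix with
#' heterogeneous row scales. With the noise and outliers switched off the
#' snapshot matrix has rank exactly `latent_rank`. Designated
#' near-constant rows get loadings and noise scaled down by 1e-3 and 1/100
#' respectively; designated wild rows receive sporadic multiplicative
#' heavy-tailed outliers.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (a [build_snapshot_matrix()] result:
#'   snapshot matrix + ages), and `ground_truth` (loadings, latent
#'   parameters, row roles, noise standard deviations, outlier mask, the
#'   config) for use in test assertions.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    M <- config$n_patients
    N <- config$n_indicators
    R <- config$latent_rank
    ages <- rtriangular(M, config$age_range_months[1L],
                        config$age_mode_months, config$age_range_months[2L])

    # latent developmental modes: scaled logistic curves of age whose
    # transitions complete within about 0.5-1.5 years, staggered across
    # the age range where the cohort has mass, so each mode carries
    # distinguishable information
    centers <- seq(70, 180, length.out = R) + stats::runif(R, -5, 5)
    slopes <- stats::runif(R, 3, 8)
    Z <- vapply(seq_len(R), function(r) {
      0.5 + 1 / (1 + exp(-(ages - centers[r]) / slopes[r]))
    }, numeric(M))                      # M x R, values in (0.5, 1.5)
    Z <- t(Z)                           # R x M

    # positive loadings with heterogeneous per-indicator scales; each
    # indicator primarily reflects one developmental mode, with weak
    # cross-loadings on the others
    primary <- rep_len(seq_len(R), N)[sample.int(N)]
    L <- matrix(stats::runif(N * R, 0.05, 0.3), N, R)
    L[cbind(seq_len(N), primary)] <- stats::runif(N, 0.8, 1.2)
    row_scale <- exp(stats::rnorm(N, 0, 0.8))
    L <- L * row_scale

    roles <- rep("normal", N)
    special <- sample.int(N, config$n_constant_like + config$n_wild)
    const_rows <- special[seq_len(config$n_constant_like)]
    wild_rows <- setdiff(special, const_rows)
    roles[const_rows] <- "constant_like"
    roles[wild_rows] <- "wild"
    L[const_rows, ] <- L[const_rows, , drop = FALSE] * 1e-3

    U <- L %*% Z                        # N x M, rank R by construction

    noise_row_sd <- config$noise_sd * apply(abs(U), 1L, stats::median)
    noise_row_sd[const_rows] <- noise_row_sd[const_rows] / 100
    E <- matrix(stats::rnorm(N * M), N, M) * noise_row_sd
    if (config$noise_sd > 0) U <- U + E

    outlier_mask <- matrix(FALSE, N, M)
    if (config$outlier_rate > 0 && length(wild_rows) > 0L) {
      for (i in wild_rows) {
        hit <- stats::runif(M) < config$outlier_rate
        if (any(hit)) {
          u <- stats::runif(sum(hit), 0.5, 1.5)
          sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
          U[i, hit] <- U[i, hit] * config$outlier_scale^(sgn * u)
          outlier_mask[i, hit] <- TRUE
        }
      }
    }
    U <- pmax(U, 1e-8)                  # indicators are positive by definition

    cohort <- build_snapshot_matrix(t(U), ages)
    list(cohort = cohort,
         ground_truth = list(loadings = L, latent_centers = centers,
                             latent_slopes = slopes, latents = Z,
                             row_scale = row_scale, roles = roles,
                             noise_row_sd = noise_row_sd,
                             outlier_mask = outlier_mask,
                             config = config))
  })
}

#' Simulate a regression testbed from a known Gaussian process
#'
#' Draws `n_points` inputs uniformly in `[-1, 1]^dims` and samples targets
#' exactly from the GP prior with the given hyperparameters (covariance
#' `K + I/beta`, sampled through its Cholesky factor). Used for
#' parameter-recovery experiments where the truth is known.
#'
#' @param n_points Number of points.
#' @param dims Input dimension.
#' @param hyper A [gp_hyper()] with `omegas` of length `dims` — the ground
#'   truth.
#' @param seed Integer seed.
#' @return List with `X` (dims x n matrix), `t` (length-n targets),
#'   `hyper`, `seed`.
#' @export
generate_gp_testbed <- function(n_points, dims, hyper, seed = 1) {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (length(hyper$omegas) != dims) stop("hyper$omegas must have length dims")
  with_local_seed(seed, {
    X <- matrix(stats::runif(dims * n_points, -1, 1), dims, n_points)
    C <- gp_covariance(X, hyper)
    ch <- chol_jitter(C)
    t <- drop(crossprod(ch$R, stats::rnorm(n_points)))
    list(X = X, t = t, hyper = hyper, seed = seed)
  })
}
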