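#' Assemble a snapshot matrix and target vector from patient records
#'
#' Collects per-patient indicator vectors into the N x M snapshot matrix `U`
#' (rows = indicators, columns = patients) paired with the M-vector of
#' chronological ages in months. One column of `U` is one patient's
#' "snapshot" of all geometry indicators.
#'
#' @param indicators Patient indicator values: an M x N matrix or data frame
#'   (one row per patient), or a list of M numeric N-vectors.
#' @param ages_months Numeric vector of M chronological ages in months,
#'   strictly positive, one per patient and in the same order.
#' @param indicator_names Optional character vector of N indicator labels.
#'   Defaults to `X01 ... XNN` in the field's customary zero-padded style.
#' @param patient_ids Optional vector of M unique patient identifiers.
#'
#' @return An object of class `snapshot_cohort`: a list with elements
#'   `U` (N x M numeric matrix), `ages_months`, `indicator_names`,
#'   `patient_ids`, `n_indicators`, `n_patients`.
#'
#' @examples
#' coh <- build_snapshot_matrix(matrix(runif(6), nrow = 2), c(100, 120))
#' dim(coh$U)  # 3 x 2
#' @export
build_snapshot_matrix <- function(indicators, ages_months,
                                  indicator_names = NULL,
                                  patient_ids = NULL) {
  if (is.list(indicators) && !is.data.frame(indicators)) {
    lens <- lengths(indicators)
    if (length(unique(lens)) > 1L) {
      stop("ragged indicator vectors: lengths ", paste(unique(lens), collapse = ", "))
    }
    indicators <- do.call(rbind, lapply(indicators, as.numeric))
  }
  indicators <- as.matrix(indicators)
  storage.mode(indicators) <- "double"
  M <- nrow(indicators)
  N <- ncol(indicators)
  if (M < 1L || N < 1L) stop("need at least one patient and one indicator")
  if (length(ages_months) != M) {
    stop("length of ages_months (", length(ages_months),
         ") does not match number of patients (", M, ")")
  }
  bad <- which(!is.finite(indicators), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite indicator value at patient row ", bad[1L, 1L],
         ", indicator column ", bad[1L, 2L])
  }
  ages_months <- as.numeric(ages_months)
  if (any(!is.finite(ages_months)) || any(ages_months <= 0)) {
    stop("ages_months must be finite and strictly positive")
  }
  if (is.null(indicator_names)) {
    indicator_names <- sprintf("X%02d", seq_len(N))
  }
  if (length(indicator_names) != N) stop("indicator_names must have length ", N)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(M))
  if (anyDuplicated(patient_ids)) stop("patient_ids contains duplicates")

  U <- t(indicators)            # N x M, column per patient
  rownames(U) <- indicator_names
  colnames(U) <- as.character(patient_ids)
  structure(
    list(U = U, ages_months = ages_months,
         indicator_names = indicator_names,
         patient_ids = as.character(patient_ids),
         n_indicators = N, n_patients = M),
    class = "snapshot_cohort"
  )
}

#' @export
print.snapshot_cohort <- function(x, ...) {
  cat("Snapshot cohort: ", x$n_indicators, " indicators x ",
      x$n_patients, " patients\n", sep = "")
  cat("  age range: ", round(min(x$ages_months), 1), "-",
      round(max(x$ages_months), 1), " months\n", sep = "")
  invisible(x)
}

# Coerce a snapshot_cohort or plain matrix to the N x M snapshot matrix.
as_snapshot_matrix <- function(U) {
  if (inherits(U, "snapshot_cohort")) U <- U$U
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  if (any(!is.finite(U))) stop("snapshot matrix contains non-finite values")
  U
}
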