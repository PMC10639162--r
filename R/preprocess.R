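#' Body mass index
#'
#' @param height_m height in meters (positive).
#' @param weight_kg weight in kilograms (positive).
#' @return BMI in kg/m2. Vectorized.
#' @examples
#' compute_bmi(1.70, 72.25)  # 25
#' @export
compute_bmi <- function(height_m, weight_kg) {
  if (any(!is.finite(height_m)) || any(!is.finite(weight_kg)) ||
      any(height_m <= 0) || any(weight_kg <= 0))
    stop_invalid("height and weight must be positive and finite")
  weight_kg / height_m^2
}

#' Obesity label from BMI
#'
#' Dichotomizes BMI at the 25 kg/m2 cut-point used for Korean adults; the
#' boundary itself counts as obese.
#'
#' @param bmi finite BMI value(s).
#' @param threshold dividing line, default 25.
#' @return Logical: `TRUE` iff `bmi >= threshold`.
#' @export
label_obesity <- function(bmi, threshold = 25) {
  if (any(!is.finite(bmi))) stop_invalid("bmi must be finite")
  bmi >= threshold
}

#' Exclude records containing no-response codes
#'
#' A record with a no-response code in *any* feature column is removed
#' entirely (listwise deletion; the study design excludes rather than
#' imputes). Survivor order is preserved, and the operation is idempotent.
#'
#' @param records data frame of individual records.
#' @param no_response_codes nonempty set of sentinel codes.
#' @param feature_cols columns to scan; defaults to the survey feature
#'   columns per [individual_feature_names()].
#' @return The surviving records, with a `n_dropped` attribute.
#' @export
drop_no_response <- function(records, no_response_codes = 9L,
                             feature_cols = individual_feature_names(records)) {
  stopifnot(is.data.frame(records), length(no_response_codes) >= 1)
  if (!all(feature_cols %in% names(records)))
    stop_invalid("unknown feature columns: %s",
                 paste(setdiff(feature_cols, names(records)), collapse = ", "))
  if (nrow(records) == 0 || length(feature_cols) == 0) return(records)
  hit <- Reduce(`|`, lapply(records[feature_cols],
                            function(x) x %in% no_response_codes))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(hit)
  out
}

#' Per-capita normalization of district totals
#'
#' Districts differ widely in area and population, so district-level totals
#' are converted to per-person values by dividing by district population.
#'
#' @param district_values named numeric vector or list, district id -> total.
#' @param populations named vector, district id -> positive population.
#' @return Named numeric vector of per-capita values (same districts).
#' @examples
#' per_capita_normalize(c(A = 1000), c(A = 500))  # A = 2
#' @export
per_capita_normalize <- function(district_values, populations) {
  district_values <- unlist(district_values)
  populations <- unlist(populations)
  if (is.null(names(district_values)) || is.null(names(populations)) ||
      !setequal(names(district_values), names(populations)))
    stop_invalid("district_values and populations must cover identical districts")
  populations <- populations[names(district_values)]
  if (any(!is.finite(populations)) || any(populations <= 0))
    stop_invalid("populations must be positive")
  if (any(!is.finite(district_values)) || any(district_values < 0))
    stop_invalid("district values must be nonnegative and finite")
  district_values / populations
}

#' Random oversampling to a 1:1 class balance
#'
#' Resamples the minority class with replacement until the two classes are
#' equal in count; majority records are untouched and every added record is
#' an exact copy of an existing minority record. Intended to be applied to
#' *training* data only (inside cross-validation folds), never before
#' splitting.
#'
#' @param records data frame with a logical/0-1 label column.
#' @param seed integer seed (deterministic resampling).
#' @param label_col name of the label column, default `"obese"`.
#' @return The balanced data frame (original records first, then duplicates).
#' @export
random_oversample <- function(records, seed, label_col = "obese") {
  stopifnot(is.data.frame(records), label_col %in% names(records))
  lab <- as.logical(records[[label_col]])
  if (any(is.na(lab))) stop_invalid("label column contains missing values")
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0)
    stop_invalid("random_oversample requires both classes present (got %d/%d)",
                 n0, n1)
  if (n1 == n0) return(records)
  minority <- which(if (n1 < n0) lab else !lab)
  deficit <- abs(n0 - n1)
  extra <- with_seed(seed, sample(minority, deficit, replace = TRUE))
  out <- rbind(records, records[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}
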