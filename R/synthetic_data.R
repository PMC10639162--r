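#' Simulated Seoul-like districts
#'
#' Draws a set of administrative districts on the unit square, each with a
#' planar centroid and a population. Coordinates are abstract planar units
#' (the downstream spatial model only ever uses Euclidean inter-centroid
#' distance), so no geodesy is involved. The default of 25 districts mirrors
#' the number of autonomous Gu districts of a large Korean metropolis.
#'
#' @param n_districts number of districts to generate (at least 2).
#' @param seed integer seed; identical inputs give identical output.
#' @return A data frame with columns `district_id`, `u`, `v` (planar centroid
#'   coordinates in `[0, 1]`) and `population` (integer, 80k-700k).
#' @examples
#' generate_districts(25, seed = 1)
#' @export
generate_districts <- function(n_districts = 25, seed) {
  if (!is.numeric(n_districts) || length(n_districts) != 1L ||
      is.na(n_districts) || n_districts < 2)
    stop_invalid("n_districts must be a single number >= 2, got %s",
                 format(n_districts)[1])
  n_districts <- as.integer(n_districts)
  with_seed(seed, {
    data.frame(
      district_id = sprintf("D%02d", seq_len(n_districts)),
      u = runif(n_districts),
      v = runif(n_districts),
      population = as.integer(round(exp(runif(n_districts, log(8e4), log(7e5))))),
      stringsAsFactors = FALSE
    )
  })
}

# default spatially varying coefficient surfaces on the unit square;
# factor names echo the social/environmental factors of the district-level
# analysis. Two factors are true zeros so that screening and shrinkage have
# known prunable targets.
default_district_surfaces <- function() {
  list(
    green_park_area = function(u, v) -(0.35 + 0.25 * v),
    land_price      = function(u, v) -(0.40 + 0.20 * u),
    bus_rate        = function(u, v)   0.45 + 0.15 * sin(pi * (u + v) / 2),
    bicycle_rate    = function(u, v) -(0.32 + 0.28 * u * v),
    health_budget   = function(u, v) rep(0, length(u)),
    bus_rush_rate   = function(u, v) rep(0, length(u))
  )
}

default_individual_effects <- function() {
  c(body_shape_awareness = 3.6,
    weight_control       = 1.8,
    high_bp              = 1.2,
    fast_food            = 0.9,
    household_income     = -0.9)
}

#' Ground truth for the synthetic two-track study
#'
#' Bundles everything the generators need and everything recovery tests need
#' afterwards: the spatially varying coefficient surfaces of the district
#' model, the logistic effects of the individual model, the injected
#' pathological features (an exact duplicate column and true-null features),
#' and the seed. The logistic intercept is calibrated exactly (enumeration
#' over the factorial of ordinal codes, bisection on the intercept) so that
#' the implied obesity prevalence equals `obesity_base_rate`.
#'
#' @param district_surfaces named list of functions `(u, v) -> coefficient`;
#'   one per district-level factor. Defaults to four smooth non-zero surfaces
#'   (|beta| >= 0.3 everywhere) and two identically-zero surfaces.
#' @param intercept_surface function `(u, v) -> baseline obesity rate`.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   district obesity rates.
#' @param covariate_sd marginal standard deviation of the district covariates
#'   (drawn as centered per-capita deviations, `N(0, covariate_sd^2)`).
#' @param individual_effects named numeric vector of logistic coefficients on
#'   the ordinal survey codes.
#' @param null_features names of individual features generated but carrying
#'   zero true effect.
#' @param duplicate_features named character vector: new column -> source
#'   column, copied exactly (to exercise collinearity pruning).
#' @param obesity_base_rate target obesity prevalence in (0, 1).
#' @param n_levels number of ordinal response levels (codes `1:n_levels`).
#' @param seed integer seed stored with the truth; generators default to it.
#' @return An object of class `synthetic_truth`.
#' @examples
#' tr <- synthetic_truth(seed = 1)
#' tr$individual_intercept
#' @export
synthetic_truth <- function(district_surfaces = default_district_surfaces(),
                            intercept_surface = function(u, v) 0.30 + 0.04 * (u + v - 1),
                            noise_sd = 0.02,
                            covariate_sd = 0.15,
                            individual_effects = default_individual_effects(),
                            null_features = c("education", "stress_level"),
                            duplicate_features = c(weight_control_dup = "weight_control"),
                            obesity_base_rate = 0.30,
                            n_levels = 4L,
                            seed = 1L) {
  stopifnot(is.list(district_surfaces), length(district_surfaces) >= 1,
            !is.null(names(district_surfaces)),
            is.function(intercept_surface),
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(individual_effects), !is.null(names(individual_effects)),
            obesity_base_rate > 0, obesity_base_rate < 1,
            n_levels >= 2)
  if (length(duplicate_features) &&
      !all(duplicate_features %in% c(names(individual_effects), null_features)))
    stop_invalid("duplicate_features must point at generated feature columns")
  overlap <- intersect(names(individual_effects),
                       c(null_features, names(duplicate_features)))
  if (length(overlap))
    stop_invalid("features cannot be both effective and null/duplicate: %s",
                 paste(overlap, collapse = ", "))

  intercept <- calibrate_logistic_intercept(individual_effects,
                                            obesity_base_rate, n_levels, seed)
  structure(
    list(district_surfaces = district_surfaces,
         intercept_surface = intercept_surface,
         noise_sd = noise_sd,
         covariate_sd = covariate_sd,
         individual_effects = individual_effects,
         null_features = null_features,
         duplicate_features = duplicate_features,
         individual_intercept = intercept,
         obesity_base_rate = obesity_base_rate,
         n_levels = as.integer(n_levels),
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic two-track ground truth\n")
  cat(sprintf("  district factors : %s\n",
              paste(names(x$district_surfaces), collapse = ", ")))
  cat(sprintf("  rate noise sd    : %.3g\n", x$noise_sd))
  cat(sprintf("  individual model : logit(p) = %.3f + <effects, codes>\n",
              x$individual_intercept))
  eff <- sprintf("%s=%.2g", names(x$individual_effects), x$individual_effects)
  cat(sprintf("  effects          : %s\n", paste(eff, collapse = ", ")))
  cat(sprintf("  null features    : %s\n", paste(x$null_features, collapse = ", ")))
  cat(sprintf("  duplicates       : %s\n",
              paste(sprintf("%s<-%s", names(x$duplicate_features),
                            x$duplicate_features), collapse = ", ")))
  cat(sprintf("  base obesity rate: %.2f (seed %d)\n",
              x$obesity_base_rate, x$seed))
  invisible(x)
}

# Solve E[plogis(c + sum_k beta_k X_k)] = target for c, with X_k iid uniform
# on 1:n_levels. Exact via the full factorial when small enough, Monte Carlo
# with a derived seed otherwise.
calibrate_logistic_intercept <- function(effects, target, n_levels, seed) {
  p <- length(effects)
  if (p == 0) return(qnorm(0) * 0 + log(target / (1 - target)))
  if (n_levels^p <= 2^20) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_levels)), p)))
    eta0 <- drop(grid %*% effects)
  } else {
    eta0 <- with_seed(derive_seed(seed, "intercept-calibration"), {
      drop(matrix(sample(seq_len(n_levels), 2e5 * p, replace = TRUE),
                  ncol = p) %*% effects)
    })
  }
  uniroot(function(c0) mean(plogis(c0 + eta0)) - target,
          interval = c(-200, 200), tol = 1e-10)$root
}

#' District feature panel from true coefficient surfaces
#'
#' Simulates the district-level analysis table: covariates are drawn as
#' centered per-capita deviations, and the obesity rate of district *i* is
#' the local linear predictor `beta0(u_i, v_i) + sum_k x_ik beta_k(u_i, v_i)`
#' plus Gaussian noise, clipped to `[0, 1]`. The generating truth and the
#' pre-clipping linear predictor are retained as attributes for recovery
#' tests.
#'
#' @param geoms district geometries from [generate_districts()].
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed; defaults to `truth$seed`.
#' @return A data frame with `district_id`, `u`, `v`, `population`, one column
#'   per factor, and `y` (obesity rate). Attributes: `truth`,
#'   `linear_predictor` (unclipped), `true_beta` (districts x factors matrix
#'   of the true local coefficients), `true_intercept`.
#' @export
generate_district_panel <- function(geoms, truth, seed = truth$seed) {
  stopifnot(is.data.frame(geoms), nrow(geoms) >= 1,
            all(c("district_id", "u", "v", "population") %in% names(geoms)),
            inherits(truth, "synthetic_truth"))
  n <- nrow(geoms)
  factors <- names(truth$district_surfaces)
  p <- length(factors)

  true_beta <- vapply(truth$district_surfaces,
                      function(f) {
                        b <- f(geoms$u, geoms$v)
                        if (length(b) == 1) b <- rep(b, n)
                        stopifnot(all(is.finite(b)))
                        b
                      }, numeric(n))
  true_beta <- matrix(true_beta, nrow = n,
                      dimnames = list(geoms$district_id, factors))
  b0 <- truth$intercept_surface(geoms$u, geoms$v)
  if (length(b0) == 1) b0 <- rep(b0, n)

  out <- with_seed(derive_seed(seed, "district-panel"), {
    X <- matrix(rnorm(n * p, sd = truth$covariate_sd), n, p,
                dimnames = list(NULL, factors))
    linpred <- b0 + rowSums(X * true_beta)
    y <- pmin(1, pmax(0, linpred + rnorm(n, sd = truth$noise_sd)))
    list(X = X, linpred = linpred, y = y)
  })

  panel <- data.frame(district_id = geoms$district_id,
                      u = geoms$u, v = geoms$v,
                      population = geoms$population,
                      out$X, y = out$y,
                      stringsAsFactors = FALSE)
  attr(panel, "truth") <- truth
  attr(panel, "linear_predictor") <- out$linpred
  attr(panel, "true_beta") <- true_beta
  attr(panel, "true_intercept") <- b0
  panel
}

# inverse-CDF truncated normal draw on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Survey-like individual records with a known logistic obesity model
#'
#' Simulates individual respondents: ordinal survey codes (`1:n_levels`) per
#' feature, a district assignment, and height/weight. The obesity label is
#' drawn from the logistic model in `truth`; height and weight are then
#' sampled so that BMI is on the labeled side of the 25 kg/m2 threshold,
#' which makes BMI computation and labeling round-trip the generated label
#' exactly. The generated table contains an exact duplicate feature pair and
#' true-null features, as declared in `truth`, so collinearity and relevance
#' screening have known targets.
#'
#' @param n number of records (at least 1).
#' @param truth a [synthetic_truth()] object.
#' @param districts either `NULL` (single district "D01"), a character vector
#'   of district ids sampled uniformly, or a data frame with a `district_id`
#'   column.
#' @param no_response_rate per-cell probability that a survey feature entry is
#'   replaced by the no-response sentinel code (default 0: clean data).
#' @param no_response_code the sentinel code (default 9).
#' @param seed integer seed; defaults to `truth$seed`.
#' @return A data frame with `record_id`, `district_id`, one column per survey
#'   feature, `height_m`, `weight_kg`, and the true label `obese` (logical).
#' @export
generate_individual_records <- function(n, truth, districts = NULL,
                                        no_response_rate = 0,
                                        no_response_code = 9L,
                                        seed = truth$seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("n must be a single number >= 1, got %s", format(n)[1])
  stopifnot(inherits(truth, "synthetic_truth"),
            no_response_rate >= 0, no_response_rate < 1)
  n <- as.integer(n)
  if (is.null(districts)) districts <- "D01"
  if (is.data.frame(districts)) districts <- districts$district_id

  eff <- truth$individual_effects
  feat_names <- c(names(eff), truth$null_features)

  with_seed(derive_seed(seed, "individual-records"), {
    X <- matrix(sample(seq_len(truth$n_levels), n * length(feat_names),
                       replace = TRUE),
                nrow = n, dimnames = list(NULL, feat_names))
    eta <- truth$individual_intercept + drop(X[, names(eff), drop = FALSE] %*% eff)
    obese <- runif(n) < plogis(eta)

    # BMI consistent with the label: obese -> BMI >= 25, else BMI < 25
    bmi <- numeric(n)
    if (any(obese))  bmi[obese]  <- rtruncnorm(sum(obese), 27.5, 2.2, 25, 45)
    if (any(!obese)) bmi[!obese] <- rtruncnorm(sum(!obese), 22.0, 1.8, 14,
                                               25 - 1e-9)
    height <- pmin(2.00, pmax(1.40, rnorm(n, 1.64, 0.08)))
    weight <- bmi * height^2

    df <- data.frame(record_id = sprintf("R%06d", seq_len(n)),
                     district_id = if (length(districts) == 1) rep(districts, n)
                                   else sample(districts, n, replace = TRUE),
                     X,
                     stringsAsFactors = FALSE)
    for (dup in names(truth$duplicate_features))
      df[[dup]] <- df[[truth$duplicate_features[[dup]]]]
    if (no_response_rate > 0) {
      cols <- c(feat_names, names(truth$duplicate_features))
      mask <- matrix(runif(n * length(feat_names)) < no_response_rate,
                     nrow = n)
      for (j in seq_along(feat_names)) {
        df[[feat_names[j]]][mask[, j]] <- as.integer(no_response_code)
      }
      # duplicates must stay exact copies of their source column
      for (dup in names(truth$duplicate_features))
        df[[dup]] <- df[[truth$duplicate_features[[dup]]]]
    }
    df$height_m <- height
    df$weight_kg <- weight
    df$obese <- obese
    df
  })
}

#' Survey feature columns of an individual-records table
#'
#' @param records a data frame from [generate_individual_records()].
#' @return Character vector of feature column names (everything except the
#'   identifier, anthropometric and label columns).
#' @export
individual_feature_names <- function(records) {
  setdiff(names(records),
          c("record_id", "district_id", "height_m", "weight_kg", "bmi", "obese"))
}

#' @importFrom stats pnorm
NULL
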