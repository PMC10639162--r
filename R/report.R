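#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end analysis, with defaults
#' mirroring the study settings: BMI cut-point 25, VIF threshold 30, OLS
#' screen at 0.05, a 5,000-tree random forest validated by 10-fold
#' cross-validation, top-5 Shapley extraction, and a per-district lasso
#' penalty searched in [0.001, 0.03]. Desk-scale knobs (`n_individuals`,
#' `trees`, boosting rounds) are overridable. The object round-trips through
#' JSON unchanged.
#'
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param n_districts,n_individuals synthetic cohort sizes.
#' @param no_response_rate,no_response_codes survey no-response injection
#'   rate and sentinel code(s).
#' @param bmi_threshold obesity dividing line (kg/m2).
#' @param vif_threshold,alpha feature-screening thresholds.
#' @param classifier family used for the per-district models.
#' @param trees random-forest tree count.
#' @param folds cross-validation folds.
#' @param shap_top_k features reported per district.
#' @param shap_nrounds boosting rounds of the per-district tree ensembles
#'   that Shapley attribution explains.
#' @param kernel,bandwidth geographic kernel family and bandwidth (`NULL` =
#'   median pairwise distance).
#' @param lambda_min,lambda_max,lambda_length penalty grid for the
#'   geographically weighted lasso.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L,
                            n_districts = 25L,
                            n_individuals = 2500L,
                            no_response_rate = 0.02,
                            no_response_codes = 9L,
                            bmi_threshold = 25,
                            vif_threshold = 30,
                            alpha = 0.05,
                            classifier = "random_forest",
                            trees = 5000L,
                            folds = 10L,
                            shap_top_k = 5L,
                            shap_nrounds = 100L,
                            kernel = "gaussian",
                            bandwidth = NULL,
                            lambda_min = 0.001,
                            lambda_max = 0.03,
                            lambda_length = 30L) {
  stopifnot(n_districts >= 2, n_individuals >= 10, folds >= 2,
            vif_threshold >= 1, alpha > 0, alpha <= 1,
            lambda_min > 0, lambda_max >= lambda_min, shap_top_k >= 1)
  cfg <- list(seed = as.integer(seed), n_districts = as.integer(n_districts),
              n_individuals = as.integer(n_individuals),
              no_response_rate = no_response_rate,
              no_response_codes = no_response_codes,
              bmi_threshold = bmi_threshold,
              vif_threshold = vif_threshold, alpha = alpha,
              classifier = classifier, trees = as.integer(trees),
              folds = as.integer(folds),
              shap_top_k = as.integer(shap_top_k),
              shap_nrounds = as.integer(shap_nrounds),
              kernel = kernel, bandwidth = bandwidth,
              lambda_min = lambda_min, lambda_max = lambda_max,
              lambda_length = as.integer(lambda_length))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-17s %s\n", nm,
                if (is.null(x[[nm]])) "<median distance>"
                else paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

pipeline_log <- function(con, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  writeLines(line, con)
}

#' Run the two-track obesity-factor pipeline
#'
#' Orchestrates the full analysis on synthetic data with known ground truth:
#' generate districts, a district panel and individual records; exclude
#' no-response records and label obesity from BMI; screen features (iterative
#' VIF, then OLS); cross-validate the candidate classifiers and the
#' per-district classifier; rank per-district individual factors by Shapley
#' attribution; and fit the geographically weighted lasso to the district
#' panel. All artifacts are plain text and deterministic under a fixed
#' configuration.
#'
#' Artifacts written to `out_dir`: `config.json`, `panel.csv`,
#' `individuals.csv`, `centroids.geojson`, `screening.json`, `metrics.json`
#' (model comparison + per-district classifier metrics with a mean/sd total
#' row), `top5.csv` (per-district top-k Shapley features),
#' `gwlasso_summary.csv`, `coefficients.csv`, `coefficients.geojson`
#' (choropleth-ready per-district coefficients), and `run_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param truth optional [synthetic_truth()] override; defaults to the
#'   package's standard study conditions at `config$seed`.
#' @return Invisibly, a list with the in-memory stage results and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  paths <- list(log = log_path)

  pipeline_log(con, "pipeline start (seed %d, %d districts, %d individuals)",
               config$seed, config$n_districts, config$n_individuals)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  paths$config <- file.path(out_dir, "config.json")

  ## -- synthesis ------------------------------------------------------------
  if (is.null(truth)) truth <- synthetic_truth(seed = config$seed)
  districts <- generate_districts(config$n_districts, seed = config$seed)
  panel <- generate_district_panel(districts, truth)
  individuals <- generate_individual_records(
    config$n_individuals, truth, districts = districts,
    no_response_rate = config$no_response_rate,
    no_response_code = config$no_response_codes[1])
  paths$panel <- write_table_csv(panel, file.path(out_dir, "panel.csv"))
  paths$individuals <- write_table_csv(individuals,
                                       file.path(out_dir, "individuals.csv"))
  paths$centroids <- write_geojson_points(districts,
                                          file.path(out_dir, "centroids.geojson"))
  pipeline_log(con, "synthesis: %d districts, %d individual records",
               nrow(panel), nrow(individuals))

  ## -- preprocessing --------------------------------------------------------
  clean <- drop_no_response(individuals,
                            no_response_codes = config$no_response_codes)
  clean$bmi <- compute_bmi(clean$height_m, clean$weight_kg)
  clean$obese <- label_obesity(clean$bmi, threshold = config$bmi_threshold)
  pipeline_log(con, "preprocess: %d records kept (%d no-response excluded); prevalence %.3f",
               nrow(clean), attr(clean, "n_dropped") %||% 0, mean(clean$obese))

  ## -- feature screening ----------------------------------------------------
  feats <- individual_feature_names(clean)
  screen <- screen_features(clean[, feats, drop = FALSE], clean$obese,
                            threshold = config$vif_threshold,
                            alpha = config$alpha)
  features <- names(screen$X)
  jsonlite::write_json(
    list(vif_removed = screen$vif_report$removal_order,
         vif = as.list(screen$vif_report$vif),
         ols_p_values = as.list(screen$ols_report$p_values),
         selected = features),
    file.path(out_dir, "screening.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$screening <- file.path(out_dir, "screening.json")
  pipeline_log(con, "screening: VIF>%g removed [%s]; OLS alpha=%g dropped [%s]; %d features kept",
               config$vif_threshold,
               paste(screen$vif_report$removal_order, collapse = ", "),
               config$alpha,
               paste(screen$ols_report$dropped, collapse = ", "),
               length(features))

  ## -- classification -------------------------------------------------------
  specs <- list(model_spec("logistic"),
                model_spec("random_forest", trees = config$trees),
                model_spec("xgboost", nrounds = config$shap_nrounds),
                model_spec("gradient_boosting", nrounds = config$shap_nrounds))
  comparison <- compare_models(clean, specs, k = config$folds,
                               seed = derive_seed(config$seed, "compare"),
                               features = features)
  pipeline_log(con, "model comparison (pooled accuracy): %s",
               paste(sprintf("%s %.3f", comparison$ranking$model,
                             comparison$ranking$accuracy), collapse = "; "))

  district_spec <- model_spec(config$classifier, trees = config$trees,
                              nrounds = config$shap_nrounds)
  per_district <- lapply(split(clean, clean$district_id), function(dd) {
    cv <- kfold_cv(dd, district_spec, k = config$folds,
                   seed = derive_seed(config$seed, dd$district_id[1]),
                   features = features)
    data.frame(district_id = dd$district_id[1],
               n = nrow(dd),
               accuracy = cv$pooled$accuracy, precision = cv$pooled$precision,
               recall = cv$pooled$recall, f1 = cv$pooled$f1)
  })
  per_district <- do.call(rbind, per_district)
  rownames(per_district) <- NULL
  total <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1"),
    mean = colMeans(per_district[, c("accuracy", "precision", "recall", "f1")],
                    na.rm = TRUE),
    sd = apply(per_district[, c("accuracy", "precision", "recall", "f1")], 2,
               sd, na.rm = TRUE),
    row.names = NULL)
  jsonlite::write_json(list(comparison = comparison$ranking,
                            per_district = per_district,
                            total = total),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  paths$metrics <- file.path(out_dir, "metrics.json")
  pipeline_log(con, "per-district %s: mean accuracy %.3f (sd %.3f)",
               district_spec$label, total$mean[1], total$sd[1])

  ## -- Shapley ranking ------------------------------------------------------
  shap_spec <- model_spec("gradient_boosting", nrounds = config$shap_nrounds)
  top_rows <- lapply(split(clean, clean$district_id), function(dd) {
    bal <- random_oversample(dd, seed = derive_seed(config$seed,
                                                    paste0("shap-", dd$district_id[1])))
    mod <- fit_classifier(shap_spec, bal, features = features,
                          seed = derive_seed(config$seed, "shap-fit"))
    rk <- rank_features(compute_shap(mod, dd), district_id = dd$district_id[1])
    rk[rk$rank <= config$shap_top_k, , drop = FALSE]
  })
  top5 <- do.call(rbind, top_rows)
  rownames(top5) <- NULL
  paths$top5 <- write_table_csv(top5, file.path(out_dir, "top5.csv"))
  lead <- top5$feature[top5$rank == 1]
  pipeline_log(con, "shapley: leading factor is %s in %d of %d districts",
               names(which.max(table(lead))), max(table(lead)), length(lead))

  ## -- geographically weighted lasso ---------------------------------------
  gw <- fit_gwlasso(panel,
                    spec = kernel_spec(config$kernel, config$bandwidth),
                    grid = default_lambda_grid(config$lambda_min,
                                               config$lambda_max,
                                               config$lambda_length))
  summ <- summarize_coefficients(gw)
  paths$gwlasso_summary <- write_table_csv(summ,
                                           file.path(out_dir, "gwlasso_summary.csv"))
  coefs <- data.frame(district_id = rep(gw$district_id, length(gw$factors)),
                      factor = rep(gw$factors, each = length(gw$district_id)),
                      beta = as.vector(gw$beta),
                      beta_raw = as.vector(gw$beta_raw),
                      lambda = rep(gw$lambda, length(gw$factors)))
  paths$coefficients <- write_table_csv(coefs,
                                        file.path(out_dir, "coefficients.csv"))
  geo <- cbind(districts, as.data.frame(gw$beta))
  paths$coefficients_geojson <- write_geojson_points(
    geo, file.path(out_dir, "coefficients.geojson"),
    properties = c("population", gw$factors))
  pipeline_log(con, "gwlasso: bandwidth %.4g; %s",
               gw$bandwidth,
               paste(sprintf("%s mean %.3f (POS %d, NEG %d)", summ$feature,
                             summ$mean, summ$pos, summ$neg), collapse = "; "))
  pipeline_log(con, "pipeline done")

  invisible(list(config = config, truth = truth, panel = panel,
                 individuals = individuals, clean = clean, screen = screen,
                 comparison = comparison, per_district = per_district,
                 total = total, top5 = top5, gwlasso = gw, summary = summ,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
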