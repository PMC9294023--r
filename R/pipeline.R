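#' Run the full subtyping pipeline
#'
#' Orchestrates ingest (or simulation), validation, TIV normalisation,
#' bilateral reduction, composite ROI scoring, two-step clustering,
#' predictor-importance ranking and post-hoc cluster profiling, optionally
#' writing every intermediate artifact to disk.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   * `input`: list of `thickness`, `volumes`, `fa`, `metadata` CSV paths, or
#'   * `generator`: list with optional `n_subjects` and further overrides of
#'     [default_cohort_params()] — exactly one of `input`/`generator`;
#'   * `roi_file`: optional path to ROI definitions (default shipped file);
#'   * `clustering`: optional list (`bypass_tree`, `k`, `k_max`, `c1`, `c2`,
#'     `refine`);
#'   * `seed`: integer, used for simulation (default 1);
#'   * `out_dir`: optional output directory for artifacts.
#' @return An `als_report`: list with `cluster_sizes`, `cluster_percent`,
#'   `silhouette`, `bic` trace, `importance`, `profile`, `fit`, `scores` and
#'   `provenance` (seed, package version, config hash).
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(generator = list(n_subjects = 80), seed = 3))
#' rep$cluster_percent
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen) {
    stop("config must set exactly one of 'input' and 'generator'", call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  if (has_input) {
    with_paths <- config$input
    cohort <- read_cohort(with_paths$thickness, with_paths$volumes,
                          with_paths$fa, with_paths$metadata)
    latent <- NULL
  } else {
    params <- default_cohort_params()
    for (nm in setdiff(names(config$generator), "")) {
      params[[nm]] <- config$generator[[nm]]
    }
    sim <- simulate_cohort(params, seed = seed)
    cohort <- sim$cohort
    latent <- sim$latent
  }

  report_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- report_stage("validate", {
    v <- validate_cohort(cohort)
    if (!v$pass) drop_invalid_subjects(cohort, v) else cohort
  })
  cohort <- report_stage("normalize", normalize_volumes(cohort))
  features <- report_stage("reduce", reduce_bilateral(cohort))
  rois <- if (is.null(config$roi_file)) roi_definitions() else
    roi_definitions(config$roi_file)
  scores <- report_stage("score", composite_scores(features, rois))

  cl <- if (is.null(config$clustering)) list() else config$clustering
  # exact [[ indexing: $ would partial-match "k" to "k_max"
  fit <- report_stage("cluster", cluster_twostep(
    scores,
    k = cl[["k"]],
    bypass_tree = if (is.null(cl[["bypass_tree"]])) TRUE else isTRUE(cl[["bypass_tree"]]),
    k_max = if (is.null(cl[["k_max"]])) 15 else cl[["k_max"]],
    c1 = if (is.null(cl[["c1"]])) 0.04 else cl[["c1"]],
    c2 = if (is.null(cl[["c2"]])) 1.15 else cl[["c2"]],
    refine = isTRUE(cl[["refine"]])
  ))

  importance <- NULL
  profile <- NULL
  if (fit$k >= 2) {
    importance <- report_stage("importance", predictor_importance(scores, fit))
    profile <- report_stage("profile", cluster_profile(cohort$metadata, fit))
  }

  pct <- 100 * fit$cluster_sizes / fit$n
  report <- structure(list(
    k = fit$k,
    cluster_sizes = fit$cluster_sizes,
    cluster_percent = pct,
    silhouette = fit$silhouette,
    bic = fit$bic,
    importance = importance,
    profile = profile,
    fit = fit,
    scores = scores,
    latent = latent,
    provenance = list(seed = seed,
                      package_version = as.character(utils::packageVersion("alsclust")),
                      config_hash = rlang::hash(config))
  ), class = "als_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.als_report <- function(x, ...) {
  cat("<als_report> k=", x$k, "; sizes [",
      paste(x$cluster_sizes, collapse = ", "), "] (",
      paste(sprintf("%.1f%%", x$cluster_percent), collapse = ", "), ")",
      sep = "")
  if (!is.na(x$silhouette)) cat("; mean silhouette ", round(x$silhouette, 3), sep = "")
  cat("\n")
  if (!is.null(x$importance)) {
    cat("Top ROIs by importance: ",
        paste(utils::head(x$importance$roi, 3), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes the composite scores (+ scaling), cluster assignments, importance
#' table and a JSON report (sizes, percentages, silhouette, BIC trace,
#' tests, provenance).
#'
#' @param report An `als_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scores(report$scores, file.path(dir, "composite_scores.csv"),
               file.path(dir, "scaling_params.csv"))
  readr::write_csv(report$fit$assignments, file.path(dir, "assignments.csv"))
  if (!is.null(report$importance)) {
    readr::write_csv(tibble::as_tibble(report$importance),
                     file.path(dir, "importance.csv"))
  }
  json <- list(
    k = report$k,
    cluster_sizes = report$cluster_sizes,
    cluster_percent = report$cluster_percent,
    silhouette = report$silhouette,
    bic = report$bic,
    tests = if (!is.null(report$profile)) report$profile$tests,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
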