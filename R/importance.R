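#' Predictor importance of the ROI scores
#'
#' Ranks the 15 regional scores by how well they separate the clusters.
#' Each ROI is tested with a one-way ANOVA F across clusters (for two
#' clusters this is the pooled-variance t-test squared) and importance is
#' the max-normalised negative log p-value:
#' `importance_v = (-log10 p_v) / max_w (-log10 p_w)`, so the most
#' discriminating ROI scores exactly 1 and undiscriminating ROIs score near
#' 0. p-values are floored at 1e-300 before the transform.
#'
#' @param scores An `als_scores` tibble (or numeric matrix) used for
#'   clustering.
#' @param cluster Integer cluster labels (at least 2 clusters, every
#'   cluster with at least 2 members), or a `twostep_fit`.
#' @return An `als_importance` tibble with columns `roi`, `statistic` (F),
#'   `p.value`, `importance`, `rank`, sorted by decreasing importance (ties
#'   broken alphabetically, with a message).
#' @examples
#' coh <- simulate_cohort(n_subjects = 60, seed = 7)$cohort
#' scores <- composite_scores(reduce_bilateral(normalize_volumes(coh)))
#' fit <- cluster_twostep(scores, k = 2)
#' predictor_importance(scores, fit)
#' @export
predictor_importance <- function(scores, cluster) {
  x <- if (is.matrix(scores)) scores else score_matrix(scores)
  if (inherits(cluster, "twostep_fit")) cluster <- cluster$assignments$cluster
  g <- factor(cluster)
  if (nlevels(g) < 2) stop("importance requires at least 2 clusters", call. = FALSE)
  if (any(table(g) < 2)) stop("every cluster needs at least 2 members", call. = FALSE)
  res <- purrr::map_dfr(colnames(x), function(v) {
    vals <- x[, v]
    if (stats::var(vals) == 0) {
      return(tibble::tibble(roi = v, statistic = 0, p.value = 1))
    }
    ow <- stats::oneway.test(vals ~ g, var.equal = TRUE)
    f <- unname(ow$statistic)
    p <- unname(ow$p.value)
    if (!is.finite(f)) { f <- Inf; p <- 0 }  # zero within-cluster variance
    tibble::tibble(roi = v, statistic = f, p.value = max(p, 1e-300))
  })
  neglogp <- -log10(res$p.value)
  res$importance <- if (max(neglogp) > 0) neglogp / max(neglogp) else rep(0, nrow(res))
  ranked <- rank_predictors(res)
  structure(ranked, class = c("als_importance", class(ranked)))
}

#' Order ROIs by importance
#'
#' @param table A tibble with at least `roi` and `importance` columns.
#' @return The table sorted by decreasing importance with a `rank` column
#'   (1 = most important). Ties are broken alphabetically by ROI name and
#'   flagged with a message.
#' @export
rank_predictors <- function(table) {
  if (anyDuplicated(table$importance)) {
    message("ties in importance broken alphabetically by ROI name")
  }
  out <- dplyr::arrange(table, dplyr::desc(.data$importance), .data$roi)
  out$rank <- seq_len(nrow(out))
  out
}
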