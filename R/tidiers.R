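#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a two-step clustering fit
#'
#' @param x A `twostep_fit`.
#' @param ... Unused.
#' @return A tibble with one row per subject: `subject_id`, `cluster`, and
#'   (when k >= 2) the per-subject `silhouette` width.
#' @export
tidy.twostep_fit <- function(x, ...) {
  out <- x$assignments
  if (x$k >= 2) {
    out$silhouette <- silhouette_widths(x$scores_matrix, x$assignments$cluster)
  }
  out
}

#' One-row summary of a two-step clustering fit
#'
#' @param x A `twostep_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `k`, `n_preclusters`, `silhouette`,
#'   `bic` (at the selected k) and `smaller_cluster_pct`.
#' @export
glance.twostep_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    k = x$k,
    n_preclusters = x$n_preclusters,
    silhouette = x$silhouette,
    bic = x$bic$bic[x$bic$k == x$k],
    smaller_cluster_pct = 100 * min(x$cluster_sizes) / x$n
  )
}

#' Tidy a between-cluster test
#'
#' @param x An `als_test`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
tidy.als_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = as.numeric(x$df),
                 p.value = x$p.value, method = x$method)
}

#' Tidy a cluster profile
#'
#' @param x A `cluster_profile`.
#' @param ... Unused.
#' @return The tibble of between-cluster tests.
#' @export
tidy.cluster_profile <- function(x, ...) x$tests

#' One-row-per-cluster summary of a profile
#'
#' @param x A `cluster_profile`.
#' @param ... Unused.
#' @return A tibble with `cluster` and `n`.
#' @export
glance.cluster_profile <- function(x, ...) {
  n_rows <- x$descriptives[x$descriptives$variable == "n", ]
  tibble::tibble(cluster = n_rows$cluster, n = n_rows$count)
}
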