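#' Min-max scale a vector to the unit interval
#'
#' `scaled_i = (x_i - min) / (max - min)`. Scaling is cohort-level: the
#' extremes are taken over the supplied values, so the cohort minimum maps
#' to 0 and the maximum to 1. The output is invariant to positive affine
#' transformations of the input.
#'
#' @param x Numeric vector, length >= 2, not constant, no missing values.
#' @return A list with `scaled` (vector in \[0, 1\]), `min` and `max`.
#' @examples
#' min_max_scale(c(1, 2, 3))$scaled  # 0.0 0.5 1.0
#' @export
min_max_scale <- function(x) {
  if (anyNA(x)) stop("missing values in input to min-max scaling", call. = FALSE)
  if (length(x) < 2) stop("min-max scaling needs at least 2 values", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot min-max scale a constant vector", call. = FALSE)
  list(scaled = (x - lo) / (hi - lo), min = lo, max = hi)
}

apply_min_max <- function(x, lo, hi) (x - lo) / (hi - lo)

#' Raw grey- and white-matter indices for one ROI
#'
#' Sums the ROI's member columns into its unscaled indices: the grey-matter
#' index is the row-wise sum of the thickness (or TIV-fraction volume)
#' members, and the white-matter index the row-wise sum of the FA members.
#' In `separate` mode (long association fibres) each FA member is kept as
#' its own index instead of being pooled.
#'
#' @param features An `als_features` tibble from [reduce_bilateral()].
#' @param roi One row of [roi_definitions()] (or an equivalent list with
#'   `roi`, `gm_kind`, `gm_members`, `wm_mode`, `wm_members`).
#' @return A list with `gm` (numeric vector, or `NULL` when the ROI has no
#'   grey-matter members) and `wm` (named list of numeric vectors; one
#'   element when pooled, one per member when separate).
#' @export
roi_raw_indices <- function(features, roi) {
  gm_members <- unlist(roi$gm_members)
  wm_members <- unlist(roi$wm_members)
  wm_mode <- roi$wm_mode[[1]]
  missing <- setdiff(c(gm_members, wm_members), names(features))
  if (length(missing)) {
    stop("ROI '", roi$roi[[1]], "' references missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  row_sum <- function(cols) {
    if (length(cols) == 1) return(features[[cols]])
    rowSums(as.matrix(features[cols]))
  }
  gm <- if (length(gm_members)) row_sum(gm_members) else NULL
  wm <- if (identical(wm_mode, "pooled")) {
    stats::setNames(list(row_sum(wm_members)), "wm")
  } else {
    stats::setNames(lapply(wm_members, function(col) features[[col]]), wm_members)
  }
  list(gm = gm, wm = wm)
}

#' Composite regional integrity scores
#'
#' Computes the N x 15 matrix of composite disease-burden scores that feeds
#' the cluster analysis. For each ROI two indices are formed — the summed
#' grey-matter metric and the summed FA metric (the long association ROI
#' uses its two FA members as the two indices) — each min-max scaled to
#' \[0, 1\] over the cohort and then added, giving a score from 0 (cohort-worst
#' on both indices) to 2 (cohort-best on both). Higher scores indicate
#' superior regional integrity.
#'
#' The cohort-level scaling extremes are recorded in the `scaling` attribute
#' so new subjects can be projected onto a frozen score space by passing
#' that table back via `scaling`.
#'
#' @param features An `als_features` tibble from [reduce_bilateral()].
#' @param rois ROI definitions, see [roi_definitions()].
#' @param scaling Optional frozen scaling table (as found in the `scaling`
#'   attribute of a previous result); when supplied, its extremes are used
#'   instead of recomputing them, and scores may leave \[0, 2\].
#' @return An `als_scores` tibble: `subject_id` plus one column per ROI in
#'   canonical order, with attribute `scaling` (tibble `roi`, `index`,
#'   `min`, `max`).
#' @examples
#' coh <- simulate_cohort(n_subjects = 30, seed = 1)$cohort
#' scores <- composite_scores(reduce_bilateral(normalize_volumes(coh)))
#' range(as.matrix(scores[-1]))  # within [0, 2]
#' @export
composite_scores <- function(features, rois = roi_definitions(), scaling = NULL) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  out <- tibble::tibble(subject_id = features$subject_id)
  scale_rows <- list()
  frozen <- function(roi, index) {
    row <- scaling[scaling$roi == roi & scaling$index == index, ]
    if (nrow(row) != 1) stop("no frozen scaling for ", roi, "/", index, call. = FALSE)
    row
  }
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    idx <- roi_raw_indices(features, roi)
    indices <- c(if (!is.null(idx$gm)) list(gm = idx$gm), idx$wm)
    score <- 0
    for (nm in names(indices)) {
      if (is.null(scaling)) {
        sc <- min_max_scale(indices[[nm]])
        scaled <- sc$scaled; lo <- sc$min; hi <- sc$max
      } else {
        row <- frozen(roi$roi[[1]], nm)
        lo <- row$min; hi <- row$max
        scaled <- apply_min_max(indices[[nm]], lo, hi)
      }
      score <- score + scaled
      scale_rows[[length(scale_rows) + 1]] <-
        tibble::tibble(roi = roi$roi[[1]], index = nm, min = lo, max = hi)
    }
    out[[roi$roi[[1]]]] <- score
  }
  structure(out, scaling = dplyr::bind_rows(scale_rows),
            class = c("als_scores", class(out)))
}

#' Matrix view of a score table
#'
#' @param scores An `als_scores` tibble.
#' @return Numeric matrix (subjects x ROIs) with subject ids as row names.
#' @export
score_matrix <- function(scores) {
  m <- as.matrix(scores[setdiff(names(scores), "subject_id")])
  rownames(m) <- scores$subject_id
  m
}

#' Write composite scores (and their scaling parameters) to CSV
#'
#' @param scores An `als_scores` tibble.
#' @param path Output CSV path for the scores.
#' @param scaling_path Optional CSV path for the min/max scaling table.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, scaling_path = NULL) {
  readr::write_csv(tibble::as_tibble(scores), path)
  if (!is.null(scaling_path)) {
    readr::write_csv(attr(scores, "scaling"), scaling_path)
  }
  invisible(path)
}
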