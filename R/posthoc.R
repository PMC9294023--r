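# Post-hoc contrasts of demographic, clinical and genetic profiles between
# clusters. 2x2 tables use the continuity-corrected (Yates) chi-square;
# larger tables use the uncorrected Pearson chi-square, optionally treating
# missingness (unscreened genotype, unassessed ECAS) as its own category.
# Both are computed by stats::chisq.test behind this module's interface.

new_als_test <- function(statistic, df, p.value, method, corrected, table = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p.value = unname(p.value), method = method,
                 corrected = corrected, table = table),
            class = "als_test")
}

#' @export
print.als_test <- function(x, ...) {
  cat("<als_test> ", x$method, ": statistic=", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df=", x$df), ", p=", signif(x$p.value, 4),
      "\n", sep = "")
  invisible(x)
}

check_table <- function(table, square_2x2 = FALSE) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  }
  if (square_2x2 && !all(dim(table) == c(2, 2))) {
    stop("table must be 2x2", call. = FALSE)
  }
  if (any(dim(table) < 2)) stop("table needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  table
}

#' Continuity-corrected chi-square for a 2x2 table
#'
#' Yates-corrected test: `chi2 = sum((|O - E| - 0.5)^2 / E)` with the
#' correction capped so it never exceeds `|O - E|`; df = 1, p from the
#' upper chi-square tail.
#'
#' @param table 2x2 matrix of counts (clusters x categories).
#' @return An `als_test` with `statistic`, `df`, `p.value`.
#' @examples
#' yates_chisq(matrix(c(54, 22, 86, 52), nrow = 2, byrow = TRUE))  # ~1.29
#' @export
yates_chisq <- function(table) {
  table <- check_table(table, square_2x2 = TRUE)
  res <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  new_als_test(res$statistic, res$parameter, res$p.value,
               "chi-square (Yates continuity correction)", TRUE, table)
}

#' Pearson chi-square for an r x c table
#'
#' Uncorrected Pearson test: `chi2 = sum((O - E)^2 / E)`,
#' df = (r - 1)(c - 1). Used for tables beyond 2x2, where no continuity
#' correction applies.
#'
#' @param table r x c matrix of counts, r, c >= 2.
#' @return An `als_test`.
#' @export
pearson_chisq <- function(table) {
  table <- check_table(table)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_als_test(res$statistic, res$parameter, res$p.value,
               "Pearson chi-square", FALSE, table)
}

#' Cross-tabulate a categorical variable against cluster membership
#'
#' @param metadata Metadata tibble with `subject_id`.
#' @param assignments Tibble `subject_id`, `cluster` (e.g. from a
#'   `twostep_fit`), or a `twostep_fit`.
#' @param variable Name of a categorical metadata column.
#' @param missing_policy `"drop"` removes subjects with a missing value;
#'   `"as_category"` keeps them as an explicit `"missing"` column (the
#'   convention used for unscreened genotype and unassessed ECAS).
#' @return A `ContingencyTable`-style integer matrix (clusters x
#'   categories) with dimnames.
#' @export
build_contingency <- function(metadata, assignments, variable,
                              missing_policy = c("drop", "as_category")) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(assignments, "twostep_fit")) assignments <- assignments$assignments
  if (!variable %in% names(metadata)) {
    stop("unknown metadata variable: ", variable, call. = FALSE)
  }
  joined <- dplyr::inner_join(metadata[, c("subject_id", variable)],
                              assignments, by = "subject_id")
  vals <- as.character(joined[[variable]])
  if (missing_policy == "drop") {
    keep <- !is.na(vals)
    joined <- joined[keep, ]; vals <- vals[keep]
  } else {
    vals[is.na(vals)] <- "missing"
  }
  lev <- if (is.factor(metadata[[variable]])) {
    c(intersect(levels(metadata[[variable]]), vals),
      if ("missing" %in% vals) "missing")
  } else {
    c(sort(setdiff(unique(vals), "missing")), if ("missing" %in% vals) "missing")
  }
  tab <- table(cluster = joined$cluster, category = factor(vals, levels = lev))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(cluster = rownames(tab), category = colnames(tab)))
  m
}

#' Two-sample test of a continuous variable between two clusters
#'
#' @param metadata Metadata tibble with `subject_id`.
#' @param assignments Tibble `subject_id`, `cluster`, or a `twostep_fit`;
#'   exactly two clusters required.
#' @param variable Name of a numeric metadata column.
#' @param method `"welch"` (default, unequal variances) or `"student"`
#'   (pooled variance).
#' @return An `als_test` with the t statistic, df and two-sided p-value.
#' @export
compare_continuous <- function(metadata, assignments, variable,
                               method = c("welch", "student")) {
  method <- match.arg(method)
  if (inherits(assignments, "twostep_fit")) assignments <- assignments$assignments
  if (!variable %in% names(metadata)) {
    stop("unknown metadata variable: ", variable, call. = FALSE)
  }
  joined <- dplyr::inner_join(metadata[, c("subject_id", variable)],
                              assignments, by = "subject_id")
  joined <- joined[!is.na(joined[[variable]]), ]
  labs <- sort(unique(joined$cluster))
  if (length(labs) != 2) stop("continuous comparison requires exactly 2 clusters", call. = FALSE)
  x <- joined[[variable]][joined$cluster == labs[1]]
  y <- joined[[variable]][joined$cluster == labs[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("both clusters need at least 2 non-missing values", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = method == "student")
  new_als_test(res$statistic, res$parameter, res$p.value,
               paste0(if (method == "welch") "Welch" else "Student", " two-sample t-test"),
               FALSE)
}

#' Per-cluster clinical and genetic profile
#'
#' Summarises each cluster (n, mean +/- SD for continuous variables, count
#' and percent for categorical ones) and, when there are at least two
#' clusters, runs the pairwise tests: Welch t-tests for continuous
#' variables, Yates 2x2 chi-square for binary categoricals, Pearson r x c
#' chi-square otherwise. Variables listed in `missing_as_category` keep
#' missingness as an explicit category (default: genotype and ECAS, whose
#' screening gaps are informative); elsewhere missing values are dropped.
#'
#' @param metadata Metadata tibble with `subject_id`.
#' @param assignments Tibble `subject_id`, `cluster`, or a `twostep_fit`.
#' @param continuous,categorical Metadata columns to summarise; defaults
#'   cover the standard clinical set, intersected with what is present.
#' @param missing_as_category Categorical variables whose `NA` becomes a
#'   `"missing"` category.
#' @return A `cluster_profile`: list with `descriptives` (tibble `cluster`,
#'   `variable`, `summary`, plus the numeric pieces) and `tests` (tibble
#'   `variable`, `method`, `statistic`, `df`, `p.value`).
#' @export
cluster_profile <- function(metadata, assignments,
                            continuous = c("age", "education", "alsfrs_r"),
                            categorical = c("sex", "handedness", "onset_site",
                                            "ecas_impaired", "als_ftd", "c9orf72"),
                            missing_as_category = c("c9orf72", "ecas_impaired")) {
  if (inherits(assignments, "twostep_fit")) assignments <- assignments$assignments
  continuous <- intersect(continuous, names(metadata))
  categorical <- intersect(categorical, names(metadata))
  joined <- dplyr::inner_join(metadata, assignments, by = "subject_id")
  labs <- sort(unique(joined$cluster))

  desc <- list()
  for (lab in labs) {
    sub <- joined[joined$cluster == lab, ]
    n <- nrow(sub)
    desc[[length(desc) + 1]] <- tibble::tibble(
      cluster = lab, variable = "n", level = NA_character_,
      mean = NA_real_, sd = NA_real_, count = n, percent = NA_real_,
      summary = as.character(n))
    for (v in continuous) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      desc[[length(desc) + 1]] <- tibble::tibble(
        cluster = lab, variable = v, level = NA_character_,
        mean = mean(vals), sd = stats::sd(vals), count = length(vals),
        percent = NA_real_,
        summary = sprintf("%.1f ± %.1f", mean(vals), stats::sd(vals)))
    }
    for (v in categorical) {
      vals <- as.character(sub[[v]])
      for (lev in sort(unique(vals[!is.na(vals)]))) {
        cnt <- sum(vals == lev, na.rm = TRUE)
        pct <- 100 * cnt / n
        desc[[length(desc) + 1]] <- tibble::tibble(
          cluster = lab, variable = v, level = lev,
          mean = NA_real_, sd = NA_real_, count = cnt, percent = pct,
          summary = sprintf("%d (%.1f%%)", cnt, pct))
      }
    }
  }
  desc <- dplyr::bind_rows(desc)

  tests <- tibble::tibble(variable = character(), method = character(),
                          statistic = numeric(), df = numeric(),
                          p.value = numeric())
  if (length(labs) >= 2) {
    rows <- list()
    if (length(labs) == 2) {
      for (v in continuous) {
        t <- compare_continuous(metadata, assignments, v)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, method = t$method, statistic = t$statistic,
          df = t$df, p.value = t$p.value)
      }
    }
    for (v in categorical) {
      policy <- if (v %in% missing_as_category) "as_category" else "drop"
      tab <- build_contingency(metadata, assignments, v, policy)
      if (any(dim(tab) < 2)) next  # degenerate: a single observed category
      t <- if (all(dim(tab) == c(2, 2))) yates_chisq(tab) else pearson_chisq(tab)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, method = t$method, statistic = t$statistic,
        df = as.numeric(t$df), p.value = t$p.value)
    }
    if (length(rows)) tests <- dplyr::bind_rows(rows)
  }
  structure(list(descriptives = desc, tests = tests, clusters = labs),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  for (lab in x$clusters) {
    sub <- x$descriptives[x$descriptives$cluster == lab, ]
    n <- sub$summary[sub$variable == "n"]
    cat("Cluster ", lab, " (n = ", n, ")\n", sep = "")
    for (i in seq_len(nrow(sub))) {
      if (sub$variable[i] == "n") next
      lab_txt <- if (is.na(sub$level[i])) sub$variable[i] else
        paste0(sub$variable[i], "=", sub$level[i])
      cat("  ", format(lab_txt, width = 28), sub$summary[i], "\n")
    }
  }
  if (nrow(x$tests)) {
    cat("Between-cluster tests:\n")
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("  %-14s %-40s stat=%6.2f  p=%.4g\n", x$tests$variable[i],
                  x$tests$method[i], x$tests$statistic[i], x$tests$p.value[i]))
    }
  }
  invisible(x)
}
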