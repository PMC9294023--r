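#' Construct a raw cohort from in-memory tables
#'
#' Bundles the three metric tables, the total intracranial volume (TIV) and
#' the clinical/genetic metadata into a single cohort object, checking that
#' all tables cover the same subjects in the same order. This is the
#' programmatic entry point; [read_cohort()] builds the same object from CSV
#' files.
#'
#' @param thickness Data frame with `subject_id` and the 68 cortical
#'   thickness columns (mm).
#' @param volumes Data frame with `subject_id` and the 25 volumetric columns
#'   (mm^3, or TIV-fractions if `volumes_unit = "tiv_fraction"`).
#' @param tiv Numeric vector of total intracranial volumes (mm^3), one per
#'   subject in table row order.
#' @param fa Data frame with `subject_id` and the 40 fractional anisotropy
#'   columns (unitless, each in \[0, 1\]).
#' @param metadata Data frame with `subject_id` and clinical/genetic columns
#'   (`age`, `sex`, `handedness`, `education`, `onset_site`, `alsfrs_r`,
#'   `ecas_impaired`, `als_ftd`, `c9orf72`); unknown genotype or unassessed
#'   ECAS are encoded `NA`.
#' @param volumes_unit `"mm3"` for raw volumes or `"tiv_fraction"` after
#'   normalisation.
#' @param vocab Column vocabulary, see [metric_vocabulary()].
#' @return An object of class `als_cohort`: a list with elements
#'   `subject_ids`, `thickness`, `volumes`, `tiv`, `fa`, `metadata` and a
#'   `volumes_unit` attribute.
#' @export
als_cohort <- function(thickness, volumes, tiv, fa, metadata,
                       volumes_unit = "mm3", vocab = metric_vocabulary()) {
  thickness <- tibble::as_tibble(thickness)
  volumes <- tibble::as_tibble(volumes)
  fa <- tibble::as_tibble(fa)
  metadata <- tibble::as_tibble(metadata)
  ids <- as.character(thickness$subject_id)
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  for (tab in list(volumes, fa, metadata)) {
    if (!identical(as.character(tab$subject_id), ids)) {
      stop("tables are not aligned on the same subjects in the same order", call. = FALSE)
    }
  }
  if (length(tiv) != length(ids)) stop("tiv length does not match subject count", call. = FALSE)
  check_metric_columns(thickness, "thickness", vocab)
  check_metric_columns(volumes, "volume", vocab)
  check_metric_columns(fa, "fa", vocab)
  out <- structure(
    list(subject_ids = ids, thickness = thickness, volumes = volumes,
         tiv = as.numeric(tiv), fa = fa, metadata = metadata),
    class = "als_cohort", volumes_unit = volumes_unit
  )
  out
}

check_metric_columns <- function(tab, modality, vocab) {
  expected <- raw_metric_columns(modality, vocab)
  missing <- setdiff(expected, names(tab))
  if (length(missing)) {
    stop(modality, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), c("subject_id", "tiv", expected))
  if (length(extra)) {
    stop(modality, " table has unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  not_num <- expected[!vapply(tab[expected], is.numeric, logical(1))]
  if (length(not_num)) {
    stop(modality, " table has non-numeric column(s): ",
         paste(not_num, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.als_cohort <- function(x, ...) {
  cat("<als_cohort> ", length(x$subject_ids), " subjects; volumes in ",
      attr(x, "volumes_unit"), "\n", sep = "")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Reads the thickness, volume, FA and metadata tables, validates their
#' column sets against the vocabulary, and aligns them on the subjects
#' common to all four files (inner join by `subject_id`; subjects absent
#' from any file are dropped with a warning naming them). The volume file
#' must carry the TIV in a `tiv` column.
#'
#' @param thickness_path,volumes_path,fa_path,metadata_path Paths to UTF-8
#'   CSV files with a header row and `subject_id` as first column. Missing
#'   values are an empty cell or `NA`.
#' @param vocab Column vocabulary, see [metric_vocabulary()].
#' @return An `als_cohort` object (volumes in mm^3).
#' @seealso [validate_cohort()], [normalize_volumes()], [reduce_bilateral()]
#' @export
read_cohort <- function(thickness_path, volumes_path, fa_path, metadata_path,
                        vocab = metric_vocabulary()) {
  paths <- c(thickness_path, volumes_path, fa_path, metadata_path)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stop("file not found: ", paste(absent, collapse = ", "), call. = FALSE)

  read_one <- function(path) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           na = c("", "NA"))
    if (names(tab)[1] != "subject_id") {
      stop("first column of ", path, " must be 'subject_id'", call. = FALSE)
    }
    tab$subject_id <- as.character(tab$subject_id)
    if (anyDuplicated(tab$subject_id)) {
      stop("duplicate subject id(s) in ", path, ": ",
           paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "),
           call. = FALSE)
    }
    tab
  }
  thickness <- read_one(thickness_path)
  volumes <- read_one(volumes_path)
  fa <- read_one(fa_path)
  metadata <- read_one(metadata_path)

  if (!"tiv" %in% names(volumes)) {
    stop("volume table is missing the 'tiv' column", call. = FALSE)
  }
  # non-numeric cells in metric tables surface as parser-coerced character cols
  for (spec in list(list(thickness, "thickness"), list(volumes, "volume"), list(fa, "fa"))) {
    bad <- intersect(raw_metric_columns(spec[[2]], vocab), names(spec[[1]]))
    bad <- bad[!vapply(spec[[1]][bad], is.numeric, logical(1))]
    if (length(bad)) {
      stop(spec[[2]], " table has non-numeric value(s) in: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  common <- Reduce(intersect, list(thickness$subject_id, volumes$subject_id,
                                   fa$subject_id, metadata$subject_id))
  all_ids <- unique(c(thickness$subject_id, volumes$subject_id,
                      fa$subject_id, metadata$subject_id))
  dropped <- setdiff(all_ids, common)
  if (length(common) == 0) stop("no subjects common to all four tables", call. = FALSE)
  if (length(dropped)) {
    warning("dropped ", length(dropped), " subject(s) absent from at least one table: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  align <- function(tab) tab[match(common, tab$subject_id), , drop = FALSE]
  volumes <- align(volumes)
  als_cohort(
    thickness = align(thickness),
    volumes = volumes[setdiff(names(volumes), "tiv")],
    tiv = volumes$tiv,
    fa = align(fa),
    metadata = align(metadata),
    vocab = vocab
  )
}

#' Validate a cohort's metric values
#'
#' Screens the cohort for missing metric cells and out-of-range values
#' (non-positive thickness or TIV, FA outside \[0, 1\]) and returns a report.
#' Subjects with any violation are listed so they can be excluded; the
#' pipeline rejects rather than imputes incomplete metric data.
#'
#' @param cohort An `als_cohort`.
#' @return A list of class `cohort_validation` with a tibble of `issues`
#'   (`table`, `subject_id`, `column`, `problem`), the vector of
#'   `offending_subjects`, and a logical `pass` (`TRUE` iff no issues).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "als_cohort"))
  issues <- list()
  add <- function(table, ids, column, problem) {
    if (length(ids)) {
      issues[[length(issues) + 1]] <<- tibble::tibble(
        table = table, subject_id = ids, column = column, problem = problem)
    }
  }
  scan <- function(tab, table, check, problem) {
    for (col in setdiff(names(tab), "subject_id")) {
      x <- tab[[col]]
      add(table, cohort$subject_ids[is.na(x)], col, "missing")
      bad <- !is.na(x) & !check(x)
      add(table, cohort$subject_ids[bad], col, problem)
    }
  }
  scan(cohort$thickness, "thickness", function(x) x > 0, "non-positive thickness")
  frac <- identical(attr(cohort, "volumes_unit"), "tiv_fraction")
  scan(cohort$volumes, "volumes", function(x) x > 0 & (!frac | x < 1),
       if (frac) "volume fraction outside (0,1)" else "non-positive volume")
  scan(cohort$fa, "fa", function(x) x >= 0 & x <= 1, "FA outside [0,1]")
  add("tiv", cohort$subject_ids[is.na(cohort$tiv)], "tiv", "missing")
  add("tiv", cohort$subject_ids[!is.na(cohort$tiv) & cohort$tiv <= 0], "tiv",
      "non-positive TIV")
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(table = character(), subject_id = character(),
                   column = character(), problem = character())
  structure(list(issues = issues,
                 offending_subjects = unique(issues$subject_id),
                 pass = nrow(issues) == 0),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation> ", if (x$pass) "pass" else
    paste0("fail: ", nrow(x$issues), " issue(s) across ",
           length(x$offending_subjects), " subject(s)"), "\n", sep = "")
  if (!x$pass) print(x$issues, n = 10)
  invisible(x)
}

#' Drop subjects flagged by validation
#'
#' @param cohort An `als_cohort`.
#' @param report A `cohort_validation` from [validate_cohort()]; recomputed
#'   if omitted.
#' @return The cohort restricted to subjects with complete, in-range metrics.
#' @export
drop_invalid_subjects <- function(cohort, report = validate_cohort(cohort)) {
  keep <- !(cohort$subject_ids %in% report$offending_subjects)
  if (all(keep)) return(cohort)
  message("dropping ", sum(!keep), " subject(s) with incomplete or out-of-range metrics")
  subset_cohort(cohort, keep)
}

subset_cohort <- function(cohort, keep) {
  out <- cohort
  out$subject_ids <- cohort$subject_ids[keep]
  out$thickness <- cohort$thickness[keep, , drop = FALSE]
  out$volumes <- cohort$volumes[keep, , drop = FALSE]
  out$tiv <- cohort$tiv[keep]
  out$fa <- cohort$fa[keep, , drop = FALSE]
  out$metadata <- cohort$metadata[keep, , drop = FALSE]
  out
}

#' Express volumes as fractions of total intracranial volume
#'
#' Replaces every volumetric column by volume/TIV so that downstream scoring
#' is free of head-size effects. Volumes are kept as fractions internally;
#' multiply by 100 for the percentage convention used in reports.
#'
#' @param cohort An `als_cohort` with volumes in mm^3.
#' @return The cohort with `volumes_unit = "tiv_fraction"`; TIV unchanged.
#' @export
normalize_volumes <- function(cohort) {
  stopifnot(inherits(cohort, "als_cohort"))
  if (identical(attr(cohort, "volumes_unit"), "tiv_fraction")) {
    stop("volumes are already TIV-fractions", call. = FALSE)
  }
  if (anyNA(cohort$tiv) || any(cohort$tiv <= 0)) {
    bad <- cohort$subject_ids[is.na(cohort$tiv) | cohort$tiv <= 0]
    stop("missing or non-positive TIV for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cols <- setdiff(names(cohort$volumes), "subject_id")
  cohort$volumes[cols] <- lapply(cohort$volumes[cols], function(x) x / cohort$tiv)
  attr(cohort, "volumes_unit") <- "tiv_fraction"
  cohort
}

#' Average bilateral structures into the reduced feature matrix
#'
#' Collapses the 133 raw metric columns to 74 variables: each left/right
#' pair is replaced by its arithmetic mean and midline structures pass
#' through, yielding 34 thickness, 17 volume-fraction and 23 FA columns.
#' Volumes must already be TIV-fractions (see [normalize_volumes()]) so the
#' reduced matrix is scale-free.
#'
#' @param cohort An `als_cohort` with `volumes_unit = "tiv_fraction"`.
#' @param pairing Pairing map, see [bilateral_pairing()].
#' @return An `als_features` tibble: `subject_id` plus 74 reduced columns,
#'   with attributes `column_roles` (named vector tagging each column
#'   `thickness`/`volume_fraction`/`fa`) and `provenance` (the pairing rows
#'   used).
#' @export
reduce_bilateral <- function(cohort, pairing = bilateral_pairing()) {
  stopifnot(inherits(cohort, "als_cohort"))
  if (!identical(attr(cohort, "volumes_unit"), "tiv_fraction")) {
    stop("volumes must be normalised to TIV-fractions before reduction; ",
         "call normalize_volumes() first", call. = FALSE)
  }
  tabs <- list(thickness = cohort$thickness, volume = cohort$volumes, fa = cohort$fa)
  known <- unlist(lapply(names(tabs), function(m) setdiff(names(tabs[[m]]), "subject_id")))
  referenced <- c(pairing$left, pairing$right[!is.na(pairing$right)])
  unknown <- setdiff(referenced, known)
  if (length(unknown)) {
    stop("pairing map references unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(known, referenced)
  if (length(uncovered)) {
    stop("raw column(s) not covered by the pairing map: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(subject_id = cohort$subject_ids)
  roles <- character(0)
  role_of <- c(thickness = "thickness", volume = "volume_fraction", fa = "fa")
  for (i in seq_len(nrow(pairing))) {
    p <- pairing[i, ]
    tab <- tabs[[p$modality]]
    out[[p$reduced]] <- if (is.na(p$right)) tab[[p$left]] else
      (tab[[p$left]] + tab[[p$right]]) / 2
    roles[p$reduced] <- role_of[[p$modality]]
  }
  structure(out, column_roles = roles, provenance = pairing,
            class = c("als_features", class(out)))
}

#' Write the reduced feature matrix to CSV
#'
#' Prepends `#`-prefixed provenance comment lines (package version, column
#' roles) before the standard CSV body.
#'
#' @param features An `als_features` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  roles <- attr(features, "column_roles")
  counts <- table(roles)
  header <- c(
    paste0("# reduced feature matrix written by alsclust ",
           as.character(utils::packageVersion("alsclust"))),
    paste0("# columns: ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  )
  writeLines(header, path)
  readr::write_csv(features, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
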