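#' Column vocabulary for the raw metric tables
#'
#' The pipeline consumes three per-subject metric tables: cortical thickness
#' for 34 atlas regions in each hemisphere (68 columns, mm), 25 volumetric
#' labels (mm^3, later expressed as fractions of total intracranial volume),
#' and fractional anisotropy for 40 white-matter labels. Bilateral labels are
#' listed once; the raw tables carry `<label>_lh` and `<label>_rh` columns
#' while midline labels (corpus callosum segments, brainstem structures,
#' forceps, fornix ...) appear unsuffixed. The vocabulary ships as a YAML file
#' under `inst/extdata` so other atlas naming schemes can be mapped by
#' supplying an alternative file.
#'
#' @param path Path to a vocabulary YAML file. Defaults to the file shipped
#'   with the package.
#' @return A list with elements `thickness`, `volume` and `fa`, each holding
#'   character vectors `bilateral` and `midline`.
#' @examples
#' vocab <- metric_vocabulary()
#' length(raw_metric_columns("thickness"))  # 68
#' @export
metric_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metric_vocabulary.yaml", package = "alsclust")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("vocabulary file not found: ", path, call. = FALSE)
  }
  vocab <- yaml::read_yaml(path)
  for (mod in c("thickness", "volume", "fa")) {
    if (is.null(vocab[[mod]])) stop("vocabulary is missing modality '", mod, "'", call. = FALSE)
    vocab[[mod]]$bilateral <- as.character(vocab[[mod]]$bilateral)
    vocab[[mod]]$midline <- as.character(vocab[[mod]]$midline)
  }
  vocab
}

#' Raw column names expected in a metric table
#'
#' Expands the vocabulary into the full set of raw column names for one
#' modality: `<label>_lh`/`<label>_rh` for bilateral labels followed by the
#' midline labels.
#'
#' @param modality One of `"thickness"`, `"volume"`, `"fa"`.
#' @param vocab A vocabulary list from [metric_vocabulary()].
#' @return Character vector of raw column names (68 thickness, 25 volume,
#'   40 FA under the default vocabulary).
#' @export
raw_metric_columns <- function(modality = c("thickness", "volume", "fa"),
                               vocab = metric_vocabulary()) {
  modality <- match.arg(modality)
  v <- vocab[[modality]]
  c(as.vector(rbind(paste0(v$bilateral, "_lh"), paste0(v$bilateral, "_rh"))),
    v$midline)
}

# modality -> prefix used for reduced (bilaterally averaged) column names
.modality_prefix <- c(thickness = "th_", volume = "vol_", fa = "fa_")

#' Bilateral pairing map
#'
#' Tabulates how raw metric columns map onto reduced columns: every bilateral
#' label contributes a left/right pair averaged into one column; midline
#' labels pass through. Reduced names are prefixed `th_`, `vol_` or `fa_` so
#' they remain unique when the three tables are combined (e.g. the superior
#' cerebellar peduncle has both a volume and an FA label).
#'
#' @param vocab A vocabulary list from [metric_vocabulary()].
#' @return A tibble with columns `modality`, `reduced`, `left`, `right`
#'   (`NA` for midline labels) and `source` (the unsuffixed label).
#' @export
bilateral_pairing <- function(vocab = metric_vocabulary()) {
  purrr::map_dfr(c("thickness", "volume", "fa"), function(mod) {
    v <- vocab[[mod]]
    pre <- .modality_prefix[[mod]]
    dplyr::bind_rows(
      tibble::tibble(
        modality = mod, source = v$bilateral,
        reduced = paste0(pre, v$bilateral),
        left = paste0(v$bilateral, "_lh"), right = paste0(v$bilateral, "_rh")
      ),
      tibble::tibble(
        modality = mod, source = v$midline,
        reduced = paste0(pre, v$midline),
        left = v$midline, right = NA_character_
      )
    )
  })
}

#' Region-of-interest definitions
#'
#' Loads the 15 ROI definitions that drive composite scoring. Each ROI names
#' its grey-matter members (all thickness or all volume columns; the long
#' association ROI has none), its white-matter FA members, and the FA scaling
#' mode: `pooled` sums the FA members into one index, `separate` (long
#' association fibres only) scales each FA member on its own.
#'
#' @param path Path to an ROI definition YAML file; defaults to the shipped
#'   definitions.
#' @return A tibble with columns `roi`, `gm_kind`, `gm_members` (list),
#'   `wm_mode`, `wm_members` (list), in canonical ROI order.
#' @examples
#' rois <- roi_definitions()
#' rois$roi
#' @export
roi_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roi_definitions.yaml", package = "alsclust")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("ROI definition file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  defs <- tibble::tibble(
    roi = purrr::map_chr(raw, "name"),
    gm_kind = purrr::map_chr(raw, "gm_kind"),
    gm_members = purrr::map(raw, ~ as.character(.x$gm_members)),
    wm_mode = purrr::map_chr(raw, "wm_mode"),
    wm_members = purrr::map(raw, ~ as.character(.x$wm_members))
  )
  validate_roi_definitions(defs)
  defs
}

validate_roi_definitions <- function(defs) {
  stopifnot(is.data.frame(defs))
  if (anyDuplicated(defs$roi)) stop("duplicate ROI names", call. = FALSE)
  bad_kind <- setdiff(unique(defs$gm_kind), c("thickness", "volume", "none"))
  if (length(bad_kind)) stop("unknown gm_kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  bad_mode <- setdiff(unique(defs$wm_mode), c("pooled", "separate"))
  if (length(bad_mode)) stop("unknown wm_mode: ", paste(bad_mode, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(defs))) {
    gm <- defs$gm_members[[i]]
    kind <- defs$gm_kind[[i]]
    if (kind == "none" && length(gm) > 0) {
      stop("ROI '", defs$roi[[i]], "' has gm_kind 'none' but lists grey-matter members", call. = FALSE)
    }
    if (kind != "none" && length(gm) == 0) {
      stop("ROI '", defs$roi[[i]], "' lists no grey-matter members", call. = FALSE)
    }
    expected_prefix <- c(thickness = "th_", volume = "vol_")[kind]
    if (kind != "none" && !all(startsWith(gm, expected_prefix))) {
      stop("ROI '", defs$roi[[i]], "' mixes grey-matter modalities", call. = FALSE)
    }
    wm <- defs$wm_members[[i]]
    if (length(wm) == 0) stop("ROI '", defs$roi[[i]], "' lists no white-matter members", call. = FALSE)
    if (!all(startsWith(wm, "fa_"))) {
      stop("ROI '", defs$roi[[i]], "' has non-FA white-matter members", call. = FALSE)
    }
  }
  invisible(defs)
}
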