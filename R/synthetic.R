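# Synthetic cohort generator. Emulates the statistical structure the
# subtyping analysis assumes: two latent radiological subtypes, a graded
# per-ROI effect-size ladder (subtype 1 carries extra frontotemporal
# burden), a shared disease burden on the core motor/brainstem/commissural
# systems, genotype enrichment in subtype 1, and the study's missingness
# pattern for genetic screening and cognitive testing. Effects are injected
# at the raw-column level so the whole reduction and scoring pathway is
# exercised; volumes are generated as TIV-fractions and rescaled by a
# log-normal TIV so head-size normalisation does real work.

#' Default generator parameters for the emulated study cohort
#'
#' Parameters mirror the published cohort: 214 patients, 35.5% in the
#' frontotemporal-burden subtype, C9orf72 screening in 161/214 with carrier
#' probability 23.5% vs 6.5% among the genotyped of each subtype, ECAS
#' available in 67/76 and 117/138 with impairment in 29.8% vs 17.9% of
#' those assessed, and the printed demographic and clinical means. The
#' effect ladder decreases along the reported ROI importance hierarchy
#' (superior lateral temporal strongest, brainstem none); the shared burden
#' hits motor, brainstem and commissural regions in both subtypes,
#' modelling the core unifying pathology that does not separate subtypes.
#'
#' @return A list of class `cohort_params`. Fields: `n_subjects`,
#'   `subtype1_probability`, per-ROI `effect_ladder` and `shared_burden`
#'   (standardised mean decreases), `noise_sd` per modality (thickness mm,
#'   FA units, volumes relative to baseline fraction), `lr_correlation`,
#'   `tiv_meanlog`/`tiv_sdlog`, per-subtype `carrier_probability`,
#'   `screened_fraction`, `ecas_available_fraction`,
#'   `ecas_impaired_probability`, `ftd_probability`, and demographic means
#'   and SDs.
#' @export
default_cohort_params <- function() {
  ladder <- c(
    superior_lateral_temporal = 2.0, inferior_frontal = 1.9,
    superior_frontal = 1.8, parietal = 1.7, limbic = 1.6,
    mesial_inferior_temporal = 1.5, peri_sylvian = 1.3, subcortical = 1.1,
    long_association = 0.9, commissural = 0.7, occipital = 0.5,
    sensory = 0.3, motor = 0.1, cerebellum = 0.05, brainstem = 0.0)
  shared <- c(motor = 1.0, brainstem = 0.8, commissural = 0.5)
  structure(list(
    n_subjects = 214,
    subtype1_probability = 0.355,
    effect_ladder = ladder,
    shared_burden = shared,
    noise_sd = c(thickness = 0.12, volume = 0.07, fa = 0.03),
    lr_correlation = 0.9,
    tiv_meanlog = log(1.5e6), tiv_sdlog = 0.08,
    carrier_probability = c(0.235, 0.065),
    screened_fraction = 161 / 214,
    ecas_available_fraction = c(67 / 76, 117 / 138),
    ecas_impaired_probability = c(20 / 67, 21 / 117),
    ftd_probability = c(0.171, 0.109),
    age_mean = c(61.9, 60.5), age_sd = c(11.9, 11.9),
    education_mean = c(13.5, 14.1), education_sd = c(3.2, 3.3),
    alsfrs_mean = c(37.9, 38.8), alsfrs_sd = c(5.4, 6.2),
    male_probability = c(0.711, 0.623),
    right_handed_probability = c(0.961, 0.935),
    spinal_onset_probability = c(0.882, 0.862)
  ), class = "cohort_params")
}

validate_cohort_params <- function(p) {
  probs <- c(p$subtype1_probability, p$carrier_probability, p$screened_fraction,
             p$ecas_available_fraction, p$ecas_impaired_probability,
             p$ftd_probability, p$male_probability,
             p$right_handed_probability, p$spinal_onset_probability,
             p$lr_correlation)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  if (p$n_subjects < 4) stop("n_subjects must be at least 4", call. = FALSE)
  if (any(p$effect_ladder < 0) || any(p$shared_burden < 0)) {
    stop("effect sizes must be non-negative", call. = FALSE)
  }
  invisible(p)
}

# modality-typical baselines for readable fixtures; absolute levels are
# immaterial downstream because scoring is affine-invariant per column
.thickness_baseline <- 2.5   # mm
.fa_baseline <- 0.45
.volume_baseline_fraction <- c(
  accumbens = 4e-4, amygdala = 1.1e-3, caudate = 2.5e-3,
  cerebellum_cortex = 3.5e-2, hippocampus = 2.8e-3, pallidum = 1.2e-3,
  putamen = 3.5e-3, thalamus = 5e-3,
  cc_posterior = 6e-4, cc_middle = 4e-4, cc_central = 3.5e-4,
  cc_mid_anterior = 4e-4, cc_anterior = 6e-4,
  medulla = 3e-3, pons = 1e-2, superior_cerebellar_peduncle = 2e-4,
  midbrain = 4e-3)

# reduced column -> ROI lookup (every reduced column belongs to one ROI)
.roi_of_column <- function(rois) {
  roi_map <- character(0)
  for (i in seq_len(nrow(rois))) {
    members <- c(rois$gm_members[[i]], rois$wm_members[[i]])
    roi_map[members] <- rois$roi[[i]]
  }
  roi_map
}

#' Generate a synthetic two-subtype cohort
#'
#' Draws a latent subtype per subject, then each raw metric as
#' `baseline - (shared_burden + subtype1 * effect) * column_sd + noise`,
#' with bilateral columns sharing a common noise component
#' (`lr_correlation`). Volumes are drawn as fractions of a log-normal TIV
#' and stored in mm^3, so the pipeline's TIV normalisation is exercised.
#' Metadata (demographics, genotype with its screening gap, ECAS with its
#' availability gap) is sampled conditionally on subtype. Fully
#' reproducible for a given seed.
#'
#' @param params A `cohort_params` list, see [default_cohort_params()].
#' @param seed Integer seed controlling every random draw.
#' @param n_subjects Optional override of `params$n_subjects`.
#' @return A list with `cohort` (an `als_cohort`, volumes in mm^3) and
#'   `latent` (tibble `subject_id`, `subtype` giving the ground-truth
#'   labels for recovery experiments).
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' table(sim$latent$subtype)
#' @export
simulate_cohort <- function(params = default_cohort_params(), seed = 1,
                            n_subjects = NULL) {
  if (!is.null(n_subjects)) params$n_subjects <- n_subjects
  validate_cohort_params(params)
  withr::with_seed(as.integer(seed), simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  n <- params$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  subtype <- ifelse(stats::runif(n) < params$subtype1_probability, 1L, 2L)
  vocab <- metric_vocabulary()
  pairing <- bilateral_pairing(vocab)
  rois <- roi_definitions()
  roi_map <- .roi_of_column(rois)
  ladder <- params$effect_ladder
  shared <- params$shared_burden
  rho <- params$lr_correlation

  col_effect <- function(reduced) {
    roi <- roi_map[[reduced]]
    sh <- if (roi %in% names(shared)) shared[[roi]] else 0
    sh + ifelse(subtype == 1L, ladder[[roi]], 0)   # vector over subjects
  }
  draw_pair <- function(baseline, sdev, effect_sd) {
    mu <- baseline - effect_sd * sdev
    z0 <- stats::rnorm(n); z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    list(lh = mu + sdev * (sqrt(rho) * z0 + sqrt(1 - rho) * z1),
         rh = mu + sdev * (sqrt(rho) * z0 + sqrt(1 - rho) * z2))
  }
  draw_single <- function(baseline, sdev, effect_sd) {
    baseline - effect_sd * sdev + sdev * stats::rnorm(n)
  }

  thickness <- tibble::tibble(subject_id = ids)
  volumes_frac <- tibble::tibble(subject_id = ids)
  fa <- tibble::tibble(subject_id = ids)
  for (i in seq_len(nrow(pairing))) {
    p <- pairing[i, ]
    eff <- col_effect(p$reduced)
    if (p$modality == "thickness") {
      d <- draw_pair(.thickness_baseline, params$noise_sd[["thickness"]], eff)
      thickness[[p$left]] <- d$lh; thickness[[p$right]] <- d$rh
    } else if (p$modality == "fa") {
      sdev <- params$noise_sd[["fa"]]
      if (is.na(p$right)) {
        fa[[p$left]] <- pmin(pmax(draw_single(.fa_baseline, sdev, eff), 0), 1)
      } else {
        d <- draw_pair(.fa_baseline, sdev, eff)
        fa[[p$left]] <- pmin(pmax(d$lh, 0), 1)
        fa[[p$right]] <- pmin(pmax(d$rh, 0), 1)
      }
    } else {
      base <- .volume_baseline_fraction[[p$source]]
      sdev <- params$noise_sd[["volume"]] * base
      if (is.na(p$right)) {
        volumes_frac[[p$left]] <- pmax(draw_single(base, sdev, eff), base * 0.05)
      } else {
        d <- draw_pair(base, sdev, eff)
        volumes_frac[[p$left]] <- pmax(d$lh, base * 0.05)
        volumes_frac[[p$right]] <- pmax(d$rh, base * 0.05)
      }
    }
  }
  tiv <- stats::rlnorm(n, params$tiv_meanlog, params$tiv_sdlog)
  volumes <- volumes_frac
  vcols <- setdiff(names(volumes), "subject_id")
  volumes[vcols] <- lapply(volumes[vcols], function(x) x * tiv)

  # metadata conditional on subtype
  st <- subtype
  pick <- function(per_subtype) per_subtype[st]
  bern <- function(p) stats::runif(n) < p
  screened <- bern(params$screened_fraction)
  carrier <- bern(pick(params$carrier_probability))
  c9 <- ifelse(screened, ifelse(carrier, "carrier", "non_carrier"), NA_character_)
  ecas_avail <- bern(pick(params$ecas_available_fraction))
  impaired <- bern(pick(params$ecas_impaired_probability))
  ecas <- ifelse(ecas_avail, ifelse(impaired, "yes", "no"), NA_character_)
  metadata <- tibble::tibble(
    subject_id = ids,
    age = stats::rnorm(n, pick(params$age_mean), pick(params$age_sd)),
    sex = ifelse(bern(pick(params$male_probability)), "male", "female"),
    handedness = ifelse(bern(pick(params$right_handed_probability)), "right", "left"),
    education = pmax(stats::rnorm(n, pick(params$education_mean),
                                  pick(params$education_sd)), 5),
    onset_site = ifelse(bern(pick(params$spinal_onset_probability)),
                        "spinal", "bulbar"),
    alsfrs_r = pmin(pmax(round(stats::rnorm(n, pick(params$alsfrs_mean),
                                            pick(params$alsfrs_sd))), 0L), 48L),
    ecas_impaired = ecas,
    als_ftd = ifelse(bern(pick(params$ftd_probability)), "yes", "no"),
    c9orf72 = c9
  )
  cohort <- als_cohort(thickness, volumes, tiv, fa, metadata,
                       volumes_unit = "mm3", vocab = vocab)
  list(cohort = cohort,
       latent = tibble::tibble(subject_id = ids, subtype = subtype))
}

#' Write a cohort (and optional latent labels) to CSV files
#'
#' Writes the four tables [read_cohort()] consumes — `thickness.csv`,
#' `volumes.csv` (with a `tiv` column), `fa.csv`, `metadata.csv` — plus
#' `latent.csv` when ground-truth subtype labels are supplied.
#'
#' @param cohort An `als_cohort`, or the list returned by
#'   [simulate_cohort()] (in which case `latent` is taken from it).
#' @param dir Output directory (created if needed).
#' @param latent Optional tibble `subject_id`, `subtype`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, latent = NULL) {
  if (!inherits(cohort, "als_cohort") && is.list(cohort) && !is.null(cohort$cohort)) {
    if (is.null(latent)) latent <- cohort$latent
    cohort <- cohort$cohort
  }
  stopifnot(inherits(cohort, "als_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(thickness = file.path(dir, "thickness.csv"),
             volumes = file.path(dir, "volumes.csv"),
             fa = file.path(dir, "fa.csv"),
             metadata = file.path(dir, "metadata.csv"))
  readr::write_csv(cohort$thickness, paths[["thickness"]])
  vols <- cohort$volumes
  vols$tiv <- cohort$tiv
  readr::write_csv(vols, paths[["volumes"]])
  readr::write_csv(cohort$fa, paths[["fa"]])
  readr::write_csv(cohort$metadata, paths[["metadata"]])
  if (!is.null(latent)) {
    paths[["latent"]] <- file.path(dir, "latent.csv")
    readr::write_csv(latent, paths[["latent"]])
  }
  invisible(paths)
}
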