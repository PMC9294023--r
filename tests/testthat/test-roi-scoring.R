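test_that("min-max scaling maps extremes to 0/1 and matches recomputation", {
  expect_equal(min_max_scale(c(1, 2, 3))$scaled, c(0, 0.5, 1))
  expect_error(min_max_scale(c(5, 5, 5)), "constant")
  expect_error(min_max_scale(7), "at least 2")
  expect_error(min_max_scale(c(1, NA, 3)), "missing")

  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(50)
    sc <- min_max_scale(x)
    expect_equal(sc$scaled, (x - min(x)) / (max(x) - min(x)))
    expect_equal(range(sc$scaled), c(0, 1))
    # positive affine transforms leave the scaled values unchanged
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(min_max_scale(a * x + b)$scaled, sc$scaled, tolerance = 1e-12)
  }
})

test_that("raw ROI indices are the documented member sums", {
  sim <- simulate_cohort(seed = 22, n_subjects = 10)
  feat <- reduce_bilateral(normalize_volumes(sim$cohort))
  rois <- roi_definitions()

  motor <- roi_raw_indices(feat, rois[rois$roi == "motor", ])
  expect_equal(motor$gm, feat$th_precentral + feat$th_paracentral)
  expect_equal(motor$wm$wm, feat$fa_corticospinal_tract)

  # commissural: five callosal volume fractions summed, three FA summed
  com <- roi_raw_indices(feat, rois[rois$roi == "commissural", ])
  expect_equal(com$gm, feat$vol_cc_posterior + feat$vol_cc_middle +
                 feat$vol_cc_central + feat$vol_cc_mid_anterior + feat$vol_cc_anterior)
  expect_equal(com$wm$wm, feat$fa_forceps_major + feat$fa_forceps_minor + feat$fa_cc_body)

  # long association fibres keep their two FA members separate
  la <- roi_raw_indices(feat, rois[rois$roi == "long_association", ])
  expect_null(la$gm)
  expect_named(la$wm, c("fa_inferior_fronto_occipital_fasciculus",
                        "fa_superior_longitudinal_fasciculus"))

  broken <- rois[rois$roi == "motor", ]
  broken$gm_members <- list(c("th_precentral", "th_not_a_column"))
  expect_error(roi_raw_indices(feat, broken), "th_not_a_column")
})

test_that("composite scores span 0-2 with cohort extremes at the bounds", {
  # a cohort where subject i is uniformly the i-th best on every metric:
  # the top subject must score 2 on every ROI, the bottom subject 0
  rois <- roi_definitions()
  cols <- unique(unlist(c(rois$gm_members, rois$wm_members)))
  n <- 7
  feat <- tibble::as_tibble(c(list(subject_id = sprintf("S%d", 1:n)),
                              setNames(rep(list(as.numeric(1:n)), length(cols)), cols)))
  scores <- composite_scores(feat, rois)
  m <- score_matrix(scores)
  expect_equal(unname(m[n, ]), rep(2, 15))
  expect_equal(unname(m[1, ]), rep(0, 15))
  expect_true(all(m >= 0 & m <= 2))
})

test_that("scores match an independent spreadsheet-style recomputation", {
  sim <- simulate_cohort(seed = 23, n_subjects = 10)
  feat <- reduce_bilateral(normalize_volumes(sim$cohort))
  rois <- roi_definitions()
  scores <- composite_scores(feat, rois)
  expect_equal(unname(score_matrix(scores)), unname(spreadsheet_scores(feat, rois)),
               tolerance = 1e-12)
})

test_that("increasing a member metric never decreases that subject's score", {
  sim <- simulate_cohort(seed = 24, n_subjects = 12)
  feat <- reduce_bilateral(normalize_volumes(sim$cohort))
  rois <- roi_definitions()
  base <- score_matrix(composite_scores(feat, rois))
  # bump a mid-ranked subject without crossing the cohort extremes
  col <- "th_superior_temporal"
  ord <- order(feat[[col]])
  subj <- ord[6]
  bumped <- feat
  bumped[[col]][subj] <- (feat[[col]][subj] + feat[[col]][ord[12]]) / 2
  after <- score_matrix(composite_scores(bumped, rois))
  expect_gte(after[subj, "superior_lateral_temporal"],
             base[subj, "superior_lateral_temporal"])
})

test_that("scores are invariant to per-index affine rescaling of inputs", {
  sim <- simulate_cohort(seed = 25, n_subjects = 15)
  feat <- reduce_bilateral(normalize_volumes(sim$cohort))
  rois <- roi_definitions()
  base <- score_matrix(composite_scores(feat, rois))

  # unit change applied to every thickness column (e.g. mm -> arbitrary units)
  rescaled <- feat
  th_cols <- grep("^th_", names(feat), value = TRUE)
  rescaled[th_cols] <- lapply(rescaled[th_cols], function(x) 3.7 * x + 0.4)
  expect_equal(score_matrix(composite_scores(rescaled, rois)), base,
               tolerance = 1e-9)

  # affine change of a single-member index (sensory white matter)
  rescaled2 <- feat
  rescaled2$fa_medial_lemniscus <- 0.5 * rescaled2$fa_medial_lemniscus + 0.1
  expect_equal(score_matrix(composite_scores(rescaled2, rois)), base,
               tolerance = 1e-9)
})

test_that("frozen scaling parameters project new subjects consistently", {
  sim <- simulate_cohort(seed = 26, n_subjects = 20)
  feat <- reduce_bilateral(normalize_volumes(sim$cohort))
  rois <- roi_definitions()
  scores <- composite_scores(feat, rois)
  frozen <- attr(scores, "scaling")
  expect_true(all(frozen$max > frozen$min))
  # projecting the same cohort with its own frozen params reproduces it
  reproj <- composite_scores(feat, rois, scaling = frozen)
  expect_equal(score_matrix(reproj), score_matrix(scores), tolerance = 1e-12)
})
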