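test_that("a written cohort round-trips through CSV ingestion", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(seed = 11, n_subjects = 5)
  paths <- write_cohort(sim$cohort, dir, latent = sim$latent)
  coh <- read_cohort(paths[["thickness"]], paths[["volumes"]],
                     paths[["fa"]], paths[["metadata"]])
  expect_length(coh$subject_ids, 5)
  expect_equal(coh$thickness$insula_lh, sim$cohort$thickness$insula_lh,
               tolerance = 1e-12)
  expect_equal(coh$tiv, sim$cohort$tiv, tolerance = 1e-12)
  expect_true(validate_cohort(coh)$pass)
})

test_that("ingestion rejects malformed tables with informative errors", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(seed = 11, n_subjects = 5)
  paths <- write_cohort(sim$cohort, dir)

  # missing column named in the error
  th <- readr::read_csv(paths[["thickness"]], show_col_types = FALSE)
  readr::write_csv(th[setdiff(names(th), "insula_lh")],
                   file.path(dir, "thickness_bad.csv"))
  expect_error(
    read_cohort(file.path(dir, "thickness_bad.csv"), paths[["volumes"]],
                paths[["fa"]], paths[["metadata"]]),
    "insula_lh")

  # duplicate subject id
  readr::write_csv(th[c(1, 1, 2:5), ], file.path(dir, "thickness_dup.csv"))
  expect_error(
    read_cohort(file.path(dir, "thickness_dup.csv"), paths[["volumes"]],
                paths[["fa"]], paths[["metadata"]]),
    "duplicate")

  # non-numeric metric cell
  th_bad <- th
  th_bad$insula_lh <- as.character(th_bad$insula_lh)
  th_bad$insula_lh[2] <- "oops"
  readr::write_csv(th_bad, file.path(dir, "thickness_chr.csv"))
  expect_error(
    read_cohort(file.path(dir, "thickness_chr.csv"), paths[["volumes"]],
                paths[["fa"]], paths[["metadata"]]),
    "non-numeric")

  expect_error(read_cohort(file.path(dir, "nope.csv"), paths[["volumes"]],
                           paths[["fa"]], paths[["metadata"]]),
               "not found")
})

test_that("subjects are aligned by inner join with a warning for dropped ids", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(seed = 12, n_subjects = 4)
  paths <- write_cohort(sim$cohort, dir)
  ids <- sim$cohort$subject_ids  # S0001..S0004
  th <- readr::read_csv(paths[["thickness"]], show_col_types = FALSE)
  md <- readr::read_csv(paths[["metadata"]], show_col_types = FALSE)
  # thickness lacks the last subject, metadata lacks the first
  readr::write_csv(th[1:3, ], file.path(dir, "th_sub.csv"))
  readr::write_csv(md[2:4, ], file.path(dir, "md_sub.csv"))
  expect_warning(
    coh <- read_cohort(file.path(dir, "th_sub.csv"), paths[["volumes"]],
                       paths[["fa"]], file.path(dir, "md_sub.csv")),
    paste0(ids[1], ".*", ids[4]))
  expect_equal(coh$subject_ids, ids[2:3])
})

test_that("TIV normalisation is elementwise volume/TIV and guards bad TIV", {
  sim <- simulate_cohort(seed = 13, n_subjects = 6)
  coh <- sim$cohort
  norm <- normalize_volumes(coh)
  for (col in c("pons", "thalamus_lh", "cc_anterior")) {
    expect_equal(norm$volumes[[col]], coh$volumes[[col]] / coh$tiv)
  }
  expect_equal(norm$tiv, coh$tiv)
  expect_error(normalize_volumes(norm), "already")

  bad <- coh
  bad$tiv[2] <- 0
  expect_error(normalize_volumes(bad), "S0002")

  # a volume of 15,000 mm^3 against a TIV of 1,500,000 mm^3 is 1%
  one <- coh
  one$volumes$pons[1] <- 15000
  one$tiv[1] <- 1500000
  expect_equal(normalize_volumes(one)$volumes$pons[1], 0.01)
})

test_that("bilateral averaging yields the 17+34+23 reduced matrix", {
  sim <- simulate_cohort(seed = 14, n_subjects = 8)
  coh <- normalize_volumes(sim$cohort)
  feat <- reduce_bilateral(coh)
  roles <- attr(feat, "column_roles")
  expect_equal(ncol(feat), 75)  # subject_id + 74
  expect_equal(as.vector(table(roles)[c("volume_fraction", "thickness", "fa")]),
               c(17L, 34L, 23L))
  expect_equal(feat$th_insula, (coh$thickness$insula_lh + coh$thickness$insula_rh) / 2)
  expect_equal(feat$vol_hippocampus,
               (coh$volumes$hippocampus_lh + coh$volumes$hippocampus_rh) / 2)
  expect_equal(feat$fa_fornix, coh$fa$fornix)  # midline pass-through
  expect_true(all(as.matrix(feat[names(roles)[roles == "volume_fraction"]]) > 0 &
                  as.matrix(feat[names(roles)[roles == "volume_fraction"]]) < 1))
})

test_that("averaging is the identity on a left-right symmetric cohort", {
  sim <- simulate_cohort(seed = 15, n_subjects = 6)
  coh <- sim$cohort
  vocab <- metric_vocabulary()
  for (lab in vocab$thickness$bilateral) {
    coh$thickness[[paste0(lab, "_rh")]] <- coh$thickness[[paste0(lab, "_lh")]]
  }
  feat <- reduce_bilateral(normalize_volumes(coh))
  expect_equal(feat$th_precentral, coh$thickness$precentral_lh)
})

test_that("reduction requires TIV-fractions and a complete pairing map", {
  sim <- simulate_cohort(seed = 16, n_subjects = 5)
  expect_error(reduce_bilateral(sim$cohort), "normalise")
  coh <- normalize_volumes(sim$cohort)
  pairing <- bilateral_pairing()
  expect_error(reduce_bilateral(coh, pairing[-1, ]), "not covered")
  ghost <- pairing[1, ]
  ghost$reduced <- "th_ghost"; ghost$left <- "ghost_lh"; ghost$right <- "ghost_rh"
  expect_error(reduce_bilateral(coh, rbind(pairing, ghost)), "unknown")
})

test_that("TIV normalisation removes global head-size scale", {
  sim <- simulate_cohort(seed = 17, n_subjects = 6)
  coh <- sim$cohort
  scaled <- coh
  vcols <- setdiff(names(coh$volumes), "subject_id")
  scaled$volumes[vcols] <- lapply(scaled$volumes[vcols], function(x) x * 1.37)
  scaled$tiv <- scaled$tiv * 1.37
  f1 <- reduce_bilateral(normalize_volumes(coh))
  f2 <- reduce_bilateral(normalize_volumes(scaled))
  expect_equal(tibble::as_tibble(f1), tibble::as_tibble(f2), tolerance = 1e-12)
})

test_that("validation flags missing and out-of-range metrics and can drop subjects", {
  sim <- simulate_cohort(seed = 18, n_subjects = 6)
  coh <- sim$cohort
  coh$thickness$insula_lh[2] <- NA
  coh$fa$fornix[3] <- 1.5
  rep <- validate_cohort(coh)
  expect_false(rep$pass)
  expect_setequal(rep$offending_subjects, c("S0002", "S0003"))
  expect_true(any(rep$issues$problem == "missing"))
  expect_true(any(rep$issues$problem == "FA outside [0,1]"))
  expect_message(kept <- drop_invalid_subjects(coh, rep), "dropping 2")
  expect_length(kept$subject_ids, 4)
  expect_true(validate_cohort(kept)$pass)
})
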