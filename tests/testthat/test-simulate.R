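# Small-cohort generator settings used throughout these tests to keep the
# runtime modest; the full study-scale conditions are exercised by the
# recovery checks in test-acceptance.R.
small_cohort <- function(seed, ...) {
  simulate_cohort(n_train = 300, n_test = 200, n_lipids = 80,
                  n_signal_lipids = 12, seed = seed, ...)
}

test_that("the same seed reproduces the bundle exactly", {
  b1 <- small_cohort(5)
  b2 <- small_cohort(5)
  expect_identical(b1$diet, b2$diet)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$lipids$values, b2$lipids$values)
  expect_identical(b1$truth$subjects, b2$truth$subjects)
  b3 <- small_cohort(6)
  expect_false(identical(b1$lipids$values, b3$lipids$values))
})

test_that("generated questionnaires are always scorable by default", {
  b <- small_cohort(8)
  s <- score_hei(b$diet)
  expect_equal(sum(s$excluded), 0)
  expect_false(anyNA(s$total))
  bm <- small_cohort(8, missing_diet_rate = 0.1)
  sm <- score_hei(bm$diet)
  expect_gt(sum(sm$excluded), 0)
})

test_that("the HEI total hits its target mean and spread", {
  means <- sds <- numeric(10)
  for (s in 1:10) {
    b <- simulate_cohort(n_train = 700, n_test = 500, n_lipids = 40,
                         n_signal_lipids = 8, seed = 400 + s)
    hs <- score_hei(b$diet)
    means[s] <- mean(hs$total); sds[s] <- sd(hs$total)
  }
  expect_lt(abs(mean(means) - 5.8), 0.15)
  expect_lt(abs(mean(sds) - 1.5), 0.25)
})

test_that("the latent diet factor drives the HEI at r > 0.9", {
  b <- small_cohort(9)
  hs <- score_hei(b$diet)
  expect_gt(cor(b$truth$subjects$diet_quality, hs$total), 0.9)
  expect_equal(b$truth$r_diet_hei,
               cor(b$truth$subjects$diet_quality, hs$total),
               tolerance = 1e-10)
  # the two waves differ in diet quality, core below refresher
  core <- hs$total[b$demographics$wave == "core"]
  ref <- hs$total[b$demographics$wave == "refresher"]
  expect_lt(mean(core), mean(ref))
})

test_that("MetS prevalence lands near its target across seeds", {
  prev <- vapply(1:5, function(s) {
    b <- simulate_cohort(n_train = 700, n_test = 500, n_lipids = 40,
                         n_signal_lipids = 8, seed = 500 + s)
    mean(classify_mets(b$clinical)$mets)
  }, numeric(1))
  expect_true(all(abs(prev - 0.37) < 0.05))
  b <- simulate_cohort(n_train = 700, n_test = 500, n_lipids = 40,
                       n_signal_lipids = 8, seed = 501,
                       mets_target_prevalence = 0.2)
  expect_lt(abs(mean(classify_mets(b$clinical)$mets) - 0.2), 0.05)
})

test_that("planted lipid loadings honor the requested coupling", {
  b <- small_cohort(10, diet_lipid_coupling = 0.4)
  tl <- b$truth$lipid_loadings
  expect_equal(sum(tl$signal), 12)
  expect_true(all(tl$loading[!tl$signal] == 0))
  s2 <- sum(tl$loading^2)
  R <- sqrt(s2 / (1 + s2))
  expect_equal(R * b$truth$r_diet_hei, 0.4, tolerance = 1e-10)
  # null coupling plants nothing
  b0 <- small_cohort(10, diet_lipid_coupling = 0)
  expect_true(all(b0$truth$lipid_loadings$loading == 0))
  # a coupling beyond what the questionnaire chain supports is refused
  expect_error(small_cohort(10, diet_lipid_coupling = 0.99), "infeasible")
})

test_that("below-LOD censoring is concentrated where designed", {
  b <- small_cohort(11)
  frac <- colMeans(b$lipids$below_lod)
  tl <- b$truth$lipid_loadings
  expect_true(all(frac[tl$signal] < 0.20))  # signal species survive the filter
  expect_gt(sum(frac >= 0.20), 0)           # some noise species are dropped
  # censored cells sit at the bottom of each species' distribution
  j <- which(frac > 0.3)[1]
  v <- b$lipids$values[, j]
  expect_lte(max(v[b$lipids$below_lod[, j]]), min(v[!b$lipids$below_lod[, j]]))
})

test_that("biomarker effects carry the designed sign structure", {
  b <- simulate_cohort(n_train = 1500, n_test = 0, n_lipids = 40,
                       n_signal_lipids = 8, seed = 600)
  D <- b$truth$subjects$diet_quality
  cl <- b$clinical
  expect_gt(cor(D, cl$hdl_mg_dl), 0)
  expect_lt(cor(D, cl$insulin_uiu_ml), 0)
  expect_lt(cor(D, cl$homa_ir), 0)
  expect_lt(cor(D, cl$il6_pg_ml), 0)
  expect_lt(cor(D, cl$crp_mg_l), 0)
  expect_lt(cor(D, cl$bmi), 0)
})

test_that("bundles round-trip through the directory format", {
  b <- small_cohort(12)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  b2 <- read_cohort(dir)
  expect_equal(b2$demographics, b$demographics)
  expect_equal(b2$diet, b$diet)
  expect_equal(b2$clinical, b$clinical, tolerance = 1e-12)
  expect_equal(b2$lipids$values, b$lipids$values, tolerance = 1e-12)
  expect_identical(b2$lipids$below_lod, b$lipids$below_lod)
  expect_equal(b2$truth$subjects$diet_quality,
               b$truth$subjects$diet_quality, tolerance = 1e-12)
  file.remove(file.path(dir, "lipids.csv"))
  expect_error(read_cohort(dir), "lipids.csv")
})

test_that("a single-wave bundle (no test subjects) is valid", {
  b <- simulate_cohort(n_train = 300, n_test = 0, n_lipids = 40,
                       n_signal_lipids = 8, seed = 13)
  expect_equal(nrow(b$demographics), 300)
  expect_true(all(b$demographics$wave == "core"))
  expect_equal(nrow(validate_cohort(b)), 0)
})

test_that("validation flags schema and range violations", {
  b <- small_cohort(14)
  expect_equal(nrow(validate_cohort(b)), 0)
  b$clinical$waist_cm[3] <- -5
  b$diet$subject_id[2] <- b$diet$subject_id[1]
  rep <- validate_cohort(b)
  expect_true(any(rep$check == "nonpositive_value" & rep$detail == "waist_cm"))
  expect_true(any(rep$check == "duplicate_subject_id" & rep$table == "diet"))
})
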