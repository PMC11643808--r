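sim_xy <- function(n = 50, p = 5, beta = c(2, 0, 0, 0, 0), noise = 1,
                   seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("sp", seq_len(p))
  list(x = x, y = drop(x %*% beta[seq_len(p)]) + noise * rnorm(n))
}

test_that("full shrinkage gives the empty model with the mean intercept", {
  d <- sim_xy()
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 1e4)
  expect_length(m$selected, 0)
  expect_equal(unname(m$intercept), mean(d$y), tolerance = 1e-8)
  expect_equal(as.numeric(predict(m, d$x)), rep(0, nrow(d$x)))
})

test_that("the unpenalized fit matches ordinary least squares", {
  d <- sim_xy(n = 30, p = 3, beta = c(1, -0.5, 0.25), seed = 2)
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0)
  ols <- coef(lm(d$y ~ d$x))
  expect_equal(unname(m$weights), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(unname(m$intercept), unname(ols[1]), tolerance = 1e-4)
})

test_that("a planted single-species signal is selected with its weight", {
  d <- sim_xy(n = 50, p = 5, beta = c(2, 0, 0, 0, 0), noise = 0.05, seed = 3)
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0.02)
  expect_true("sp1" %in% m$selected)
  expect_equal(unname(m$weights["sp1"]), 2, tolerance = 0.1)
  # full coefficient vector agrees with a naive coordinate-descent oracle
  o <- oracle_lasso(d$x, d$y, 0.02)
  expect_equal(unname(m$weights), o$beta, tolerance = 1e-6)
  expect_equal(unname(m$intercept), o$intercept, tolerance = 1e-6)
})

test_that("the internal refit solver agrees with glmnet across penalties", {
  d <- sim_xy(n = 80, p = 20, beta = c(1, -0.7, 0.4, rep(0, 17)), seed = 4)
  for (lam in c(0.5, 0.1, 0.02)) {
    g <- glmnet::glmnet(d$x, d$y, lambda = lam, standardize = FALSE,
                        thresh = 1e-12)
    cd <- heilipids:::.cd_lasso_fit(d$x, d$y, lam, rep(0, ncol(d$x)))
    expect_equal(cd$beta, as.numeric(g$beta), tolerance = 1e-5)
    expect_equal(cd$intercept, as.numeric(g$a0), tolerance = 1e-5)
  }
})

test_that("leave-one-out refits reproduce direct refits on n-1 subjects", {
  d <- sim_xy(n = 60, p = 10, beta = c(1, -0.5, rep(0, 8)), seed = 5)
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0.05)
  loo <- loocv_signature_scores(d$x, d$y, model = m)
  expect_equal(attr(loo, "provenance"), "loocv_train")
  for (i in c(1, 30, 60)) {
    g <- glmnet::glmnet(d$x[-i, ], d$y[-i], lambda = 0.05,
                        standardize = FALSE, thresh = 1e-13)
    expect_equal(loo[i], sum(d$x[i, ] * as.numeric(g$beta)),
                 tolerance = 1e-4)
  }
  # excluding no observation reproduces the full-data model exactly
  full <- heilipids:::.cd_lasso_fit(d$x, d$y, 0.05, unname(m$weights),
                                    exclude = -1L)
  expect_equal(full$beta, unname(m$weights), tolerance = 1e-3)
})

test_that("null-signal LOO scores are uncorrelated with the outcome", {
  rs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(60 * 10), 60, 10)
    colnames(x) <- paste0("sp", 1:10)
    y <- rnorm(60)
    loo <- loocv_signature_scores(x, y, lambda = 0.05)
    if (sd(loo) == 0) 0 else cor(loo, y)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("in-sample scores overfit relative to LOO scores on average", {
  diffs <- vapply(1:10, function(s) {
    d <- sim_xy(n = 80, p = 15, beta = c(0.4, -0.3, rep(0, 13)),
                noise = 1, seed = 200 + s)
    m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0.05)
    ins <- cor(predict(m, d$x), d$y)
    loo <- cor(loocv_signature_scores(d$x, d$y, model = m), d$y)
    ins - loo
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("signature scoring is linear in the lipid profile", {
  d <- sim_xy(seed = 6)
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0.1)
  x1 <- d$x; x2 <- d$x[nrow(d$x):1, ]
  lhs <- predict(m, 2 * x1 + 3 * x2)
  rhs <- 2 * predict(m, x1) + 3 * predict(m, x2)
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
})

test_that("prediction demands every selected species", {
  d <- sim_xy(seed = 7, noise = 0.05)
  m <- hei_signature(d$x, d$y, lambda_rule = "fixed", lambda = 0.02)
  xm <- d$x[, setdiff(colnames(d$x), "sp1")]
  expect_error(predict(m, xm), "sp1")
})

test_that("signature-HEI correlation matches a hand computation", {
  expect_equal(signature_cor(1:10, 1:10)$r, 1)
  expect_equal(signature_cor(1:10, 10:1)$r, -1)
  s <- c(1.2, 0.5, 2.0, 1.1, 0.3); y <- c(3, 2, 6, 5, 1)
  hand_r <- sum((s - mean(s)) * (y - mean(y))) /
    sqrt(sum((s - mean(s))^2) * sum((y - mean(y))^2))
  res <- signature_cor(s, y)
  expect_equal(res$r, hand_r, tolerance = 1e-12)
  tstat <- hand_r * sqrt(3) / sqrt(1 - hand_r^2)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
  expect_equal(res$n, 5)
  expect_error(signature_cor(rep(1, 5), y), "variance")
})

test_that("class composition percentages are exact and sum to 100", {
  meta <- data.frame(species = c("a", "b", "c", "d"),
                     class = c("TG", "TG", "PC", "PE-O"))
  m <- structure(list(selected = c("a", "b", "c", "d"),
                      species_meta = meta), class = "hei_signature")
  cs <- signature_class_summary(m)
  expect_equal(cs$percent[cs$class == "TG"], 50)
  expect_equal(cs$percent[cs$class == "PC"], 25)
  expect_equal(sum(cs$percent), 100)
  # planted class counts 13/11/6/27 over 57 species
  meta2 <- data.frame(
    species = sprintf("s%02d", 1:57),
    class = rep(c("TG", "PC", "PE-O", "other"), c(13, 11, 6, 27)))
  m2 <- structure(list(selected = meta2$species, species_meta = meta2),
                  class = "hei_signature")
  cs2 <- signature_class_summary(m2)
  expect_equal(cs2$percent[cs2$class == "TG"], 100 * 13 / 57, tolerance = 1e-10)
  expect_equal(cs2$percent[cs2$class == "PC"], 100 * 11 / 57, tolerance = 1e-10)
  expect_equal(cs2$percent[cs2$class == "PE-O"], 100 * 6 / 57, tolerance = 1e-10)
  # empty model -> empty table
  m0 <- structure(list(selected = character(), species_meta = meta),
                  class = "hei_signature")
  expect_equal(nrow(signature_class_summary(m0)), 0)
})

test_that("degenerate outcomes and tiny samples are rejected", {
  d <- sim_xy(n = 30, p = 3, seed = 8)
  expect_error(hei_signature(d$x, rep(2, 30), lambda_rule = "fixed",
                             lambda = 0.1), "variance")
  expect_error(hei_signature(d$x[1:15, ], d$y[1:15], lambda_rule = "fixed",
                             lambda = 0.1), "20 subjects")
  expect_error(loocv_signature_scores(d$x[1:5, ], d$y[1:5], lambda = 0.1),
               "n < 10")
})

test_that("strong equal planted signals are found by CV-selected lasso", {
  # 10 equally loaded signal species among 200 noise species
  found <- vapply(1:5, function(s) {
    b <- simulate_cohort(n_train = 500, n_test = 0, n_lipids = 210,
                         n_signal_lipids = 10, diet_lipid_coupling = 0.6,
                         loading_decay = 1, lod_high_species = 0,
                         seed = 300 + s)
    z <- standardize_lipids(filter_by_lod(b$lipids))
    hs <- score_hei(b$diet)
    y <- hs$total[match(rownames(z), hs$subject_id)]
    m <- hei_signature(z, y, seed = s)
    truth <- b$truth$lipid_loadings
    sum(truth$species[truth$signal] %in% m$selected)
  }, numeric(1))
  expect_gte(median(found), 8)
})
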