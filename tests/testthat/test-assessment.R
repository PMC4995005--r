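test_that("RPIQ follows its definition and is scale invariant", {
  y <- c(1, 2, 3, 4, 5) # IQR = 2 with linear-interpolation quartiles
  expect_equal(rpiq(y, msep = 4), 1, tolerance = 1e-10)
  expect_equal(rpiq(y, msep = 1), 2, tolerance = 1e-10)
  c0 <- 3.7
  expect_equal(rpiq(c0 * y, msep = c0^2 * 4), rpiq(y, 4),
               tolerance = 1e-12)
  expect_error(rpiq(y, 0), class = "soilcmin_perfect_prediction_error")
  expect_error(rpiq(c(1, 2, 3), 1), class = "soilcmin_data_error")
})

test_that("orthogonal components receive their marginal shares", {
  set.seed(21)
  n <- 120
  c1 <- rnorm(n); c1 <- c1 - mean(c1)
  c2 <- resid(lm(rnorm(n) ~ c1)) # orthogonal to c1 and centered
  y <- c1 + c2 + rnorm(n, 0, 0.5)
  comps <- cbind(a = c1, b = c2)
  seq_imp <- sequential_importance(y, comps, "sequential")
  marg_imp <- sequential_importance(y, comps, "marginal")
  expect_equal(seq_imp$pct, marg_imp$pct, tolerance = 1e-8)
  r2 <- function(x) 100 * summary(lm(y ~ x))$r.squared
  expect_equal(seq_imp$pct, c(r2(c1), r2(c2)), tolerance = 1e-6)
  fit <- lm(y ~ c1 + c2)
  expect_equal(sum(seq_imp$pct), 100 * summary(fit)$r.squared,
               tolerance = 1e-8)
})

test_that("sequential attribution charges shared variance to the first term", {
  set.seed(22)
  n <- 200
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n) # correlation 0.5 with z1
  y <- z1 + z2
  comps <- cbind(first = z1, second = z2)
  # noiseless construction: anova warns about an essentially perfect fit
  imp <- suppressWarnings(sequential_importance(y, comps, "sequential"))
  # oracle: explicit projections. SS1 = |P_1 y|^2, SS2 = |P_2|1 y|^2
  c1 <- z1 - mean(z1); c2 <- z2 - mean(z2); yc <- y - mean(y)
  ss1 <- sum(c1 * yc)^2 / sum(c1^2)
  r2c <- c2 - c1 * sum(c1 * c2) / sum(c1^2)
  ss2 <- sum(r2c * yc)^2 / sum(r2c^2)
  tss <- sum(yc^2)
  expect_equal(imp$pct, 100 * c(ss1, ss2) / tss, tolerance = 1e-8)
  expect_gt(imp$pct[1], imp$pct[2]) # first-listed gets the shared part
  expect_equal(sum(imp$pct), 100, tolerance = 1e-8) # noiseless: totals conserved
})

test_that("attribution agrees with redundancy-analysis sums of squares", {
  set.seed(23)
  n <- 90
  comps <- cbind(u = rnorm(n), v = rnorm(n))
  y <- comps %*% c(1, 0.5) + rnorm(n, 0, 0.3)
  imp <- sequential_importance(as.numeric(y), comps, "sequential")
  rd <- vegan::rda(y ~ u + v, data = as.data.frame(comps))
  an <- suppressWarnings(stats::anova(rd, by = "terms", permutations = 19))
  expect_equal(imp$ss / (n - 1), an$Variance[1:2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("model importances plus remainder reproduce explained deviance", {
  mf <- model_frame(simulate_dataset(seed = 24)$dataset)
  f <- fit_gam(model_spec("log_rs_control",
                          list(model_term("bacterial_j", "poly2", TRUE),
                               model_term("sand", "I"))), mf)
  imp <- relative_importance(f)
  expect_true(all(imp$pct >= -1e-8))
  expect_equal(sum(imp$pct) + attr(imp, "remainder"),
               explained_deviance(f), tolerance = 1e-6)
  # time-only model: the single component carries all explained deviance
  # (up to the slight rescaling of the shrunk component by the ordination)
  f0 <- fit_gam(model_spec("log_rs_control", list()), mf)
  imp0 <- relative_importance(f0)
  expect_equal(imp0$pct, explained_deviance(f0), tolerance = 1e-3)
})

test_that("BIC follows the Gaussian profile form and orders nested fits", {
  expect_equal(bic_gam(list(n = 100, rss = 100, edf = 3)),
               3 * log(100), tolerance = 1e-10)
  expect_equal(bic_gam(list(n = 100, rss = 100, edf = 3)), 13.8155,
               tolerance = 1e-4)
  b_small <- bic_gam(list(n = 50, rss = 10, edf = 4))
  b_big <- bic_gam(list(n = 50, rss = 20, edf = 4))
  expect_lt(b_small, b_big)
  mf <- model_frame(small_dataset(seed = 25))
  f1 <- fit_gam(model_spec("log_rs_control", list()), mf)
  f2 <- fit_gam(model_spec("log_rs_control",
                           list(model_term("ph", "I"))), mf)
  expect_equal(bic_gam(f1),
               bic_gam(list(n = nrow(f1$train), rss = f1$gam$deviance,
                            edf = edf_total(f1))), tolerance = 1e-10)
  expect_true(is.finite(bic_gam(f2)))
})

test_that("kinetics ANOVA separates time levels and is translation invariant", {
  set.seed(26)
  d <- expand.grid(land_use = c("cropland", "grassland"),
                   time = c(3, 7), replicate = 1:15)
  d$value <- ifelse(d$time == 3, 0, 10) + rnorm(nrow(d), 0, 1)
  a <- kinetics_anova(d)
  expect_identical(length(unique(a$time_letters$letters)), 2L)
  expect_true(all(nchar(a$time_letters$letters) == 1))
  d2 <- d; d2$value <- d$value + 1
  a2 <- kinetics_anova(d2)
  expect_equal(a2$anova$statistic, a$anova$statistic, tolerance = 1e-10)
  expect_identical(a2$time_letters$letters, a$time_letters$letters)
  # per-time land-use contrasts are reported with significance codes
  expect_identical(sort(unique(a$land_use_by_time$time)),
                   sort(as.character(unique(d$time))))
  expect_true(all(a$land_use_by_time$code %in%
                    c("***", "**", "*", "°", "ns")))
})

test_that("assessment reports are internally consistent", {
  mf <- model_frame(simulate_dataset(seed = 27)$dataset)
  sel <- suppressWarnings(
    stepwise_select(mf, "log_rs_control", c("bacterial_j", "sand"),
                    forms = c("I", "poly2"), interaction_mode = "never"))
  a <- assess_model(sel)
  y <- sel$fit$train[[sel$spec$response]]
  expect_equal(a$rpiq, rpiq(y, a$msep), tolerance = 1e-10)
  expect_equal(a$pct_deviance, explained_deviance(sel$fit),
               tolerance = 1e-10)
  expect_identical(a$terms$covariate[1], "time")
  expect_identical(a$terms$relation[1], "RF")
  expect_true(all(a$terms$relative_importance >= -1e-8))
})
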