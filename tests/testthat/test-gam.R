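# Minimal frames for engine tests: site-level covariate x, several
# sampling dates, optional land use.
gam_frame <- function(n_sites = 20, dates = c(3, 7, 14, 21), reps = 1,
                      seed = 1) {
  set.seed(seed)
  x <- rnorm(n_sites)
  d <- expand.grid(site = seq_len(n_sites), replicate = seq_len(reps),
                   time = dates)
  d$site_id <- sprintf("G%02d", d$site)
  d$x <- x[d$site]
  d$land_use <- factor(ifelse(d$site <= n_sites / 2,
                              "cropland", "grassland"))
  d
}

test_that("noiseless linear and polynomial signals are recovered exactly", {
  d <- gam_frame()
  d$y <- 2 * d$x + 1
  f <- fit_gam(model_spec("y", list(model_term("x", "I"))), d)
  expect_equal(fitted(f), d$y, tolerance = 1e-8)
  # slope on the original covariate scale
  nd <- d[1:2, ]; nd$x <- c(0, 1)
  expect_equal(diff(predict(f, nd)), 2, tolerance = 1e-6,
               ignore_attr = TRUE)

  d2 <- gam_frame(n_sites = 50)
  d2$y <- d2$x^2
  f2 <- fit_gam(model_spec("y", list(model_term("x", "poly2"))), d2)
  expect_equal(fitted(f2), d2$y, tolerance = 1e-8)
})

test_that("a penalized spline recovers a smooth signal", {
  set.seed(2)
  d <- data.frame(site_id = sprintf("G%03d", 1:200),
                  time = rep(c(3, 7, 14, 21), 50),
                  x = runif(200))
  truth <- sin(2 * pi * d$x)
  d$y <- truth + rnorm(200, 0, 0.1)
  f <- fit_gam(model_spec("y", list(model_term("x", "s"))), d, k = 10)
  expect_lt(mean((fitted(f) - truth)^2), 0.02)
  # independent penalized-spline fit agrees on the signal
  ref <- stats::smooth.spline(d$x, d$y)
  expect_lt(mean((predict(ref, d$x)$y - truth)^2), 0.02)
  expect_lt(mean((predict(ref, d$x)$y - fitted(f))^2), 0.01)
})

test_that("component columns decompose the linear predictor", {
  mf <- model_frame(small_dataset(seed = 5))
  spec <- model_spec("log_rs_control",
                     list(model_term("soc", "I", by_land_use = TRUE),
                          model_term("ph", "poly2")))
  f <- fit_gam(spec, mf)
  cm <- component_matrix(f)
  expect_identical(colnames(cm), c("time", "land_use", "soc", "ph"))
  expect_equal(rowSums(cm) + attr(cm, "intercept"), fitted(f),
               tolerance = 1e-8, ignore_attr = TRUE)
  # covariate and land-use components are centered over training rows
  expect_lt(max(abs(colMeans(cm[, c("land_use", "soc", "ph")]))), 1e-8)
})

test_that("adding a term never increases in-sample deviance", {
  mf <- model_frame(simulate_dataset(seed = 8)$dataset)
  terms <- list()
  dev_prev <- Inf
  for (t in list(model_term("ph", "I"), model_term("soc", "s"),
                 model_term("cn_ratio", "poly2"))) {
    terms <- c(terms, list(t))
    f <- fit_gam(model_spec("log_rs_control", terms), mf)
    expect_lte(f$gam$deviance, dev_prev + 1e-8)
    dev_prev <- f$gam$deviance
  }
})

test_that("prediction on training rows equals fitted values", {
  mf <- model_frame(simulate_dataset(seed = 6)$dataset)
  f <- fit_gam(model_spec("log_rs_amended",
                          list(model_term("soc", "s"))), mf)
  expect_equal(predict(f, mf), fitted(f), tolerance = 1e-10)
})

test_that("intercept-plus-time predictions add the date effect", {
  d <- gam_frame(n_sites = 10, dates = c(3, 7, 14), reps = 2, seed = 3)
  d$y <- c(3, 1, 0)[match(d$time, c(3, 7, 14))] + rnorm(nrow(d), 0, 0.1)
  f <- fit_gam(model_spec("y", list()), d)
  nd <- data.frame(time = 7)
  tm <- predict(f$gam,
                newdata = data.frame(time_f = factor(7, f$time_levels)),
                type = "terms")
  expect_equal(predict(f, nd), attr(tm, "constant") + tm[1, "s(time_f)"],
               tolerance = 1e-10, ignore_attr = TRUE)
  # unseen date: time effect zero, with a warning
  expect_warning(p <- predict(f, data.frame(time = 99)),
                 class = "soilcmin_unseen_level_warning")
  expect_equal(p, attr(tm, "constant"), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("explained deviance matches its closed form", {
  expect_equal(pct_deviance(c(0, 1, 2), c(0.5, 1, 1.5)), 75,
               tolerance = 1e-10)
  expect_equal(pct_deviance(c(0, 1, 2), c(0, 1, 2)), 100)
  d <- gam_frame(seed = 4)
  set.seed(4); d$y <- rnorm(nrow(d))
  f <- fit_gam(model_spec("y", list(model_term("x", "I"))), d)
  expect_equal(explained_deviance(f),
               pct_deviance(d$y, fitted(f)), tolerance = 1e-8)
})

test_that("term significance flags a strong linear effect", {
  set.seed(9)
  d <- data.frame(site_id = sprintf("G%03d", 1:100),
                  time = rep(c(3, 7, 14, 21), 25),
                  x = rnorm(100))
  d$y <- 5 * d$x + rnorm(100, 0, 0.1)
  f <- fit_gam(model_spec("y", list(model_term("x", "I"))), d)
  sig <- term_significance(f)
  row <- sig[sig$covariate == "x", ]
  expect_lt(row$p_value, 0.001)
  expect_identical(row$code, "***")
})

test_that("significance codes map p-value bands as reported", {
  expect_identical(sig_code(c(0.0001, 0.005, 0.03, 0.07, 0.2)),
                   c("***", "**", "*", "°", "ns"))
})

test_that("a heavily penalized smooth collapses toward its linear part", {
  d <- gam_frame(n_sites = 30, dates = c(3, 7), seed = 10)
  set.seed(10); d$y <- 1.5 * d$x + rnorm(nrow(d), 0, 0.2)
  f <- fit_gam(model_spec("y", list(model_term("x", "s"))), d)
  big <- mgcv::gam(stats::formula(f$gam), data = f$train,
                   sp = c(1e8, 1e8))
  lin <- stats::lm(y ~ x, data = f$train)
  expect_equal(unname(fitted(big)), unname(fitted(lin)), tolerance = 1e-3)
})
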