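test_that("a noiseless linear response is recovered to OLS precision", {
  set.seed(1)
  d <- data.frame(x = runif(200, 0, 10))
  d$y <- 3 + 2 * d$x
  # zero residual variance makes REML step-halving chatty; harmless here
  m <- suppressWarnings(fit_gam(d, "y", list(smooth_term("x", k = 8))))
  ols <- cbind(1, d$x) %*% solve(crossprod(cbind(1, d$x)),
                                 crossprod(cbind(1, d$x), d$y))
  expect_lt(max(abs(predict(m, d) - drop(ols))), 1e-6)
  expect_lt(max(abs(predict(m, d) - d$y)), 1e-6)
})

test_that("a constant response gives zero deviance explained", {
  d <- data.frame(x = seq(0, 1, length.out = 50), y = 5)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 5)))
  expect_equal(m$dev_expl, 0, tolerance = 1e-8)
  expect_equal(unique(round(predict(m, d), 8)), 5)
})

test_that("a noisy sine is recovered within the stated RMSE", {
  set.seed(42)
  d <- data.frame(x = runif(500, 0, 1))
  truth <- sin(2 * pi * d$x)
  d$y <- truth + rnorm(500, 0, 0.1)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 20)))
  expect_lt(sqrt(mean((predict(m, d) - truth)^2)), 0.05)
})

test_that("predictions on training data equal fitted values and recomputed
           deviance explained matches the stored value", {
  set.seed(2)
  d <- data.frame(a = runif(120), b = runif(120))
  d$y <- d$a^2 + cos(3 * d$b) + rnorm(120, 0, 0.05)
  m <- fit_gam(d, "y", list(smooth_term("a", k = 6), smooth_term("b", k = 6)))
  expect_equal(as.numeric(predict(m, d)), as.numeric(fitted(m$fit)),
               tolerance = 1e-10)
  expect_equal(energyscape:::recompute_dev_expl(m), m$dev_expl,
               tolerance = 1e-8)
})

test_that("clamping pins out-of-range predictors to the training edge", {
  set.seed(3)
  d <- data.frame(x = runif(100, 0, 1))
  d$y <- exp(d$x) + rnorm(100, 0, 0.01)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 10)))
  at_edge <- predict(m, data.frame(x = max(d$x)))
  beyond_clamped <- predict(m, data.frame(x = 2))
  expect_equal(as.numeric(beyond_clamped), as.numeric(at_edge))
  expect_identical(attr(beyond_clamped, "n_clamped"), 1L)
  beyond_free <- predict(m, data.frame(x = 2), clamp = FALSE)
  expect_false(isTRUE(all.equal(as.numeric(beyond_free),
                                as.numeric(at_edge))))
  expect_error(predict(m, data.frame(z = 1)), "lacks predictor")
})

test_that("rank-deficient designs fail with the offending term named", {
  d <- data.frame(x = rep(1, 50), y = rnorm(50))
  expect_error(fit_gam(d, "y", list(smooth_term("x"))), "'x'")
  expect_error(fit_gam(d[0, ], "y", list(smooth_term("x"))), "10 rows")
})

test_that("posterior coefficient simulation is correct and reproducible", {
  set.seed(4)
  d <- data.frame(x = runif(150))
  d$y <- 2 * d$x + rnorm(150, 0, 0.2)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 6)))
  # determinism under a seed
  expect_identical(simulate_coefficients(m, 5, seed = 9),
                   simulate_coefficients(m, 5, seed = 9))
  # zero covariance collapses every draw onto the fitted coefficients
  m0 <- m
  m0$covariance <- matrix(0, length(m$coefficients),
                          length(m$coefficients))
  dr0 <- simulate_coefficients(m0, 7, seed = 1)
  expect_equal(dr0, matrix(m$coefficients, 7, length(m$coefficients),
                           byrow = TRUE,
                           dimnames = list(NULL, names(m$coefficients))),
               ignore_attr = "repaired")
  # the empirical mean of many draws sits within 3 Monte-Carlo SE
  k <- 10000
  dr <- simulate_coefficients(m, k, seed = 2)
  se <- sqrt(diag(m$covariance) / k)
  expect_true(all(abs(colMeans(dr) - m$coefficients) <= 3 * se + 1e-12))
  # a negative eigenvalue is floored and flagged
  mneg <- m
  mneg$covariance <- diag(c(rep(1e-4, length(m$coefficients) - 1), -1e-3))
  expect_true(attr(simulate_coefficients(mneg, 3, seed = 1), "repaired"))
})

test_that("monotone constraints yield monotone partial responses", {
  set.seed(5)
  d <- data.frame(x = runif(200, 0, 1), z = runif(200))
  d$y <- plogis(8 * (d$x - 0.5)) + 0.3 * d$z + rnorm(200, 0, 0.15)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 12,
                                        constraint = "increasing"),
                            smooth_term("z", k = 5)))
  grid <- data.frame(x = seq(0, 1, length.out = 300), z = 0.5)
  expect_true(all(diff(predict(m, grid)) >= -1e-7))
})

test_that("model records serialize to self-describing JSON", {
  set.seed(6)
  d <- data.frame(x = runif(60))
  d$y <- d$x + rnorm(60, 0, 0.1)
  m <- fit_gam(d, "y", list(smooth_term("x", k = 5)),
               response_units = "m")
  path <- file.path(tempdir(), "model.json")
  write_smooth_model(m, path)
  rec <- read_smooth_model_record(path)
  expect_equal(rec$coefficients, as.numeric(m$coefficients))
  expect_equal(rec$dev_expl, m$dev_expl)
  expect_equal(rec$ranges$x, as.numeric(m$ranges$x))
  expect_identical(rec$response_units, "m")
  file.remove(path)
})
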