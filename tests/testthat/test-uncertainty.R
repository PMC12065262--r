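zero_cov <- function(models) {
  for (nm in c("depth_day", "depth_night", "cost", "hif", "ingestion"))
    models[[nm]]$covariance <- matrix(
      0, length(models[[nm]]$coefficients),
      length(models[[nm]]$coefficients))
  models
}

test_that("the chain ensemble is the four-way Cartesian product", {
  models <- models0()
  ens10 <- build_ensemble(models, k = 10, seed = 1)
  expect_identical(ensemble_size(ens10), 10000L)
  expect_identical(nrow(ensemble_realizations(ens10)), 10000L)
  ens2 <- build_ensemble(models, k = 2, seed = 1)
  expect_identical(nrow(ensemble_realizations(ens2)), 16L)
  r <- ensemble_realizations(ens2)
  expect_identical(nrow(unique(r)), 16L)
  expect_named(r, c("depth", "cost", "hif", "ingestion"))
  expect_error(build_ensemble(models, k = 0), "k")
  expect_error(build_ensemble(models, k = 2, percentiles = c(95, 5)),
               "percentiles")
  m2 <- models; m2$cost$covariance <- NULL
  expect_error(build_ensemble(m2, k = 2), "covariance")
})

test_that("a zero-covariance ensemble collapses onto the point estimate", {
  models <- zero_cov(models0())
  ens <- build_ensemble(models, k = 1, seed = 3)
  dmat <- ensemble_delta_balance(ens, env0(), env0_future(), month = 7)
  point_h <- project_energetics(env0(), models, months = 7)[[1]]
  point_f <- project_energetics(env0_future(), models, months = 7)[[1]]
  expect_equal(as.vector(dmat),
               as.vector(point_f$fields$balance - point_h$fields$balance),
               tolerance = 1e-10)
})

test_that("anomaly percentiles and the zero-overlap mask behave", {
  # identical positive members: p5 = p95 > 0, no overlap with zero
  mm <- matrix(3, nrow = 4, ncol = 10)
  ap <- anomaly_percentiles(mm)
  expect_equal(ap$percentiles["p5", ], ap$percentiles["p95", ])
  expect_false(any(ap$overlap_zero))
  # members symmetric about zero overlap everywhere
  sym <- rbind(matrix(2, 3, 6), matrix(-2, 3, 6))
  expect_true(all(anomaly_percentiles(sym)$overlap_zero))
  expect_error(anomaly_percentiles(mm[1, , drop = FALSE]), "2 ensemble")
  # percentiles are monotone in the percentile argument
  set.seed(11)
  rnd <- matrix(rnorm(600), 60, 10)
  apr <- anomaly_percentiles(rnd, c(5, 25, 50, 75, 95))
  expect_true(all(diff(apr$percentiles) >= 0))
  # against the normal-quantile oracle, per cell, at Monte-Carlo tolerance
  big <- matrix(rnorm(20000, mean = 1, sd = 2), 2000, 10)
  apn <- anomaly_percentiles(big, c(5, 95))
  expect_equal(as.vector(apn$percentiles["p5", ]),
               rep(qnorm(0.05, 1, 2), 10), tolerance = 0.15)
  expect_equal(as.vector(apn$percentiles["p95", ]),
               rep(qnorm(0.95, 1, 2), 10), tolerance = 0.15)
})

test_that("ensemble draws and enumeration are reproducible", {
  models <- models0()
  a <- build_ensemble(models, k = 3, seed = 77)
  b <- build_ensemble(models, k = 3, seed = 77)
  expect_identical(a$draws, b$draws)
  c2 <- build_ensemble(models, k = 3, seed = 78)
  expect_false(identical(a$draws, c2$draws))
})

test_that("with GAM covariances zeroed, all spread comes from the
           climate-source slot", {
  models <- zero_cov(models0())
  cfg <- cfg0()
  envs_h <- list(esm1 = generate_env_fields(cfg, "historical", "esm1"),
                 esm2 = generate_env_fields(cfg, "historical", "esm2"))
  envs_f <- list(esm1 = generate_env_fields(cfg, "future", "esm1"),
                 esm2 = generate_env_fields(cfg, "future", "esm2"))
  va <- variance_attribution(models, envs_h, envs_f, k = 2, seed = 5,
                             month = 7)
  tab <- va$table
  expect_true(all(tab$variance >= 0))
  expect_identical(tab$slot[1], "climate_source")
  expect_equal(tab$share[tab$slot == "climate_source"], 1)
  expect_true(all(tab$variance[tab$slot != "climate_source"] < 1e-12))
  # zero spread everywhere: contributions all zero, not NaN
  va0 <- variance_attribution(models, envs_h["esm1"], envs_f["esm1"],
                              k = 2, seed = 5, month = 7)
  expect_true(all(va0$table$share == 0))
  expect_true(all(va0$table$variance == 0))
})

test_that("attribution reports ranked nonnegative spreads plus remainder", {
  models <- models0()
  cfg <- cfg0()
  envs_h <- list(esm1 = generate_env_fields(cfg, "historical", "esm1"),
                 esm2 = generate_env_fields(cfg, "historical", "esm2"))
  envs_f <- list(esm1 = generate_env_fields(cfg, "future", "esm1"),
                 esm2 = generate_env_fields(cfg, "future", "esm2"))
  va <- variance_attribution(models, envs_h, envs_f, k = 3, seed = 6,
                             month = 7)
  tab <- va$table
  expect_true(all(tab$variance >= 0))
  expect_true(all(diff(tab$variance) <= 0))
  expect_true(is.finite(va$total_variance))
  expect_true(is.finite(va$interaction_remainder))
})
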