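const <- energetics_constants()

test_that("oxycalorific conversion follows the fixed coefficient", {
  expect_identical(mo2_to_kj(1, 1, 1, const), 0.01359)
  expect_identical(mo2_to_kj(0, 5, 10, const), 0)
  expect_equal(mo2_to_kj(100, 11, 24, const), 358.776)
  expect_error(mo2_to_kj(-1, 1, 1, const), ">= 0")
  # bilinear in mo2 x weight, linear in hours
  set.seed(1)
  x <- runif(20, 0, 300); w <- runif(20, 5, 20); h <- runif(20, 0, 24)
  expect_equal(mo2_to_kj(2 * x, w, h, const), 2 * mo2_to_kj(x, w, h, const))
  expect_equal(mo2_to_kj(x, 3 * w, h, const), 3 * mo2_to_kj(x, w, h, const))
  expect_equal(mo2_to_kj(x, w, 2 * h, const), 2 * mo2_to_kj(x, w, h, const))
})

test_that("the balance accounting identity holds exactly", {
  expect_equal(daily_balance(1000, 100, const), 538)
  expect_identical(daily_balance(0, 0, const), 0)
  expect_equal(daily_balance(1000, 638, const), 0)
  # slope 1 - 0.092 - 0.27 = 0.638 in ingested, -1 in cost, exact algebra
  set.seed(2)
  i1 <- runif(50, 0, 5000); i2 <- runif(50, 0, 5000)
  cc <- runif(50, 0, 2000)
  expect_equal((daily_balance(i1, cc, const) -
                  daily_balance(i2, cc, const)) / (i1 - i2),
               rep(0.638, 50))
  expect_equal(daily_balance(i1, cc + 7, const),
               daily_balance(i1, cc, const) - 7)
  expect_error(daily_balance(-1, 0, const), ">= 0")
})

test_that("constants enforce their invariants", {
  expect_error(energetics_constants(sda_loss = 1.2), "loss fractions")
  expect_error(energetics_constants(sda_loss = 0.6, egestion_loss = 0.5),
               "< 1")
  expect_error(energetics_constants(thermal_min = 25), "thermal_min")
  expect_error(energetics_constants(lw_a = 1), "inconsistent")
})

test_that("length-weight and length interpolation behave as configured", {
  expect_gt(length_to_weight(80, const), 10.5)
  expect_lt(length_to_weight(80, const), 11.5)
  expect_error(length_to_weight(-5, const), "> 0")
  r <- as.Date("2005-01-01"); q <- as.Date("2005-03-02")  # 60-day span
  expect_equal(interpolate_length(70, 80, r, q, r + 30), 75)
  expect_equal(interpolate_length(70, 80, r, q, r), 70)
  expect_equal(interpolate_length(70, 80, r, q, q), 80)
  expect_error(interpolate_length(70, 80, r, q, q + 1), "outside")
})

test_that("depth models recover the generator's diel links", {
  dd <- depth_data0()
  models <- models0()
  dp <- cfg0()$depth
  truth_day <- pmin(pmax(dp$day_d0 + dp$day_o2 * dd$o2depth_3p5 +
                           dp$day_t200 * (dd$t200 - 10), 0), 200)
  truth_night <- pmax(dp$night_d0 + dp$night_t200 * (dd$t200 - 10), 0)
  expect_lt(rmse(predict(models$depth_day, dd), truth_day), 5)
  expect_lt(rmse(predict(models$depth_night, dd), truth_night), 5)
  # fitted day response is monotone increasing in the oxygen-surface depth
  grid <- data.frame(t200 = median(dd$t200), moon = median(dd$moon),
                     o2depth_3p5 = seq(min(dd$o2depth_3p5),
                                       max(dd$o2depth_3p5),
                                       length.out = 100))
  expect_true(all(diff(predict(models$depth_day, grid)) > -0.05))
})

test_that("the night moon response is flat when the generator ignores moon", {
  models <- models0()
  dd <- depth_data0()
  m <- models$depth_night
  grid <- data.frame(t200 = median(dd$t200), moon = seq(0, 100, 2),
                     o2depth_3p5 = median(dd$o2depth_3p5))
  X <- predict(m$fit, newdata = grid, type = "lpmatrix")
  pr <- drop(X %*% m$coefficients)
  se <- sqrt(pmax(rowSums((X %*% m$covariance) * X), 0))
  # the partial response stays within its own 2-SE band of flatness
  expect_true(all(abs(pr - mean(pr)) <= 2 * se + 0.1))
})

test_that("the cost model reproduces the respirometry surface", {
  cfg <- cfg0()
  m2 <- models0()$cost
  grd <- expand.grid(temperature = seq(10.5, 24.5, 0.5),
                     speed = seq(0.6, 2.9, 0.1))
  truth <- respirometry_truth(cfg, grd$temperature, grd$speed)
  pr <- predict(m2, grd)
  expect_lt(max(abs(pr - truth)), 0.01 * diff(range(truth)))
  # strictly more expensive to swim at 2 than 1 BL/s at any temperature
  t_seq <- seq(10.5, 24.5, 0.5)
  expect_true(all(predict(m2, data.frame(temperature = t_seq, speed = 2)) >
                    predict(m2, data.frame(temperature = t_seq, speed = 1))))
  expect_error(fit_cost_model(data.frame(temperature = runif(60, 10, 25),
                                         speed = 2,
                                         mo2 = runif(60, 100, 200))),
               "one-dimensional")
  expect_error(fit_cost_model(generate_respirometry(cfg)[1:30, ]),
               ">= 50")
})

test_that("the ingestion model recovers the feeding-trial surface", {
  cfg <- cfg0()
  m4 <- models0()$ingestion
  grd <- expand.grid(hif = seq(0.2, 4.8, 0.2),
                     temperature = seq(10.5, 24.5, 1),
                     pct_finfish = seq(42, 98, 7))
  truth <- feeding_truth(cfg, grd$hif, grd$temperature, grd$pct_finfish)
  pr <- predict_ingestion(m4, grd$hif, grd$temperature, grd$pct_finfish)
  expect_lt(rmse(pr, truth), 0.01 * diff(range(truth)))
  # zero HIF predicts (near) zero intake
  z <- predict_ingestion(m4, 0, seq(11, 24, 1), 70)
  expect_true(all(z < 0.01 * diff(range(truth))))
  expect_true(all(z >= 0))
})

test_that("the foraging model is flat in length when the generator is", {
  m3 <- models0()$hif
  hd <- assemble_hif_data(tags0(), env0())
  grid <- data.frame(mesozoo = median(hd$mesozoo),
                     length_cm = seq(min(hd$length_cm), max(hd$length_cm),
                                     length.out = 50),
                     day_length = median(hd$day_length))
  X <- predict(m3$fit, newdata = grid, type = "lpmatrix")
  pr <- drop(X %*% m3$coefficients)
  se <- sqrt(pmax(rowSums((X %*% m3$covariance) * X), 0))
  expect_true(all(abs(pr - mean(pr)) <= 2 * se + 0.02))
})

test_that("noisy refits stay within three standard errors of truth", {
  cfg <- base_cfg()  # default noise levels
  resp <- generate_respirometry(cfg)
  m2 <- fit_cost_model(resp)
  grd <- expand.grid(temperature = seq(11, 24, 1),
                     speed = seq(0.7, 2.8, 0.3))
  truth <- respirometry_truth(cfg, grd$temperature, grd$speed)
  X <- predict(m2$fit, newdata = grd, type = "lpmatrix")
  pr <- drop(X %*% m2$coefficients)
  se <- sqrt(pmax(rowSums((X %*% m2$covariance) * X), 0))
  expect_gt(mean(abs(pr - truth) <= 3 * se), 0.95)

  trials <- generate_feeding_trials(cfg)
  m4 <- fit_ingestion_model(trials)
  grd4 <- expand.grid(hif = seq(0.5, 4.5, 0.5),
                      temperature = seq(11, 24, 1.5), pct_finfish = 70)
  truth4 <- feeding_truth(cfg, grd4$hif, grd4$temperature,
                          grd4$pct_finfish)
  X4 <- predict(m4$fit, newdata = grd4, type = "lpmatrix")
  pr4 <- drop(X4 %*% m4$coefficients)
  se4 <- sqrt(pmax(rowSums((X4 %*% m4$covariance) * X4), 0))
  expect_gt(mean(abs(pr4 - truth4) <= 3 * se4), 0.95)
})
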