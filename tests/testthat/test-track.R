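test_that("haversine distances match independent geometry oracles", {
  expect_identical(great_circle_km(10, 20, 10, 20), 0)
  # spherical law of cosines oracle at (0,0)-(0,1)
  slc <- 6371 * acos(pmin(1, sin(0) * sin(0) +
                            cos(0) * cos(0) * cos(1 * pi / 180)))
  expect_equal(great_circle_km(0, 0, 0, 1), slc, tolerance = 1e-9)
  expect_equal(great_circle_km(0, 0, 0, 1), 111.19, tolerance = 0.01)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_error(great_circle_km(91, 0, 0, 0), "lat")
  # established-package cross-check on random point pairs
  set.seed(9)
  p1 <- cbind(runif(25, -180, 180), runif(25, -80, 80))
  p2 <- cbind(runif(25, -180, 180), runif(25, -80, 80))
  ref <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  expect_equal(great_circle_km(p1[, 2], p1[, 1], p2[, 2], p2[, 1]), ref,
               tolerance = 1e-9)
})

test_that("the 7-day smoother preserves length and window arithmetic", {
  expect_equal(smooth_distances(rep(4.2, 30)), rep(4.2, 30))
  x <- rep(0, 21); x[11] <- 7
  s <- smooth_distances(x)
  expect_length(s, 21)
  expect_equal(s[8:14], rep(1, 7))
  expect_equal(s[c(7, 15)], c(0, 0))
  expect_warning(out <- smooth_distances(1:5), "shorter")
  expect_identical(out, 1:5)
})

test_that("vertical distance is half the absolute path, descents cheap", {
  expect_equal(vertical_km(c(0, 100, 0)), 0.1)
  expect_equal(vertical_km(rep(50, 100)), 0)
  expect_equal(vertical_km(seq(0, 500, length.out = 60)), 0.25)
  # steps across a gap are excluded
  ts <- as.POSIXct("2005-06-01", tz = "UTC") + c(0, 60, 600, 660)
  expect_equal(vertical_km(c(0, 100, 500, 600), ts), 0.5 * 200 / 1000)
})

test_that("speed conversion follows body-length arithmetic", {
  expect_equal(speed_bls(86.4, 0, 100), 1)
  expect_equal(speed_bls(0, 0, 80), 0)
  expect_equal(speed_bls(40, 10, 50), 2 * speed_bls(40, 10, 100))
  expect_error(speed_bls(10, 0, 0), "> 0")
})

test_that("track energetics satisfy the exact accounting decomposition", {
  tag <- tags0()[[1]]
  const <- energetics_constants()
  tr <- track_daily_energetics(tag, models0(), const)
  expect_identical(nrow(tr), nrow(tag$daily))
  expect_true(all(tr$horizontal_km >= 0 & tr$vertical_km >= 0 &
                    tr$speed_bls >= 0))
  # balance = daily_balance(ingested, cost) row by row, exactly
  expect_equal(tr$balance_kj,
               daily_balance(tr$ingested_kj, tr$movement_cost_kj, const))
  # sum(balance) + sum(cost) + sum(losses) = sum(ingested), exactly
  losses <- (const$sda_loss + const$egestion_loss) * tr$ingested_kj
  expect_equal(sum(tr$balance_kj) + sum(tr$movement_cost_kj) + sum(losses),
               sum(tr$ingested_kj))
})

test_that("a fasting fish pays movement costs with no intake", {
  cfg <- cfg0()
  tag <- generate_tag_record(cfg, "faster", feeding_schedule = data.frame(),
                             env = env0())
  tr <- track_daily_energetics(tag, models0())
  range4 <- diff(range(generate_feeding_trials(cfg)$kj_ingested))
  expect_true(all(tr$ingested_kj < 0.01 * range4))
  expect_equal(tr$balance_kj, 0.638 * tr$ingested_kj - tr$movement_cost_kj,
               tolerance = 1e-12)
  expect_true(all(tr$balance_kj < 0))
})

test_that("re-experiencing under identical fields changes nothing", {
  tag <- tags0()[[2]]
  rx <- reexperience_track(tag, env0(), env0(), models0())
  expect_equal(rx$delta_balance_kj, rep(0, nrow(rx)))
})

test_that("swapping the period labels negates the change exactly", {
  tag <- tags0()[[2]]
  fwd <- reexperience_track(tag, env0(), env0_future(), models0())
  bwd <- reexperience_track(tag, env0_future(), env0(), models0())
  expect_equal(fwd$delta_balance_kj, -bwd$delta_balance_kj)
  # deployment-mean change equals the mean of daily changes (linearity)
  expect_equal(mean(fwd$delta_balance_kj),
               mean(fwd$balance_fut_kj) - mean(fwd$balance_hist_kj))
})

test_that("a warmer-only future raises movement costs along the track", {
  cfg <- noise_free(synth_config(seed = 7, resolution = 4,
                                 lat_range = c(20, 52),
                                 lon_range = c(150, -130),
                                 deployment_days = 60, n_fish = 3,
                                 warming_offset = 1.5,
                                 zoo_trend = c(south = 1, north = 1)))
  env_f <- generate_env_fields(cfg, "future", "obs")
  tag <- tags0()[[1]]
  models <- models0()
  const <- energetics_constants()
  kin <- track_kinematics(tag, const)
  cost_for <- function(env) {
    ev <- env_at(env, kin$lat, kin$lon, kin$date)
    t_amb <- temp_at_depth(ev$sst, ev$t200, kin$mean_depth_m)
    mo2 <- pmax(0, predict(models$cost, data.frame(
      temperature = t_amb, speed = kin$speed_bls)))
    mo2_to_kj(mo2, kin$weight_kg, 24, const)
  }
  d_cost <- cost_for(env_f) - cost_for(env0())
  expect_true(all(d_cost > 0))
})

test_that("smoothing before or after summing distances agree closely", {
  set.seed(10)
  x <- runif(120, 0, 60)
  expect_equal(sum(smooth_distances(x)), sum(x),
               tolerance = 0.02 * sum(x))
})
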