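test_that("day length follows the sunrise equation", {
  dates <- as.Date("2005-01-01") + seq(0, 360, 30)
  expect_true(all(abs(day_length_hours(0, dates) - 12) < 0.15))
  expect_equal(day_length_hours(50, as.Date("2005-06-21")), 16.3,
               tolerance = 0.3)
  # equinox: ~12 h everywhere up to 60 degrees
  eq <- day_length_hours(seq(-60, 60, 5), as.Date("2005-03-20"))
  expect_true(all(abs(eq - 12) < 0.15))
  # polar night / day saturate instead of erroring
  expect_equal(day_length_hours(89, as.Date("2005-12-21")), 0)
  expect_equal(day_length_hours(89, as.Date("2005-06-21")), 24)
  expect_error(day_length_hours(95, as.Date("2005-06-21")), "lat")
})

test_that("moon illumination has the synodic period", {
  d <- as.Date("2005-03-01") + 0:60
  f <- moon_fraction(d)
  expect_true(all(f >= 0 & f <= 100))
  f1 <- moon_fraction(as.Date("2005-03-01") + 0:29)
  f2 <- moon_fraction(as.Date("2005-03-01") + 29.530589 + 0:29)
  expect_lt(max(abs(f1 - f2)), 2)
})

test_that("the linear profile honors its two constraints", {
  expect_equal(temp_at_depth(20, 14, 0), 20)
  expect_equal(temp_at_depth(20, 14, 200), 8)
  z <- seq(0, 200, 0.5)
  expect_equal(mean(temp_at_depth(20, 14, z)), 14, tolerance = 1e-3)
  # depths beyond the resolved layer clamp to 200 m
  expect_equal(temp_at_depth(20, 14, 350), temp_at_depth(20, 14, 200))
})

test_that("cell areas follow spherical geometry", {
  expect_equal(cell_areas(0, 1), 12364, tolerance = 1)
  expect_equal(cell_areas(60, 1) / cell_areas(0, 1), 0.5,
               tolerance = 0.005)
  lat <- seq(-89.5, 89.5, 1)
  total <- 360 * sum(cell_areas(lat, 1))
  expect_equal(total, 4 * pi * 6371^2, tolerance = 0.001 * 4 * pi * 6371^2)
})

test_that("the thermal mask uses inclusive envelope bounds", {
  maps <- maps0()
  const <- energetics_constants()
  for (m in maps)
    expect_identical(m$fields$mask,
                     m$fields$sst >= const$thermal_min &
                       m$fields$sst <= const$thermal_max)
  # boundary behavior: 10.9 out, 11.0 in, 22.0 in, 22.1 out
  sst <- c(10.9, 11, 22, 22.1)
  expect_identical(sst >= const$thermal_min & sst <= const$thermal_max,
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("maps satisfy the per-cell accounting identity and are pure", {
  m <- maps0()[[7]]
  const <- energetics_constants()
  expect_equal(m$fields$balance,
               daily_balance(m$fields$ingested, m$fields$cost, const))
  again <- project_energetics(env0(), models0(), months = 7)[[1]]
  expect_identical(again$fields, m$fields)
})

test_that("uniform fields project to longitude-uniform maps", {
  cfg <- noise_free(synth_config(
    seed = 7, resolution = 4, lat_range = c(20, 52),
    lon_range = c(150, -130),
    env = list(sst_lat_slope = 0, sst_seas_amp = 0, zoo_lat = 0,
               zoo_east = 0, zoo_seas_amp = 0, o2_dip = 0)))
  env <- generate_env_fields(cfg, "historical")
  maps <- project_energetics(env, models0(), months = 6)
  bal <- maps[[1]]$fields$balance
  # constant along longitude; only latitude (day length) varies
  expect_lt(max(apply(bal, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("missing fields are reported by name", {
  env <- env0()
  env$fields$mesozoo <- NULL
  expect_error(project_energetics(env, models0()), "mesozoo")
})

test_that("uniform warming moves cells out at the warm edge only", {
  m <- maps0()[[7]]
  const <- energetics_constants()
  delta <- 1.5
  sst2 <- m$fields$sst + delta
  mask2 <- sst2 >= const$thermal_min & sst2 <= const$thermal_max
  lost <- m$fields$mask & !mask2
  gained <- !m$fields$mask & mask2
  expect_true(all(m$fields$sst[lost] > const$thermal_max - delta))
  expect_true(all(m$fields$sst[gained] < const$thermal_min))
  expect_equal(sum(mask2) - sum(m$fields$mask), sum(gained) - sum(lost))
})

test_that("habitat change metrics are exact on identical periods and
           bounded by the field inside the mask", {
  hc0 <- habitat_change(maps0(), maps0())
  expect_equal(hc0$delta_area_km2, rep(0, 4))
  expect_equal(hc0$delta_balance_kj, rep(0, 4))
  expect_equal(hc0$pct_delta_area, rep(0, 4))

  maps_f <- project_energetics(env0_future(), models0())
  hc <- habitat_change(maps0(), maps_f)
  expect_equal(hc$pct_delta_area,
               100 * (hc$area_fut_km2 - hc$area_hist_km2) /
                 hc$area_hist_km2)
  # independent recomputation of one season's weighted mean
  const <- energetics_constants()
  jja <- energyscape:::seasonal_map(maps0(), 6:8, const, "JJA")
  areas <- energyscape:::cell_area_matrix(jja$grid)
  w <- sum(jja$fields$balance[jja$fields$mask] *
             areas[jja$fields$mask]) / sum(areas[jja$fields$mask])
  expect_equal(hc$balance_hist_kj[hc$season == "JJA"], w)
  expect_gte(w, min(jja$fields$balance[jja$fields$mask]))
  expect_lte(w, max(jja$fields$balance[jja$fields$mask]))
})

test_that("ensemble summaries match the closed-form t interval", {
  base <- habitat_change(maps0(), project_energetics(env0_future(),
                                                     models0()))
  # five synthetic sources: known additive spread on one season's metrics
  shifts <- c(-2, -1, 0, 1, 2) * 10
  summaries <- do.call(rbind, lapply(seq_along(shifts), function(i) {
    s <- base
    s$source_id <- paste0("esm", i)
    s$delta_balance_kj <- s$delta_balance_kj + shifts[i]
    s
  }))
  es <- ensemble_summary(summaries)
  row <- es[es$season == "DJF" & es$metric == "delta_balance_kj", ]
  x <- base$delta_balance_kj[base$season == "DJF"] + shifts
  half <- qt(0.975, 4) * sd(x) / sqrt(5)
  expect_equal(row$mean, mean(x), tolerance = 1e-9)
  expect_equal(row$ci_hi - row$mean, half, tolerance = 1e-9)
  expect_equal(row$mean - row$ci_lo, half, tolerance = 1e-9)

  # identical sources collapse the interval to zero width
  same <- do.call(rbind, lapply(1:3, function(i) base))
  es0 <- ensemble_summary(same)
  expect_true(all(es0$ci_hi - es0$ci_lo < 1e-9, na.rm = TRUE))

  # 3 positive vs 2 negative balance changes flag a direction disagreement
  mixed <- do.call(rbind, lapply(1:5, function(i) {
    s <- base[base$season == "JJA", ]
    s$delta_balance_kj <- c(5, 3, 1, -2, -4)[i]
    s
  }))
  expect_true(all(ensemble_summary(mixed)$direction_disagreement))
})
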