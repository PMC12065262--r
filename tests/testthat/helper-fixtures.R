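# Shared study-system fixtures, memoized so the model chain is fitted once
# per test run. The noise-free configuration is the analytic-oracle system;
# the noisy one uses the generator's default noise levels.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

base_cfg <- function() {
  synth_config(seed = 7, resolution = 4,
               lat_range = c(20, 52), lon_range = c(150, -130),
               deployment_days = 60, n_fish = 3)
}

cfg0 <- function() noise_free(base_cfg())

env0 <- function() memo("env0",
  generate_env_fields(cfg0(), "historical", "obs"))

env0_future <- function() memo("env0_future",
  generate_env_fields(cfg0(), "future", "obs"))

tags0 <- function() memo("tags0", generate_tag_records(cfg0(), env = env0()))

models0 <- function() memo("models0",
  fit_energetics_models(tags0(), env0(), generate_respirometry(cfg0()),
                        generate_feeding_trials(cfg0())))

maps0 <- function() memo("maps0", project_energetics(env0(), models0()))

truth0 <- function() memo("truth0", project_energetics_truth(cfg0(), env0()))

depth_data0 <- function() memo("depth_data0",
  assemble_depth_data(tags0(), env0()))

# cells of a truth slice whose chained covariates all sit inside the fitted
# models' training ranges (so clamping plays no role)
eligible_cells <- function(tr, models) {
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  in_range(tr$t200, models$depth_day$ranges$t200) &
    in_range(tr$o2depth_3p5, models$depth_day$ranges$o2depth_3p5) &
    in_range(tr$mesozoo, models$hif$ranges$mesozoo) &
    in_range(tr$day_length, models$hif$ranges$day_length) &
    in_range(tr$t_day, models$cost$ranges$temperature) &
    in_range(tr$t_night, models$cost$ranges$temperature) &
    in_range(tr$hif, models$ingestion$ranges$hif) &
    in_range(tr$t_day, models$ingestion$ranges$temperature)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
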