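# small shared synthetic objects, built once per test run
small_env <- function(seed = 7, nx = 15, ny = 15, n_days = 25, ...) {
  make_environment(nx = nx, ny = ny, seed = seed,
                   style = "coastal_gradient", n_days = n_days, ...)
}

flat_env <- function(seed = 3, nx = 12, ny = 12, depth_m = 40, n_days = 12,
                     ...) {
  make_environment(nx = nx, ny = ny, seed = seed, style = "flat",
                   depth_m = depth_m, n_days = n_days, ...)
}

mid_cell <- function(env) bassgeo:::rc_cell(env, round(env$ny / 2),
                                            round(env$nx / 2))

small_archive <- function(seed = 5, n_days = 10, env = NULL) {
  if (is.null(env)) env <- small_env(n_days = n_days + 2)
  tr <- simulate_track(env, n_days, mid_cell(env), seed = seed)
  list(env = env, track = tr,
       archive = record_tag(tr, env, seed = seed + 1))
}
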