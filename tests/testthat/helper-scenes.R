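# Shared fixtures, built in code and cached for the test run. Scenes are
# deliberately smaller than the generator's 18-plant default tray (3x2 grid,
# 280x170 px) so the full suite stays fast; all noise/falloff/shape parameters
# stay at generator defaults.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) assign(key, maker(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_scene <- function(key = "wt1d", ...) {
  args <- list(...)
  cached(key, function() {
    defaults <- list(width = 280, height = 170, n_cols = 3, n_rows = 2,
                     n_days = 1, rng_seed = 101)
    generate_session(do.call(scene_spec, utils::modifyList(defaults, args)))
  })
}

test_calibration <- function() calibration_spec(0.25)

# piecewise-constant disk image with ground truth
disk_image <- function(h = 80, w = 80, cy = 40, cx = 40, r = 20,
                       fg = 200, bg = 50, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- sqrt((row(matrix(0, h, w)) - cy)^2 + (col(matrix(0, h, w)) - cx)^2)
  truth <- d <= r
  img <- ifelse(truth, fg, bg)
  if (noise_sd > 0) img <- pmin(pmax(img + rnorm(h * w, 0, noise_sd), 0), 255)
  list(img = img, truth = truth, dist = d)
}

# timestamped blank PNG session on disk; returns the directory
write_png_session <- function(times, dir = tempfile("sess"), size = 8,
                              rgb = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in times) {
    nm <- format(as.POSIXct(t, tz = "UTC"), "img_%Y-%m-%dT%H-%M.png")
    px <- if (rgb) array(runif(size * size * 3), c(size, size, 3))
          else matrix(runif(size * size), size, size)
    png::writePNG(px, file.path(dir, nm))
  }
  dir
}
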