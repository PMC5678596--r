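test_that("rosette stamps hit their target area and are deterministic", {
  st <- render_rosette(1000)
  expect_true(abs(attr(st, "area_px") - 1000) <= 10)
  expect_identical(render_rosette(750, rotation = 1.1),
                   render_rosette(750, rotation = 1.1))
  # single lobe: simply connected (filling holes changes nothing)
  st1 <- render_rosette(600, leaf_count = 1)
  expect_equal(sum(clean_mask(st1, 0, TRUE)), sum(st1))
  expect_error(render_rosette(5000, max_radius = 10), "cell size")
})

test_that("a one-day 12:12 session has the right frame grid and modalities", {
  sc <- small_scene()
  expect_length(sc$session$frames, 72L)
  mods <- vapply(sc$session$frames, function(f) f$modality, "")
  expect_equal(sum(mods == "VIS"), 36L)
  expect_equal(sum(mods == "NIR"), 36L)
  expect_equal(sc$session$periods$kind, c("light", "dark"))
  # VIS frames are 3-plane, NIR single-plane
  expect_true(is.array(sc$session$frames[[1]]$pixels))
  expect_true(is.matrix(sc$session$frames[[37]]$pixels))
})

test_that("ground-truth areas equal mask pixel counts exactly, every frame", {
  sc <- small_scene()
  for (i in seq(1, 72, by = 7)) {
    counts <- tabulate(sc$truth$masks[[i]][sc$truth$masks[[i]] > 0], nbins = 6)
    rec <- sc$truth$areas[sc$truth$areas$frame_index == i, ]
    expect_identical(as.numeric(counts), rec$area_px[order(rec$plant_id)])
  }
})

test_that("true areas are exponential (dip off) and reproducible from the seed", {
  sp <- scene_spec(width = 200, height = 120, n_cols = 2, n_rows = 1,
                   dip_amplitude = 0, n_days = 1, rng_seed = 77)
  sc <- generate_session(sp)
  a <- sc$truth$areas[sc$truth$areas$plant_id == 1, ]
  # analytic truth is exactly exponential
  expect_equal(a$area_mm2_true[72] / a$area_mm2_true[1],
               exp(0.20 * (a$time_days[72] - a$time_days[1])), tolerance = 1e-12)
  # rasterised truth tracks it to the stamp tolerance
  expect_equal(a$area_px[72] / a$area_px[1],
               exp(0.20 * (a$time_days[72] - a$time_days[1])), tolerance = 0.02)

  sc2 <- generate_session(sp)
  expect_identical(sc$session$frames[[5]]$pixels, sc2$session$frames[[5]]$pixels)
  expect_identical(sc$truth$areas, sc2$truth$areas)
})

test_that("the dip places the within-light-period minimum inside the dip window", {
  sp <- scene_spec(width = 200, height = 120, n_cols = 2, n_rows = 1,
                   dip_amplitude = 0.10, dip_hours = 2, n_days = 1, rng_seed = 9)
  sc <- generate_session(sp)
  a <- sc$truth$areas[sc$truth$areas$plant_id == 1, ]
  light <- a$frame_index <= 36
  tmin <- a$time_days[light][which.min(a$area_mm2_true[light])]
  expect_gt(tmin, 0)
  expect_lte(tmin * 24, 2)
})

test_that("NIR background darkens monotonically with radius under falloff", {
  sc <- small_scene()
  i <- 37  # first dark frame
  img <- sc$session$frames[[i]]$pixels
  bg <- sc$truth$masks[[i]] == 0
  h <- nrow(img); w <- ncol(img)
  d <- sqrt((row(img) - (h + 1) / 2)^2 + (col(img) - (w + 1) / 2)^2)
  bins <- cut(d[bg], breaks = seq(0, max(d), length.out = 8))
  means <- tapply(img[bg], bins, mean)
  expect_true(all(diff(na.omit(means)) < 0))
})

test_that("a written scene reloads into an identical session", {
  sp <- scene_spec(width = 120, height = 80, n_cols = 2, n_rows = 1,
                   n_days = 1, rng_seed = 13)
  sc <- generate_session(sp)
  dir <- tempfile("scene")
  write_scene(sc, dir)
  back <- load_session(dir, sp$schedule)
  expect_length(back$frames, length(sc$session$frames))
  expect_identical(back$periods, sc$session$periods)
  for (i in c(1, 40, 72)) {
    expect_equal(back$frames[[i]]$pixels, sc$session$frames[[i]]$pixels)
    expect_equal(back$frames[[i]]$modality, sc$session$frames[[i]]$modality)
  }
  truth_back <- read_traits(file.path(dir, "truth_areas.csv"))
  expect_equal(truth_back$area_px, sc$truth$areas$area_px)
})
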