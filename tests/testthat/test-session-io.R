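test_that("photoperiod partition is half-open and matches brute-force enumeration", {
  sch <- photoperiod_schedule("08:00", "20:00", 20)
  # 105 frames at 20-min spacing starting 20 min after lights-on span
  # light -> dark -> light; forced counts 35, 36, 34
  times <- as.POSIXct("2024-04-01 08:20", tz = "UTC") + (0:104) * 1200
  dir <- write_png_session(times)
  sess <- load_session(dir, sch)
  expect_equal(nrow(sess$periods), 3L)
  expect_equal(sess$periods$kind, c("light", "dark", "light"))
  expect_equal(sess$periods$n_frames, c(35L, 36L, 34L))

  # independent oracle: classify each timestamp directly against the clock
  lt <- as.POSIXlt(times)
  mins <- lt$hour * 60 + lt$min
  oracle_kind <- ifelse(mins >= 8 * 60 & mins < 20 * 60, "light", "dark")
  r <- rle(oracle_kind)
  expect_equal(sess$periods$n_frames, r$lengths)
  expect_equal(sess$periods$kind, r$values)

  # partition is exhaustive and disjoint
  covered <- unlist(Map(seq, sess$periods$first_frame, sess$periods$last_frame))
  expect_equal(sort(covered), seq_along(times))

  # frame exactly at lights_off is the first dark frame
  i_off <- which(format(times, "%H:%M") == "20:00")
  expect_equal(sess$frames[[i_off]]$modality, "NIR")
  dark <- sess$periods[sess$periods$kind == "dark", ]
  expect_equal(dark$first_frame[1], i_off)
})

test_that("a sequence inside one photoperiod forms a single light period", {
  sch <- photoperiod_schedule("08:00", "20:00", 20)
  times <- as.POSIXct("2024-04-01 08:00", tz = "UTC") + (0:35) * 1200
  sess <- load_session(write_png_session(times), sch)
  expect_equal(nrow(sess$periods), 1L)
  expect_equal(sess$periods$kind, "light")
  expect_equal(sess$periods$n_frames, 36L)
  expect_true(all(vapply(sess$frames, function(f) f$modality, "") == "VIS"))
})

test_that("loading is idempotent and error cases are reported", {
  sch <- photoperiod_schedule()
  times <- as.POSIXct("2024-04-01 09:00", tz = "UTC") + (0:3) * 1200
  dir <- write_png_session(times)
  s1 <- load_session(dir, sch)
  s2 <- load_session(dir, sch)
  expect_identical(lapply(s1$frames, `[[`, "pixels"),
                   lapply(s2$frames, `[[`, "pixels"))
  expect_identical(s1$periods, s2$periods)

  expect_error(load_session(tempfile("empty"), sch), "no image files")

  # bad timestamp substring -> error naming the file
  bad <- tempfile("bad"); dir.create(bad)
  png::writePNG(matrix(0.5, 4, 4), file.path(bad, "img_2024-99-99T99-99.png"))
  expect_error(load_session(bad, sch), "unparseable.*2024-99-99")

  # mixed raster dimensions -> error
  mix <- write_png_session(times[1:2])
  png::writePNG(array(0.5, c(16, 16, 3)),
                file.path(mix, "img_2024-04-01T10-00.png"))
  expect_error(load_session(mix, sch), "identical raster dimensions")
})

test_that("mask write/read round trip is bit-exact and one file per frame", {
  sch <- photoperiod_schedule()
  times <- as.POSIXct("2024-04-01 08:00", tz = "UTC") + (0:34) * 1200
  sess <- load_session(write_png_session(times, size = 12), sch)
  set.seed(3)
  masks <- replicate(35, matrix(sample(0:2, 144, replace = TRUE), 12, 12),
                     simplify = FALSE)
  out <- tempfile("masks")
  paths <- write_masks(sess, masks, out)
  expect_length(paths, 35L)
  for (i in c(1, 17, 35)) {
    expect_identical(read_mask(paths[i]), matrix(as.integer(masks[[i]]), 12, 12))
  }
  # all-zero mask decodes to all zeros
  zi <- tempfile(fileext = ".png")
  png::writePNG(matrix(0L, 12, 12) / 255, zi)
  expect_true(all(read_mask(zi) == 0L))
  # dimension mismatch is refused
  expect_error(write_masks(sess, c(masks[-1], list(matrix(0L, 5, 5))), out),
               "dimensions")
})

test_that("trait CSV round trip preserves values and unit conversion", {
  tab <- tibble::tibble(
    plant_id = rep(1:2, each = 3),
    timestamp = rep(as.POSIXct("2024-04-01 08:00", tz = "UTC") + (0:2) * 1200, 2),
    frame_index = rep(1:3, 2),
    period_index = 1L, period_kind = "light",
    pra_px = c(400, 410, 420, 100, 105, 110),
    pra_mm2 = c(400, 410, 420, 100, 105, 110) * 0.5^2
  )
  path <- tempfile(fileext = ".csv")
  write_traits(tab, path)
  lines <- readLines(path)
  expect_length(lines, 7L)  # header + 6 rows
  back <- read_traits(path)
  expect_equal(back$pra_px, tab$pra_px)
  expect_equal(back$pra_mm2, tab$pra_mm2)
  expect_equal(back$pra_mm2[1], 100)  # 400 px at 0.5 mm/px
  expect_equal(names(back)[1:7], names(tab))
})
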