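test_that("the exact partition of a piecewise-constant image is a fixed point", {
  # exact for the pure two-region model (mu = 0); with a length penalty the
  # minimiser smooths rasterisation jaggies, which the Dice tests cover
  dk <- disk_image()
  res <- chan_vese(dk$img, dk$truth, chan_vese_params(mu = 0))
  expect_identical(res$mask, dk$truth)
  expect_equal(dice(res$mask, dk$truth), 1.0)
})

test_that("perturbed initialisations converge to the disk with high Dice", {
  dk <- disk_image()
  for (delta in c(-5, 5)) {
    init <- dk$dist <= 20 + delta
    dirn <- if (delta > 0) "contract" else "expand"
    res <- chan_vese(dk$img, init, chan_vese_params(direction = dirn))
    expect_gte(dice(res$mask, dk$truth), 0.98)
    expect_true(all(diff(res$state$energy_trace) <= 1e-9))
  }
})

test_that("region means in the returned state are the arithmetic means", {
  dk <- disk_image(noise_sd = 8, seed = 5)
  res <- chan_vese(dk$img, dk$dist <= 23, chan_vese_params(direction = "contract"))
  I <- dk$img / 255
  expect_equal(res$state$c_in, mean(I[res$mask]))
  expect_equal(res$state$c_out, mean(I[!res$mask]))
  expect_true(is.finite(res$state$energy))
})

test_that("degenerate inputs follow the stated contracts", {
  cst <- matrix(100, 30, 30)
  init <- matrix(FALSE, 30, 30); init[10:20, 10:20] <- TRUE
  expect_warning(res <- chan_vese(cst, init), "degenerate")
  expect_identical(res$mask, init)
  expect_error(chan_vese(cst, matrix(FALSE, 30, 30)), "empty initialization")
})

test_that("energy is non-increasing across iterations on noisy images", {
  set.seed(77)
  for (k in 1:5) {
    dk <- disk_image(r = 15 + 3 * k, noise_sd = 12, seed = k)
    init <- dk$dist <= 15 + 3 * k + sample(c(-4, 4), 1)
    res <- chan_vese(dk$img, init)
    expect_true(all(diff(res$state$energy_trace) <= 1e-9))
  }
})

test_that("propagation over a stationary dark period stays on the plants", {
  sc <- small_scene("static", growth_rate = 0, dip_amplitude = 0, rng_seed = 55)
  per <- sc$session$periods
  dk <- which(per$kind == "dark")[1]
  idx <- per$first_frame[dk]:(per$first_frame[dk] + 9)
  seed <- sc$truth$masks[[idx[1]]]
  out <- propagate_dark_period(sc$session$frames[idx], seed, "forward")
  expect_length(out, 10L)
  first <- out[[1]]
  for (m in out) expect_gte(dice(m > 0, first > 0), 0.99)
})

test_that("forward propagation tracks growing plants and keeps their labels", {
  sc <- small_scene()
  per <- sc$session$periods
  dk <- which(per$kind == "dark")[1]
  idx <- per$first_frame[dk]:per$last_frame[dk]
  seed <- sc$truth$masks[[idx[1] - 1L]]
  out <- propagate_dark_period(sc$session$frames[idx], seed, "forward")
  expect_length(out, length(idx))
  expect_setequal(setdiff(unique(as.vector(out[[length(out)]])), 0L), 1:6)
  # per-plant areas non-decreasing within 2% (plants grow through the night)
  for (k in 1:6) {
    areas <- vapply(out, function(m) sum(m == k), double(1))
    expect_true(all(diff(areas) >= -0.02 * areas[-length(areas)]))
  }
})

test_that("average_passes means the two series and falls back on missing", {
  f <- tibble::tibble(plant_id = c(1, 1, 2), frame_index = c(1, 2, 1),
                      pra_px = c(100, 0, 100), missing = c(FALSE, TRUE, FALSE))
  r <- tibble::tibble(plant_id = c(1, 1, 2), frame_index = c(1, 2, 1),
                      pra_px = c(110, 96, 100), missing = FALSE)
  avg <- average_passes(f, r)
  expect_equal(avg$pra_px[avg$plant_id == 1 & avg$frame_index == 1], 105)
  expect_equal(avg$pra_px[avg$plant_id == 1 & avg$frame_index == 2], 96)
  expect_equal(avg$pra_px[avg$plant_id == 2], 100)  # equal inputs pass through
  expect_false(any(avg$missing))
  # output bounded by the pair everywhere
  expect_true(all(avg$pra_px >= pmin(f$pra_px, r$pra_px) - 1e-12 |
                  f$missing | r$missing))
  expect_true(all(avg$pra_px <= pmax(f$pra_px, r$pra_px) + 1e-12))
  # mismatched frame sets are refused
  expect_error(average_passes(f[1:2, ], r), "different")
})
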