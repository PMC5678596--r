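#' Synthetic diel scene specification
#'
#' Defines a tray of non-touching rosettes growing exponentially under a
#' photoperiod schedule, rendered as VIS (RGB) frames in the light phase and
#' NIR (grayscale) frames in the dark phase, with per-frame ground-truth
#' masks and areas. Per plant, the true area follows
#' `A(t) = A0 * exp(r t) * (1 - dip(t))` where `dip(t)` is a half-sine of
#' amplitude `dip_amplitude` over `dip_hours` after each lights-on (the
#' top-view signature of epinastic leaf movement) and zero otherwise.
#'
#' Defaults emulate a 6x3 tray of 18 Arabidopsis-like rosettes at 0.25 mm/px
#' with wild-type-like growth; `scene_preset()` switches between the
#' wild-type-like contrast (r = 0.20 day^-1, 10% dawn dip) and a slow
#' mutant-like one (r = 0.08 day^-1, no dip).
#'
#' @param width,height Raster size in pixels.
#' @param n_cols,n_rows Plant grid layout (`n_cols * n_rows` plants).
#' @param mm_per_pixel Pixel calibration.
#' @param initial_area_mm2 Per-plant PRA at t = 0 (mm^2); recycled.
#' @param growth_rate Per-plant RER r in day^-1; recycled.
#' @param leaf_count,lobedness Rosette stamp shape: number of leaf lobes and
#'   relative lobe depth in `[0, 1)`.
#' @param plant_hsv Length-3 HSV of plant pixels (hue degrees, s, v).
#' @param hue_jitter,value_jitter Per-pixel VIS jitter SDs.
#' @param soil_rgb Length-3 soil base colour on `[0, 255]`.
#' @param soil_noise Per-pixel per-channel soil texture SD (grey levels).
#' @param nir_plant,nir_soil NIR reflectance of plant and soil pixels.
#' @param nir_falloff Radial illumination falloff strength in `[0, 1)`:
#'   intensity is multiplied by `1 - falloff * (d / d_max)^2`.
#' @param nir_noise Additive Gaussian NIR noise SD (grey levels).
#' @param dip_amplitude Relative dawn PRA dip in `[0, 0.5]`.
#' @param dip_hours Dip duration after lights-on, hours.
#' @param schedule A [photoperiod_schedule()].
#' @param interval_minutes Frame interval.
#' @param n_days Session length in days.
#' @param rng_seed Integer seed; the whole scene is reproducible from it.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width = 520, height = 280, n_cols = 6, n_rows = 3,
                       mm_per_pixel = 0.25,
                       initial_area_mm2 = 60, growth_rate = 0.20,
                       leaf_count = 8, lobedness = 0.15,
                       plant_hsv = c(120, 0.55, 0.45),
                       hue_jitter = 6, value_jitter = 0.04,
                       soil_rgb = c(110, 80, 55), soil_noise = 12,
                       nir_plant = 200, nir_soil = 80,
                       nir_falloff = 0.3, nir_noise = 5,
                       dip_amplitude = 0.10, dip_hours = 2,
                       schedule = photoperiod_schedule("08:00", "20:00", 20),
                       interval_minutes = 20, n_days = 1,
                       rng_seed = 42) {
  n_plants <- n_cols * n_rows
  stopifnot(dip_amplitude >= 0, dip_amplitude <= 0.5,
            nir_falloff >= 0, nir_falloff < 1,
            lobedness >= 0, lobedness < 1,
            all(is.finite(growth_rate)), all(initial_area_mm2 > 0))
  spec <- list(width = width, height = height, n_cols = n_cols, n_rows = n_rows,
               n_plants = n_plants, mm_per_pixel = mm_per_pixel,
               initial_area_mm2 = rep_len(initial_area_mm2, n_plants),
               growth_rate = rep_len(growth_rate, n_plants),
               leaf_count = leaf_count, lobedness = lobedness,
               plant_hsv = plant_hsv, hue_jitter = hue_jitter,
               value_jitter = value_jitter,
               soil_rgb = soil_rgb, soil_noise = soil_noise,
               nir_plant = nir_plant, nir_soil = nir_soil,
               nir_falloff = nir_falloff, nir_noise = nir_noise,
               dip_amplitude = dip_amplitude, dip_hours = dip_hours,
               schedule = schedule, interval_minutes = interval_minutes,
               n_days = n_days, rng_seed = as.integer(rng_seed))
  structure(spec, class = "scene_spec")
}

#' @rdname scene_spec
#' @param preset `"wt"` (wild-type-like) or `"mutant"` (slow, dip-free).
#' @param ... Overrides passed on to [scene_spec()].
#' @export
scene_preset <- function(preset = c("wt", "mutant"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    wt = list(growth_rate = 0.20, dip_amplitude = 0.10),
    mutant = list(growth_rate = 0.08, dip_amplitude = 0))
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

#' Render one rosette stamp
#'
#' A smoothed star polygon with `leaf_count` lobes, `r(theta) = R * (1 +
#' lobedness * cos(leaf_count * (theta - rotation)))`, rasterised and scaled
#' by bisection on R so the pixel count is within 1% of the target (counts
#' are integers, so very small targets resolve to the nearest achievable
#' count). Deterministic given its arguments.
#'
#' @param area_px Target pixel count, >= 1.
#' @param leaf_count,lobedness Shape parameters.
#' @param rotation Lobe phase in radians.
#' @param max_radius Error if the stamp radius would exceed this (cell bound).
#' @return Logical matrix containing the stamp, with attribute `area_px`.
#' @export
render_rosette <- function(area_px, leaf_count = 8, lobedness = 0.15,
                           rotation = 0, max_radius = Inf) {
  stopifnot(area_px >= 1)
  shape_area <- pi * (1 + lobedness^2 / 2)  # area of r(theta) at R = 1
  R0 <- sqrt(area_px / shape_area)
  rasterise <- function(R) {
    half <- ceiling(R * (1 + lobedness)) + 1L
    n <- 2L * half + 1L
    cy <- cx <- half + 1L
    yy <- matrix(seq_len(n) - cy, n, n)
    xx <- t(yy)
    d <- sqrt(xx^2 + yy^2)
    th <- atan2(yy, xx)
    d <= R * (1 + lobedness * cos(leaf_count * (th - rotation)))
  }
  count_at <- function(R) sum(rasterise(R))
  lo <- R0 * 0.8; hi <- R0 * 1.25
  while (count_at(hi) < area_px && hi < 4 * R0) hi <- hi * 1.2
  while (count_at(lo) > area_px && lo > R0 / 4) lo <- lo * 0.8
  best_R <- R0; best_err <- Inf
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    cnt <- count_at(mid)
    err <- abs(cnt - area_px)
    if (err < best_err) { best_err <- err; best_R <- mid }
    if (err <= max(1, 0.005 * area_px)) { best_R <- mid; break }
    if (cnt < area_px) lo <- mid else hi <- mid
  }
  if (best_R * (1 + lobedness) > max_radius)
    stop("target area exceeds the plant cell size")
  stamp <- rasterise(best_R)
  attr(stamp, "area_px") <- sum(stamp)
  stamp
}

dip_fraction <- function(t_days, schedule, amplitude, dip_hours) {
  if (amplitude <= 0 || dip_hours <= 0) return(rep(0, length(t_days)))
  # hours since the most recent lights-on (session starts at lights-on)
  h_since_on <- (t_days * 24) %% 24
  u <- h_since_on / dip_hours
  ifelse(u >= 0 & u < 1, amplitude * sin(pi * u), 0)
}

radial_falloff_field <- function(h, w, strength) {
  if (strength <= 0) return(matrix(1, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d <- sqrt((row(matrix(0, h, w)) - cy)^2 + (col(matrix(0, h, w)) - cx)^2)
  dmax <- sqrt((h / 2)^2 + (w / 2)^2)
  1 - strength * (d / dmax)^2
}

#' Generate a synthetic diel session with ground truth
#'
#' Renders the full time-lapse described by a [scene_spec()]: VIS frames
#' (textured soil + colour-jittered rosettes) in the light phase, NIR frames
#' (reflectance x radial falloff + Gaussian noise) in the dark phase. Rosette
#' edges are hard (not antialiased) so the recorded ground truth is exact at
#' pixel resolution. Fully reproducible from `rng_seed`.
#'
#' @param spec A [scene_spec()].
#' @param start Session start timestamp; defaults to lights-on so that frame
#'   times align with the photoperiod.
#' @return List with `session` (a `diel_session`) and `truth`, itself a list:
#'   `masks` (per-frame integer label matrices), `areas` (tibble: `plant_id`,
#'   `frame_index`, `time_days`, `area_mm2_true` — the analytic target —,
#'   `area_px` — the exact rasterised count —, `area_mm2_px`), and `spec`.
#' @export
generate_session <- function(spec, start = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  sch <- spec$schedule
  if (is.null(start)) {
    start <- as.POSIXct(sprintf("2024-04-01 %02d:%02d:00",
                                sch$lights_on %/% 60, sch$lights_on %% 60),
                        tz = "UTC")
  }
  n_frames <- as.integer(spec$n_days * 24 * 60 / spec$interval_minutes)
  t_days <- (seq_len(n_frames) - 1L) * spec$interval_minutes / 1440
  times <- start + t_days * 86400
  h <- spec$height; w <- spec$width
  cell_w <- w / spec$n_cols; cell_h <- h / spec$n_rows
  cell_r <- min(cell_w, cell_h) / 2

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)

  # fixed per-plant geometry: grid cell centres with small jitter + rotation
  plants <- tibble::tibble(
    plant_id = seq_len(spec$n_plants),
    col = rep(seq_len(spec$n_cols), times = spec$n_rows),
    row = rep(seq_len(spec$n_rows), each = spec$n_cols),
    cx = 0, cy = 0, rotation = stats::runif(spec$n_plants, 0, 2 * pi)
  )
  plants$cx <- round((plants$col - 0.5) * cell_w + stats::runif(spec$n_plants, -2, 2))
  plants$cy <- round((plants$row - 0.5) * cell_h + stats::runif(spec$n_plants, -2, 2))

  px_per_mm2 <- 1 / spec$mm_per_pixel^2
  falloff <- radial_falloff_field(h, w, spec$nir_falloff)
  mins_of_day <- (as.POSIXlt(times)$hour * 60 + as.POSIXlt(times)$min)
  is_light <- in_light_phase(mins_of_day, sch)
  dip <- dip_fraction(t_days, sch, spec$dip_amplitude, spec$dip_hours)

  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  area_rows <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    lab <- matrix(0L, h, w)
    apx <- numeric(spec$n_plants)
    amm <- numeric(spec$n_plants)
    for (k in seq_len(spec$n_plants)) {
      a_mm2 <- spec$initial_area_mm2[k] * exp(spec$growth_rate[k] * t_days[i]) * (1 - dip[i])
      target_px <- max(1, round(a_mm2 * px_per_mm2))
      stamp <- render_rosette(target_px, spec$leaf_count, spec$lobedness,
                              rotation = plants$rotation[k],
                              max_radius = cell_r - 2)
      sh <- nrow(stamp); half <- (sh - 1L) %/% 2L
      r0 <- plants$cy[k] - half; c0 <- plants$cx[k] - half
      rr <- r0:(r0 + sh - 1L); cc <- c0:(c0 + sh - 1L)
      keep_r <- rr >= 1 & rr <= h; keep_c <- cc >= 1 & cc <= w
      sub <- lab[rr[keep_r], cc[keep_c]]
      stn <- stamp[keep_r, keep_c]
      sub[stn & sub == 0L] <- k
      lab[rr[keep_r], cc[keep_c]] <- sub
      amm[k] <- a_mm2
    }
    apx <- tabulate(lab[lab > 0L], nbins = spec$n_plants)
    masks[[i]] <- lab
    fg <- lab > 0L
    if (is_light[i]) {
      n_fg <- sum(fg)
      base <- array(0, dim = c(h, w, 3))
      for (ch in 1:3) {
        soil <- matrix(stats::rnorm(h * w, spec$soil_rgb[ch], spec$soil_noise), h, w)
        base[, , ch] <- soil
      }
      if (n_fg) {
        hh <- stats::rnorm(n_fg, spec$plant_hsv[1], spec$hue_jitter)
        ss <- pmin(pmax(stats::rnorm(n_fg, spec$plant_hsv[2], 0.04), 0), 1)
        vv <- pmin(pmax(stats::rnorm(n_fg, spec$plant_hsv[3], spec$value_jitter), 0), 1)
        rgb <- hsv_to_rgb255(hh, ss, vv)
        for (ch in 1:3) {
          plane <- base[, , ch]
          plane[fg] <- rgb[, ch]
          base[, , ch] <- plane
        }
      }
      px <- round(clip255(base))
      frames[[i]] <- new_frame(px, times[i], "VIS")
    } else {
      refl <- matrix(spec$nir_soil, h, w)
      refl[fg] <- spec$nir_plant
      img <- refl * falloff + matrix(stats::rnorm(h * w, 0, spec$nir_noise), h, w)
      frames[[i]] <- new_frame(round(clip255(img)), times[i], "NIR")
    }
    area_rows[[i]] <- tibble::tibble(
      plant_id = seq_len(spec$n_plants), frame_index = i,
      time_days = t_days[i],
      area_mm2_true = amm, area_px = as.numeric(apx),
      area_mm2_px = apx * spec$mm_per_pixel^2
    )
  }
  session <- new_diel_session(frames, sch)
  truth <- list(masks = masks, areas = dplyr::bind_rows(area_rows), spec = spec)
  list(session = session, truth = truth)
}

#' Write a synthetic scene to disk in the formats the pipeline reads
#'
#' VIS frames as RGB PNG, NIR frames as grayscale PNG (timestamps encoded in
#' the filenames), ground-truth label masks under `truth_masks/`, and the
#' true-area table as `truth_areas.csv`.
#'
#' @param scene Output of [generate_session()].
#' @param out_dir Target directory.
#' @return Invisibly, `out_dir`.
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in scene$session$frames) {
    path <- file.path(out_dir, paste0(f$name, ".png"))
    png::writePNG(if (f$modality == "VIS") f$pixels / 255 else f$pixels / 255, path)
  }
  tm <- file.path(out_dir, "truth_masks")
  write_masks(scene$session, scene$truth$masks, tm)
  readr::write_csv(scene$truth$areas, file.path(out_dir, "truth_areas.csv"))
  invisible(out_dir)
}

#' Simulate a bare PRA time series
#'
#' Analytic exponential growth with the dawn-dip modulation and optional
#' multiplicative observation noise — no rendering involved. Useful for
#' validating the RER estimators in isolation.
#'
#' @param r Growth rate, day^-1.
#' @param a0 Initial PRA (mm^2).
#' @param n_days Length in days.
#' @param interval_minutes Sampling interval.
#' @param noise_cv Multiplicative noise SD (e.g. 0.02 for 2%); log-normal,
#'   `value = A(t) * exp(rnorm(0, noise_cv))`.
#' @param dip_amplitude,dip_hours Dawn-dip parameters (default: none).
#' @param schedule Photoperiod schedule (frame 1 at lights-on).
#' @param plant_id Identifier stored in the series.
#' @param seed Optional RNG seed for the noise.
#' @return PRA series tibble as from [pra_series()].
#' @export
simulate_pra_series <- function(r, a0 = 60, n_days = 3, interval_minutes = 20,
                                noise_cv = 0, dip_amplitude = 0, dip_hours = 2,
                                schedule = photoperiod_schedule("08:00", "20:00", 20),
                                plant_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_days * 24 * 60 / interval_minutes)
  t_days <- (seq_len(n) - 1L) * interval_minutes / 1440
  a <- a0 * exp(r * t_days) * (1 - dip_fraction(t_days, schedule, dip_amplitude, dip_hours))
  if (noise_cv > 0) a <- a * exp(stats::rnorm(n, 0, noise_cv))
  tibble::tibble(plant_id = as.integer(plant_id), time_days = t_days, pra = a,
                 missing = FALSE, frame_index = seq_len(n))
}

#' Period table for a simulated PRA series
#'
#' The light/dark period partition (frame-index based) that a rendered
#' session with the same schedule would produce; pairs with
#' [simulate_pra_series()] for driving [daily_rer()] without rendering.
#'
#' @param n_days,interval_minutes,schedule As in [simulate_pra_series()].
#' @return Period tibble (`period_index`, `kind`, `first_frame`,
#'   `last_frame`, `n_frames`).
#' @export
simulated_periods <- function(n_days = 3, interval_minutes = 20,
                              schedule = photoperiod_schedule("08:00", "20:00", 20)) {
  n <- as.integer(n_days * 24 * 60 / interval_minutes)
  t_days <- (seq_len(n) - 1L) * interval_minutes / 1440
  mins <- (schedule$lights_on + t_days * 1440) %% 1440
  kind <- ifelse(in_light_phase(mins, schedule), "light", "dark")
  r <- rle(kind)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  tibble::tibble(period_index = seq_along(r$values), kind = r$values,
                 first_frame = starts, last_frame = ends, n_frames = r$lengths)
}
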