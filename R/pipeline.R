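#' Read a pipeline configuration file
#'
#' YAML with keys: `input_dir`, `output_dir`, `schedule` (`lights_on`,
#' `lights_off`, `interval_minutes`), `calibration` (`mm_per_pixel`),
#' `threshold` (`space`, `ranges` — six numbers, low/high per channel),
#' `clean` (`min_area_px`, `fill_holes`), `illumination` (`enabled`,
#' `blur_sigma`, `flatten_strength`), `chanvese` (`mu`, `lambda_in`,
#' `lambda_out`, `max_iters`, `tol`, `bias`), `labelling` (`mode` =
#' `auto`/`seeded`, `seed_file`, `max_dist`), `rer` (`window`). Missing keys
#' fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A named list with the same structure as the YAML file.
#' @export
as_pipeline_config <- function(cfg) {
  sch <- cfg$schedule %||% list()
  schedule <- photoperiod_schedule(sch$lights_on %||% "08:00",
                                   sch$lights_off %||% "20:00",
                                   sch$interval_minutes %||% 20)
  thr <- cfg$threshold %||% list()
  spec <- threshold_spec(thr$space %||% "HSV",
                         if ((thr$space %||% "HSV") == "GRAY_OTSU") NULL
                         else unlist(thr$ranges %||% c(90, 150, 0.2, 1, 0.1, 1)))
  ill <- cfg$illumination %||% list()
  cv <- cfg$chanvese %||% list()
  lb <- cfg$labelling %||% list()
  cl <- cfg$clean %||% list()
  structure(list(
    input_dir = cfg$input_dir,
    output_dir = cfg$output_dir,
    schedule = schedule,
    calibration = calibration_spec((cfg$calibration %||% list())$mm_per_pixel %||% 1),
    threshold = spec,
    clean = list(min_area_px = cl$min_area_px %||% 25,
                 fill_holes = cl$fill_holes %||% TRUE),
    illumination = illumination_params(ill$blur_sigma,
                                       ill$flatten_strength %||% 0.5,
                                       ill$enabled %||% TRUE),
    chanvese = chan_vese_params(cv$mu %||% 0.2, cv$lambda_in %||% 1,
                                cv$lambda_out %||% 1, cv$max_iters %||% 200,
                                cv$tol %||% 1e-4, bias = cv$bias %||% 2),
    labelling = list(mode = lb$mode %||% "auto", seed_file = lb$seed_file,
                     max_dist = lb$max_dist %||% Inf),
    rer_window = (cfg$rer %||% list())$window %||% 10
  ), class = "pipeline_config")
}

#' Run the full diel workflow on an in-memory session
#'
#' Light periods: every VIS frame is range-thresholded, cleaned, and labelled
#' — the first frame of the first light period by left-to-right numbering (or
#' from seeds), after which labels are locked and propagated by
#' nearest-centroid matching (fragments of a split plant merge into its id).
#' Dark periods: Chan-Vese propagation seeded from the preceding light
#' period's last mask (forward, expansion bias) and from the following light
#' period's first mask (reverse, contraction bias); the two PRA series are
#' averaged. A dark period without one of its flanking light periods uses the
#' single available pass.
#'
#' @param session A `diel_session`.
#' @param config A `pipeline_config` (see [as_pipeline_config()]); its
#'   `input_dir`/`output_dir` are ignored here.
#' @param seeds Optional seed tibble overriding auto labelling.
#' @return A `diel_traits` object: list with `traits` (tibble: one row per
#'   plant per frame), `daily` and `diel` RER series, `masks` (canonical,
#'   forward for dark frames), `masks_reverse` (dark frames only, named by
#'   frame index), `warnings`, and the `config`/`session` metadata.
#' @export
process_session <- function(session, config = as_pipeline_config(list()),
                            seeds = NULL) {
  frames <- session$frames
  periods <- session$periods
  warn_log <- character(0)
  note <- function(...) warn_log <<- c(warn_log, sprintf(...))
  masks <- vector("list", length(frames))
  n_plants <- NULL
  ref <- NULL  # locked per-plant centroids, updated every labelled frame

  # --- light periods: stateless per-frame thresholding ---
  light_rows <- which(periods$kind == "light")
  for (pi in light_rows) {
    for (i in periods$first_frame[pi]:periods$last_frame[pi]) {
      f <- frames[[i]]
      if (f$modality != "VIS") {
        note("frame %d inside light period %d is not VIS; skipped", i, pi)
        next
      }
      bin <- if (config$threshold$space == "GRAY_OTSU") {
        lum <- 0.299 * f$pixels[, , 1] + 0.587 * f$pixels[, , 2] + 0.114 * f$pixels[, , 3]
        otsu_threshold(round(lum))$mask
      } else {
        threshold_ranges(f, config$threshold)
      }
      bin <- clean_mask(bin, config$clean$min_area_px, config$clean$fill_holes)
      if (is.null(ref)) {
        lab <- if (!is.null(seeds)) label_seeded(bin, seeds, config$labelling$max_dist)
               else label_auto(bin)
        n_plants <- attr(lab, "n_plants")
      } else {
        lab <- match_to_centroids(bin, ref, config$labelling$max_dist)
      }
      cents <- label_centroids(lab)
      if (nrow(cents)) {
        if (is.null(ref)) ref <- cents
        else ref <- dplyr::rows_update(ref, cents[, c("plant_id", "x", "y", "area")],
                                       by = "plant_id", unmatched = "ignore")
      }
      masks[[i]] <- lab
    }
  }
  if (is.null(n_plants) || n_plants == 0)
    stop("no plants found in the first light frame")
  plant_ids <- seq_len(n_plants)
  if (!is.null(seeds)) plant_ids <- sort(seeds$plant_id)

  # --- dark periods: forward/reverse Chan-Vese propagation ---
  dark_rows <- which(periods$kind == "dark")
  masks_reverse <- list()
  dark_pra <- list()
  for (pi in dark_rows) {
    idx <- periods$first_frame[pi]:periods$last_frame[pi]
    nir <- frames[idx]
    seed_fwd <- if (pi > 1 && periods$kind[pi - 1] == "light")
      masks[[periods$last_frame[pi - 1]]] else NULL
    seed_rev <- if (pi < nrow(periods) && periods$kind[pi + 1] == "light")
      masks[[periods$first_frame[pi + 1]]] else NULL
    if (is.null(seed_fwd) && is.null(seed_rev)) {
      note("dark period %d has no adjacent light mask; skipped", pi)
      next
    }
    fwd <- rev_ <- NULL
    if (!is.null(seed_fwd)) {
      fwd <- withCallingHandlers(
        propagate_dark_period(nir, seed_fwd, "forward", config$chanvese,
                              config$illumination),
        warning = function(w) { note("dark period %d fwd: %s", pi, conditionMessage(w))
                                invokeRestart("muffleWarning") })
    }
    if (!is.null(seed_rev)) {
      rev_ <- withCallingHandlers(
        propagate_dark_period(rev(nir), seed_rev, "reverse", config$chanvese,
                              config$illumination),
        warning = function(w) { note("dark period %d rev: %s", pi, conditionMessage(w))
                                invokeRestart("muffleWarning") })
      rev_ <- rev(rev_)  # back to chronological order
    }
    pra_of <- function(mlist) dplyr::bind_rows(lapply(seq_along(mlist), function(j) {
      m <- measure_pra(mlist[[j]], frames[[idx[j]]], config$calibration, plant_ids)
      m$frame_index <- idx[j]
      m
    }))
    if (!is.null(fwd) && !is.null(rev_)) {
      avg <- average_passes(pra_of(fwd), pra_of(rev_))
      for (j in seq_along(idx)) masks_reverse[[as.character(idx[j])]] <- rev_[[j]]
      canon <- fwd
    } else if (!is.null(fwd)) {
      avg <- dplyr::select(pra_of(fwd), "plant_id", "frame_index", "pra_px", "missing")
      canon <- fwd
    } else {
      avg <- dplyr::select(pra_of(rev_), "plant_id", "frame_index", "pra_px", "missing")
      canon <- rev_
    }
    for (j in seq_along(idx)) masks[[idx[j]]] <- canon[[j]]
    dark_pra[[length(dark_pra) + 1L]] <- avg
  }
  dark_pra <- if (length(dark_pra)) dplyr::bind_rows(dark_pra) else NULL

  # --- trait table ---
  t_days <- session_times_days(session)
  frame_period <- integer(length(frames))
  for (pi in seq_len(nrow(periods)))
    frame_period[periods$first_frame[pi]:periods$last_frame[pi]] <- pi
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    if (is.null(masks[[i]])) {
      if (!is.null(dark_pra) && i %in% dark_pra$frame_index) {
        # handled below via averaged areas
      } else {
        note("frame %d produced no mask and no PRA", i)
        next
      }
    }
    base <- if (!is.null(masks[[i]]))
      measure_pra(masks[[i]], frames[[i]], config$calibration, plant_ids)
    else
      tibble::tibble(plant_id = plant_ids, timestamp = frames[[i]]$timestamp,
                     frame_index = i, pra_px = 0, pra_mm2 = 0, missing = TRUE)
    if (!is.null(dark_pra)) {
      dp <- dark_pra[dark_pra$frame_index == i, ]
      if (nrow(dp)) {
        m <- match(base$plant_id, dp$plant_id)
        base$pra_px <- ifelse(is.na(m), base$pra_px, dp$pra_px[m])
        base$missing <- ifelse(is.na(m), base$missing, dp$missing[m])
        base$pra_mm2 <- base$pra_px * config$calibration$mm_per_pixel^2
      }
    }
    base$time_days <- t_days[i]
    base$period_index <- frame_period[i]
    base$period_kind <- periods$kind[frame_period[i]]
    rows[[i]] <- base
  }
  traits <- dplyr::bind_rows(rows)
  series <- pra_series(traits)
  daily <- tryCatch(suppress_to_log(daily_rer(series, session), note),
                    error = function(e) { note("daily RER: %s", conditionMessage(e)); NULL })
  diel <- tryCatch(suppress_to_log(diel_rer(series, config$rer_window), note),
                   error = function(e) { note("diel RER: %s", conditionMessage(e)); NULL })
  structure(list(traits = traits, daily = daily, diel = diel,
                 masks = masks, masks_reverse = masks_reverse,
                 warnings = warn_log, config = config,
                 schedule = session$schedule, periods = periods,
                 n_plants = length(plant_ids)),
            class = "diel_traits")
}

suppress_to_log <- function(expr, note) {
  withCallingHandlers(expr, warning = function(w) {
    note("%s", conditionMessage(w)); invokeRestart("muffleWarning")
  })
}

#' Run the pipeline from a configuration
#'
#' Loads the session from `config$input_dir`, runs [process_session()], and
#' writes the outputs under `config$output_dir`: `masks/` (labelled PNGs;
#' reverse-pass dark masks under `masks_reverse/`), `traits.csv`,
#' `rer_daily.csv`, `rer_diel.csv` and a `manifest.yaml` echoing the
#' configuration, package version and accumulated warnings.
#'
#' @param config A `pipeline_config` or path to a YAML config file.
#' @return The `diel_traits` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input_dir) || !dir.exists(config$input_dir))
    stop("config error: input_dir does not exist")
  out <- config$output_dir %||% stop("config error: output_dir missing")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- NULL
  if (identical(config$labelling$mode, "seeded")) {
    if (is.null(config$labelling$seed_file) || !file.exists(config$labelling$seed_file))
      stop("config error: labelling.mode is 'seeded' but seed_file is missing")
    seeds <- read_seeds(config$labelling$seed_file)
  }
  session <- load_session(config$input_dir, config$schedule)
  res <- process_session(session, config, seeds)
  empty <- matrix(0L, nrow(session$frames[[1]]$pixels), ncol(session$frames[[1]]$pixels))
  write_masks(session, lapply(res$masks, function(m) m %||% empty),
              file.path(out, "masks"))
  if (length(res$masks_reverse)) {
    dir.create(file.path(out, "masks_reverse"), showWarnings = FALSE)
    for (nm in names(res$masks_reverse)) {
      i <- as.integer(nm)
      png::writePNG(res$masks_reverse[[nm]] / 255,
                    file.path(out, "masks_reverse",
                              paste0(session$frames[[i]]$name, "_mask.png")))
    }
  }
  write_traits(res$traits, file.path(out, "traits.csv"))
  if (!is.null(res$daily))
    readr::write_csv(tibble::as_tibble(res$daily), file.path(out, "rer_daily.csv"))
  if (!is.null(res$diel))
    readr::write_csv(tibble::as_tibble(res$diel), file.path(out, "rer_diel.csv"))
  manifest <- list(
    package = "dielpheno",
    version = as.character(utils::packageVersion("dielpheno")),
    run_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_frames = length(session$frames),
    n_plants = res$n_plants,
    warnings = as.list(res$warnings)
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(res)
}

#' @export
print.diel_traits <- function(x, ...) {
  cat(sprintf("Diel trait set: %d plants x %d frames (%d periods); %d warnings\n",
              x$n_plants, length(x$masks), nrow(x$periods), length(x$warnings)))
  invisible(x)
}
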