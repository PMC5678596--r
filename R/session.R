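#' Photoperiod schedule
#'
#' Describes when lights go on and off each day. A frame timestamped at `t`
#' belongs to the light phase iff `t` falls in the half-open clock interval
#' `[lights_on, lights_off)`; a frame at exactly `lights_off` is therefore the
#' first dark frame.
#'
#' @param lights_on,lights_off Clock times as `"HH:MM"` strings.
#' @param interval_minutes Nominal acquisition interval in minutes (metadata;
#'   loading does not enforce it).
#' @return An object of class `photoperiod_schedule` with the parsed clock
#'   times and the light/dark durations in hours (which always sum to 24).
#' @examples
#' photoperiod_schedule("08:00", "20:00")  # a 12:12 cycle
#' @export
photoperiod_schedule <- function(lights_on = "08:00", lights_off = "20:00",
                                 interval_minutes = 20) {
  on <- parse_clock(lights_on)
  off <- parse_clock(lights_off)
  if (on == off) stop("lights_on and lights_off must differ")
  light_h <- ((off - on) %% 1440) / 60
  structure(
    list(lights_on = on, lights_off = off,
         light_hours = light_h, dark_hours = 24 - light_h,
         interval_minutes = interval_minutes),
    class = "photoperiod_schedule"
  )
}

parse_clock <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop("cannot parse clock time: ", x)
  as.integer(m[2]) * 60L + as.integer(m[3])
}

#' @export
print.photoperiod_schedule <- function(x, ...) {
  cat(sprintf("Photoperiod %02d:%02d-%02d:%02d (%g:%g h light:dark), %d-min interval\n",
              x$lights_on %/% 60, x$lights_on %% 60,
              x$lights_off %/% 60, x$lights_off %% 60,
              x$light_hours, x$dark_hours, x$interval_minutes))
  invisible(x)
}

#' Pixel calibration
#'
#' @param mm_per_pixel Physical edge length of one pixel in millimetres;
#'   must be strictly positive. Areas convert as `mm2 = px * mm_per_pixel^2`.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(mm_per_pixel) {
  stopifnot(is.numeric(mm_per_pixel), length(mm_per_pixel) == 1L, mm_per_pixel > 0)
  structure(list(mm_per_pixel = mm_per_pixel), class = "calibration_spec")
}

# is clock time t (minutes past midnight) inside the light phase? [on, off)
in_light_phase <- function(minute_of_day, schedule) {
  on <- schedule$lights_on; off <- schedule$lights_off
  m <- minute_of_day %% 1440
  if (on < off) m >= on & m < off else m >= on | m < off
}

new_frame <- function(pixels, timestamp, modality, frame_index = NA_integer_,
                      name = NULL) {
  stopifnot(modality %in% c("VIS", "NIR"))
  if (modality == "VIS" && !is_rgb_raster(pixels))
    stop("VIS frames must have 3 colour planes")
  if (modality == "NIR" && !is_gray_raster(pixels))
    stop("NIR frames must be single-channel")
  structure(
    list(pixels = pixels, timestamp = timestamp, modality = modality,
         frame_index = frame_index,
         name = name %||% format(timestamp, "frame_%Y-%m-%dT%H-%M")),
    class = "diel_frame"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_diel_session <- function(frames, schedule) {
  ts <- as.numeric(vapply(frames, function(f) as.numeric(f$timestamp), double(1)))
  if (is.unsorted(ts, strictly = TRUE)) stop("frames must be strictly ordered by timestamp")
  dims <- vapply(frames, function(f) raster_dim(f$pixels), double(2))
  if (length(frames) > 1L && any(apply(dims, 1, function(r) length(unique(r)) > 1)))
    stop("all frames in a session must share identical raster dimensions")
  for (i in seq_along(frames)) frames[[i]]$frame_index <- i
  periods <- partition_periods(frames, schedule)
  structure(list(frames = frames, periods = periods, schedule = schedule),
            class = "diel_session")
}

# Periods are maximal runs of frames in the same photoperiod phase, reported as
# half-open frame-index ranges [first, last].
partition_periods <- function(frames, schedule) {
  mins <- vapply(frames, function(f) {
    lt <- as.POSIXlt(f$timestamp)
    lt$hour * 60 + lt$min
  }, double(1))
  kind <- ifelse(in_light_phase(mins, schedule), "light", "dark")
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    period_index = seq_along(r$values),
    kind = r$values,
    first_frame = starts,
    last_frame = ends,
    n_frames = r$lengths
  )
}

#' @export
print.diel_session <- function(x, ...) {
  cat(sprintf("Diel session: %d frames (%d VIS, %d NIR), %d periods\n",
              length(x$frames),
              sum(vapply(x$frames, function(f) f$modality == "VIS", logical(1))),
              sum(vapply(x$frames, function(f) f$modality == "NIR", logical(1))),
              nrow(x$periods)))
  print(x$periods)
  invisible(x)
}

read_raster_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      a <- as.array(img)
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop("unsupported image format: ", path)
  )
  if (is.array(px) && length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1]
  }
  round(px * 255)
}

#' Load a time-lapse session from a directory of images
#'
#' Files are matched with `filename_pattern`, timestamps are parsed from an
#' ISO-8601-like substring of the filename (default `YYYY-MM-DDTHH-MM`; file
#' modification time is used, with a warning, for names without one), frames
#' are sorted by timestamp, and modality is assigned from the photoperiod
#' schedule: a frame at time `t` is VIS iff `t` lies in `[lights_on,
#' lights_off)`. A single-channel image is forced to NIR regardless of the
#' schedule. Maximal runs of same-phase frames become the session's
#' light/dark periods.
#'
#' @param directory Path holding the images (PNG/TIFF/JPEG).
#' @param schedule A [photoperiod_schedule()].
#' @param filename_pattern Regular expression selecting the image files.
#' @param timestamp_pattern,timestamp_format Regex extracting the timestamp
#'   substring and its `strptime` format.
#' @return A `diel_session`: ordered frames plus a period table
#'   (`period_index`, `kind`, frame range).
#' @export
load_session <- function(directory, schedule,
                         filename_pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                         timestamp_pattern = "\\d{4}-\\d{2}-\\d{2}T\\d{2}-\\d{2}",
                         timestamp_format = "%Y-%m-%dT%H-%M") {
  files <- list.files(directory, pattern = filename_pattern,
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[!grepl("_mask\\.", basename(files))]
  if (!length(files)) stop("no image files matching pattern in ", directory)
  ts <- lapply(files, function(f) {
    m <- regmatches(basename(f), regexpr(timestamp_pattern, basename(f)))
    if (!length(m)) {
      warning("no timestamp in filename, using file mtime: ", basename(f))
      return(file.mtime(f))
    }
    t <- as.POSIXct(strptime(m, timestamp_format, tz = "UTC"))
    if (is.na(t)) stop("unparseable timestamp in file: ", basename(f))
    t
  })
  ord <- order(vapply(ts, as.numeric, double(1)))
  files <- files[ord]; ts <- ts[ord]
  tnum <- vapply(ts, as.numeric, double(1))
  if (anyDuplicated(tnum)) stop("duplicate timestamps in session")
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    px <- read_raster_file(files[i])
    lt <- as.POSIXlt(ts[[i]])
    light <- in_light_phase(lt$hour * 60 + lt$min, schedule)
    modality <- if (is_gray_raster(px)) "NIR" else if (light) "VIS" else "NIR"
    if (modality == "NIR" && is_rgb_raster(px)) {
      # dark-phase frame delivered as RGB: collapse to luminance
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    }
    frames[[i]] <- new_frame(px, ts[[i]], modality,
                             name = tools::file_path_sans_ext(basename(files[i])))
  }
  new_diel_session(frames, schedule)
}

#' Write labelled masks as PNG files
#'
#' One losslessly compressed single-channel 8-bit PNG per frame; the pixel
#' value is the plant index (0 = background) and the filename mirrors the
#' source frame (`<frame name>_mask.png`).
#'
#' @param session A `diel_session`.
#' @param masks List of integer label matrices, one per frame.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_masks <- function(session, masks, out_dir) {
  stopifnot(length(masks) == length(session$frames))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- raster_dim(session$frames[[1]]$pixels)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!identical(unname(raster_dim(m)), unname(d)))
      stop("mask ", i, " dimensions do not match the session raster")
    if (max(m) > 255) stop("more than 255 plant labels cannot be stored in 8-bit PNG")
    paths[i] <- file.path(out_dir, paste0(session$frames[[i]]$name, "_mask.png"))
    png::writePNG(m / 255, paths[i])
  }
  invisible(paths)
}

#' Read a labelled mask written by [write_masks()]
#' @param path PNG file path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "double"
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write / read a trait table as CSV
#'
#' Canonical column order: `plant_id, timestamp, frame_index, period_index,
#' period_kind, pra_px, pra_mm2` (plus `missing` when present). One row per
#' plant per frame.
#'
#' @param table Trait tibble.
#' @param path Output CSV path.
#' @return `write_traits` invisibly returns `path`; `read_traits` returns the
#'   parsed tibble.
#' @export
write_traits <- function(table, path) {
  stopifnot(nrow(table) > 0)
  lead <- intersect(c("plant_id", "timestamp", "frame_index", "period_index",
                      "period_kind", "pra_px", "pra_mm2", "missing"),
                    names(table))
  table <- table[, c(lead, setdiff(names(table), lead))]
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

session_times_days <- function(session) {
  t0 <- as.numeric(session$frames[[1]]$timestamp)
  vapply(session$frames, function(f) (as.numeric(f$timestamp) - t0) / 86400, double(1))
}
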