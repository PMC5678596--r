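#' Relative expansion rate between two PRA observations
#'
#' `RER = (ln PRA2 - ln PRA1) / (t2 - t1)` in day^-1: the slope of log area
#' per unit time, positive when the area grows forward in time. (The same
#' quantity is often written `(ln PRA1 - ln PRA2)/(t1 - t2)`; the two forms
#' are algebraically identical.)
#'
#' @param pra1,pra2 Areas (any consistent unit), strictly positive.
#' @param t1,t2 Times in days, `t1 != t2`.
#' @return Rate in day^-1.
#' @examples
#' rer(100, 100 * exp(0.2), 0, 1)  # 0.2 day^-1
#' @export
rer <- function(pra1, pra2, t1, t2) {
  if (any(pra1 <= 0) || any(pra2 <= 0)) stop("log of non-positive PRA")
  if (any(t1 == t2)) stop("t1 and t2 must differ")
  (log(pra2) - log(pra1)) / (t2 - t1)
}

#' Build a per-plant PRA series from a trait table
#'
#' @param traits Trait tibble (one row per plant per frame) with `plant_id`,
#'   `frame_index`, a time column and a PRA column.
#' @param time_col,value_col Column names for time (days) and PRA.
#' @return Tibble grouped-ready series with `plant_id`, `time_days`, `pra`,
#'   `missing`, `frame_index`.
#' @export
pra_series <- function(traits, time_col = "time_days", value_col = "pra_mm2") {
  stopifnot(all(c("plant_id", time_col, value_col) %in% names(traits)))
  out <- tibble::tibble(
    plant_id = traits$plant_id,
    time_days = traits[[time_col]],
    pra = traits[[value_col]],
    missing = if ("missing" %in% names(traits)) traits$missing else FALSE,
    frame_index = if ("frame_index" %in% names(traits)) traits$frame_index else NA_integer_
  )
  dplyr::arrange(out, .data$plant_id, .data$time_days)
}

#' Daily RER from light-period endpoints
#'
#' One RER per light period and plant, computed between the first and last
#' VIS frames of that period. Periods with a missing endpoint are skipped
#' with a warning.
#'
#' @param series PRA series tibble (see [pra_series()]).
#' @param session The `diel_session` (supplies the period partition), or a
#'   period tibble with `period_index`, `kind`, `first_frame`, `last_frame`.
#' @return Tibble with `plant_id`, `period_index`, `t_start`, `t_end`,
#'   `rer_per_day`; class `rer_series`, kind `"daily"`.
#' @export
daily_rer <- function(series, session) {
  periods <- if (inherits(session, "diel_session")) session$periods else session
  light <- periods[periods$kind == "light", , drop = FALSE]
  if (!nrow(light)) stop("no complete light period in session")
  rows <- list()
  for (pid in unique(series$plant_id)) {
    s <- series[series$plant_id == pid, ]
    for (k in seq_len(nrow(light))) {
      i1 <- light$first_frame[k]; i2 <- light$last_frame[k]
      a <- s[s$frame_index == i1, ]; b <- s[s$frame_index == i2, ]
      if (!nrow(a) || !nrow(b) || a$missing[1] || b$missing[1] ||
          a$pra[1] <= 0 || b$pra[1] <= 0 || i1 == i2) {
        warning(sprintf("plant %s: light period %d endpoint missing, skipped",
                        pid, light$period_index[k]))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant_id = pid, period_index = light$period_index[k],
        t_start = a$time_days[1], t_end = b$time_days[1],
        rer_per_day = rer(a$pra[1], b$pra[1], a$time_days[1], b$time_days[1])
      )
    }
  }
  if (!length(rows)) stop("no complete light period with valid endpoints")
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rer_series", class(out)), kind = "daily")
}

#' Multi-day average of daily RER values
#'
#' Arithmetic mean of daily RER over consecutive blocks of `days` light
#' periods (e.g. the common 3-day bars).
#'
#' @param daily Output of [daily_rer()].
#' @param days Block length in light periods.
#' @return Tibble with `plant_id`, `block`, `rer_per_day`.
#' @export
average_daily_rer <- function(daily, days = 3) {
  daily |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::arrange(.data$period_index, .by_group = TRUE) |>
    dplyr::mutate(block = (dplyr::row_number() - 1L) %/% days + 1L) |>
    dplyr::group_by(.data$plant_id, .data$block) |>
    dplyr::summarise(rer_per_day = mean(.data$rer_per_day), .groups = "drop")
}

# centred sliding median; window w covers offsets -floor((w-1)/2)..ceiling((w-1)/2).
# partial = TRUE shrinks the window at the edges instead of dropping them.
sliding_median <- function(x, w, partial = FALSE) {
  n <- length(x)
  lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- i - lo; b <- i + hi
    if (a < 1 || b > n) {
      if (!partial) next
      a <- max(1, a); b <- min(n, b)
    }
    out[i] <- stats::median(x[a:b])
  }
  out
}

#' Diel RER with a sliding-median window
#'
#' The PRA series is first smoothed by a centred sliding median of
#' `window_frames` (default 10 frames, about 3 h at 20-min sampling); the RER
#' at each interior time is then the log-slope between consecutive smoothed
#' points. Edge frames with an incomplete window are excluded. Missing values
#' in gaps of at most `max_gap` frames are linearly interpolated before
#' smoothing; longer gaps split the series and each segment is processed
#' separately.
#'
#' @param series PRA series tibble (see [pra_series()]).
#' @param window_frames Sliding-median window length in frames.
#' @param max_gap Longest missing run (frames) bridged by interpolation.
#' @return Tibble with `plant_id`, `time_days` (interval midpoints),
#'   `rer_per_day`, `window_frames`; class `rer_series`, kind `"diel"`.
#' @export
diel_rer <- function(series, window_frames = 10, max_gap = 2) {
  stopifnot(window_frames >= 1)
  rows <- list()
  for (pid in unique(series$plant_id)) {
    s <- series[series$plant_id == pid, ]
    s <- s[order(s$time_days), ]
    if (nrow(s) < window_frames + 1) stop("series shorter than the smoothing window")
    v <- ifelse(s$missing | s$pra <= 0, NA_real_, s$pra)
    seg <- split_on_long_gaps(v, max_gap)
    for (idx in seg) {
      vv <- v[idx]
      if (anyNA(vv)) vv <- stats::approx(seq_along(vv)[!is.na(vv)], vv[!is.na(vv)],
                                         xout = seq_along(vv), rule = 1)$y
      if (sum(!is.na(vv)) < window_frames + 1) next
      sm <- sliding_median(vv, window_frames)
      tt <- s$time_days[idx]
      ok <- which(!is.na(sm))
      if (length(ok) < 2) next
      i1 <- ok[-length(ok)]; i2 <- ok[-1]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant_id = pid,
        time_days = (tt[i1] + tt[i2]) / 2,
        rer_per_day = (log(sm[i2]) - log(sm[i1])) / (tt[i2] - tt[i1])
      )
    }
  }
  if (!length(rows)) stop("no segment long enough for the smoothing window")
  out <- dplyr::bind_rows(rows)
  out$window_frames <- as.integer(window_frames)
  structure(out, class = c("rer_series", class(out)), kind = "diel")
}

# indices of maximal runs separated by NA runs longer than max_gap
split_on_long_gaps <- function(v, max_gap) {
  isna <- is.na(v)
  if (!any(isna)) return(list(seq_along(v)))
  r <- rle(isna)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cut_after <- integer(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] > max_gap) cut_after <- c(cut_after, starts[k] - 1L, ends[k])
  }
  bounds <- sort(unique(c(0L, cut_after, length(v))))
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    idx <- idx[!isna[idx] | cumsum(!isna[idx]) > 0]  # trim leading NAs
    idx <- idx[rev(cumsum(rev(!isna[idx]))) > 0]     # trim trailing NAs
    if (length(idx)) segs[[length(segs) + 1L]] <- idx
  }
  segs
}

#' Detect a dawn PRA dip after lights-on
#'
#' Leaf movement (epinasty) shows up in top view as a transient PRA drop just
#' after lights-on. Per light period, the (partially) median-smoothed PRA is
#' examined over the `window_hours` after the period's first frame: a dip is
#' flagged when the minimum falls strictly inside the window, at least
#' `min_depth` below the period-start value, with the series recovering above
#' the minimum by the window's end.
#'
#' @param series PRA series tibble for one or more plants.
#' @param session `diel_session` or period tibble.
#' @param window_hours Search window after lights-on, hours.
#' @param min_depth Minimum relative depth of the dip (fraction of the
#'   period-start PRA). The default 0.04 sits between the smoothed noise
#'   floor of a PRA series with a few percent observation noise and the
#'   canonical ~10% amplitude of wild-type epinastic dips.
#' @param smooth_frames Median window used before detection. The default (5)
#'   is deliberately shorter than the 10-frame RER window: a dawn dip lasting
#'   a couple of hours survives a 5-frame median at nearly full depth but is
#'   strongly attenuated by longer windows.
#' @return Tibble with `plant_id`, `period_index`, `dip` (logical), `depth`
#'   (relative), `t_min` (days).
#' @export
detect_dawn_dip <- function(series, session, window_hours = 2, min_depth = 0.04,
                            smooth_frames = 5) {
  periods <- if (inherits(session, "diel_session")) session$periods else session
  light <- periods[periods$kind == "light", , drop = FALSE]
  rows <- list()
  for (pid in unique(series$plant_id)) {
    s <- series[series$plant_id == pid, ]
    s <- s[order(s$time_days), ]
    sm <- sliding_median(ifelse(s$missing, NA, s$pra), smooth_frames, partial = TRUE)
    for (k in seq_len(nrow(light))) {
      in_per <- s$frame_index >= light$first_frame[k] & s$frame_index <= light$last_frame[k]
      idx <- which(in_per)
      if (length(idx) < 3) next
      t0 <- s$time_days[idx[1]]
      win <- idx[s$time_days[idx] <= t0 + window_hours / 24]
      if (length(win) < 3) next
      # baseline: end of the preceding dark period when available (the dip is
      # a drop relative to pre-dawn PRA); else the period's first frame
      v0 <- if (idx[1] > 1 && !is.na(sm[idx[1] - 1L])) sm[idx[1] - 1L] else sm[win[1]]
      imin <- win[which.min(sm[win])]
      depth <- (v0 - sm[imin]) / v0
      recovered <- sm[win[length(win)]] > sm[imin]
      dip <- imin != win[1] && imin != win[length(win)] &&
        depth >= min_depth && recovered
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant_id = pid, period_index = light$period_index[k],
        dip = dip, depth = depth, t_min = s$time_days[imin]
      )
    }
  }
  dplyr::bind_rows(rows)
}
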