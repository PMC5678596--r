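#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a diel trait set
#'
#' Returns the long per-plant per-frame trait table (one row per plant per
#' frame: `plant_id`, `timestamp`, `frame_index`, `period_index`,
#' `period_kind`, `time_days`, `pra_px`, `pra_mm2`, `missing`).
#'
#' @param x A `diel_traits` object from [process_session()]/[run_pipeline()].
#' @param ... Unused.
#' @method tidy diel_traits
#' @export
tidy.diel_traits <- function(x, ...) {
  tibble::as_tibble(x$traits)
}

#' One-row summary of a diel trait set
#'
#' @param x A `diel_traits` object.
#' @param ... Unused.
#' @return Tibble with plant/frame/period counts, the fraction of missing
#'   records, final mean PRA (mm^2) and mean daily RER (day^-1).
#' @method glance diel_traits
#' @export
glance.diel_traits <- function(x, ...) {
  tr <- x$traits
  last <- tr[tr$frame_index == max(tr$frame_index), ]
  tibble::tibble(
    n_plants = x$n_plants,
    n_frames = length(x$masks),
    n_periods = nrow(x$periods),
    frac_missing = mean(tr$missing),
    final_mean_pra_mm2 = mean(last$pra_mm2[!last$missing]),
    mean_daily_rer = if (!is.null(x$daily)) mean(x$daily$rer_per_day) else NA_real_,
    n_warnings = length(x$warnings)
  )
}

#' @method tidy rer_series
#' @export
tidy.rer_series <- function(x, ...) tibble::as_tibble(x)

#' Plot PRA trajectories of a diel trait set
#'
#' PRA (mm^2) against time for every plant, with dark periods shaded — the
#' standard diel growth-curve display.
#'
#' @param object A `diel_traits` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diel_traits
#' @export
autoplot.diel_traits <- function(object, ...) {
  tr <- object$traits[!object$traits$missing, ]
  dark <- object$periods[object$periods$kind == "dark", ]
  t_days <- vapply(split(object$traits$time_days, object$traits$frame_index),
                   function(v) v[1], double(1))
  shade <- tibble::tibble(
    xmin = t_days[dark$first_frame],
    xmax = t_days[dark$last_frame]
  )
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_days, y = .data$pra_mm2,
                                        colour = factor(.data$plant_id)))
  if (nrow(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = expression(PRA ~ (mm^2)),
                  colour = "Plant") +
    ggplot2::theme_minimal()
}

#' Plot an RER series
#'
#' @param object An `rer_series` (daily or diel).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rer_series
#' @export
autoplot.rer_series <- function(object, ...) {
  kind <- attr(object, "kind") %||% "diel"
  if (kind == "daily") {
    ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$period_index),
                                         y = .data$rer_per_day,
                                         fill = factor(.data$plant_id))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "Light period", y = expression(RER ~ (day^-1)),
                    fill = "Plant") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days, y = .data$rer_per_day,
                                         colour = factor(.data$plant_id))) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::labs(x = "Time (days)", y = expression(RER ~ (day^-1)),
                    colour = "Plant") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
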