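#' Chan-Vese parameters
#'
#' Weights of the two-region Chan-Vese energy
#' `E = mu*|boundary| + lambda_in*sum_in (I - c_in)^2 + lambda_out*sum_out (I - c_out)^2`
#' with intensities normalised to `[0, 1]`. The `direction` biases the
#' evolution through asymmetric lambda weights: `expand` multiplies
#' `lambda_out` by `bias` (growth permitted, strong shrink discouraged),
#' `contract` multiplies `lambda_in`, `free` keeps them equal.
#'
#' @param mu Contour-length penalty weight (on unit-normalised intensities).
#' @param lambda_in,lambda_out Region data-term weights, both positive.
#' @param max_iters Iteration cap.
#' @param tol Convergence threshold on the fraction of pixels changing label
#'   per iteration.
#' @param direction `"free"`, `"expand"` or `"contract"`.
#' @param bias Asymmetry factor applied by `expand`/`contract`.
#' @return A `chan_vese_params` object.
#' @export
chan_vese_params <- function(mu = 0.2, lambda_in = 1, lambda_out = 1,
                             max_iters = 200, tol = 1e-4,
                             direction = c("free", "expand", "contract"),
                             bias = 2) {
  direction <- match.arg(direction)
  stopifnot(mu >= 0, lambda_in > 0, lambda_out > 0, max_iters >= 1,
            tol >= 0, bias >= 1)
  structure(list(mu = mu, lambda_in = lambda_in, lambda_out = lambda_out,
                 max_iters = max_iters, tol = tol, direction = direction,
                 bias = bias),
            class = "chan_vese_params")
}

effective_lambdas <- function(params) {
  li <- params$lambda_in; lo <- params$lambda_out
  switch(params$direction,
         expand = c(li, lo * params$bias),
         contract = c(li * params$bias, lo),
         free = c(li, lo))
}

chan_vese_energy <- function(I, mask, mu, li, lo) {
  inside <- I[mask]
  outside <- I[!mask]
  c_in <- if (length(inside)) mean(inside) else mean(I)
  c_out <- if (length(outside)) mean(outside) else mean(I)
  e <- mu * mask_perimeter(mask) +
    li * sum((inside - c_in)^2) + lo * sum((outside - c_out)^2)
  list(energy = e, c_in = c_in, c_out = c_out)
}

#' Two-region Chan-Vese segmentation
#'
#' Minimises the Chan-Vese energy by narrow-band pixel flips: per iteration
#' the region means are recomputed, then boundary-adjacent pixels are flipped
#' wherever the flip lowers the energy, one checkerboard parity at a time.
#' Same-parity pixels are never 4-adjacent, so simultaneous flips at fixed
#' means are independent and the energy is non-increasing across iterations
#' by construction. The contour moves at most one pixel per half-sweep, which
#' suits frame-to-frame propagation where inter-frame change is small.
#'
#' @param gray Single-channel raster (`[0, 255]` or already on `[0, 1]`).
#' @param init_mask Non-empty logical initialisation mask, same dimensions.
#' @param params A [chan_vese_params()] object.
#' @return List with `mask` (logical) and `state`, a `contour_state` carrying
#'   `c_in`, `c_out`, the final `energy`, the per-iteration `energy_trace`,
#'   and the iteration count.
#' @export
chan_vese <- function(gray, init_mask, params = chan_vese_params()) {
  stopifnot(is_gray_raster(gray), is.logical(init_mask),
            identical(dim(gray), dim(init_mask)))
  if (!any(init_mask)) stop("empty initialization")
  I <- if (max(gray) > 1) gray / 255 else gray * 1.0
  if (diff(range(I)) < .Machine$double.eps^0.5) {
    warning("degenerate image: constant intensities, returning initialization")
    st <- chan_vese_energy(I, init_mask, params$mu, params$lambda_in, params$lambda_out)
    return(list(mask = init_mask,
                state = new_contour_state(st, energy_trace = st$energy, iterations = 0L)))
  }
  lam <- effective_lambdas(params)
  li <- lam[1]; lo <- lam[2]
  mu <- params$mu
  h <- nrow(I); w <- ncol(I)
  nnb <- nbr_total4(h, w)
  parity <- (row(I) + col(I)) %% 2L
  phi <- init_mask
  trace <- numeric(0)
  n_px <- length(I)
  iters <- 0L
  st <- chan_vese_energy(I, phi, mu, li, lo)
  for (it in seq_len(params$max_iters)) {
    iters <- it
    if (!any(phi)) break  # vanished: caller decides how to proceed
    c_in <- mean(I[phi])
    c_out <- if (all(phi)) mean(I) else mean(I[!phi])
    d_in <- li * (I - c_in)^2
    d_out <- lo * (I - c_out)^2
    changed <- 0L
    for (p in 0:1) {
      nin <- nbr_count4(phi)
      on_band_out <- !phi & nin > 0L
      on_band_in <- phi & nin < nnb
      par <- parity == p
      flip_oi <- on_band_out & par & (d_in - d_out + mu * (nnb - 2 * nin) < 0)
      flip_io <- on_band_in & par & (d_out - d_in + mu * (2 * nin - nnb) < 0)
      phi[flip_oi] <- TRUE
      phi[flip_io] <- FALSE
      changed <- changed + sum(flip_oi) + sum(flip_io)
    }
    st <- chan_vese_energy(I, phi, mu, li, lo)
    trace <- c(trace, st$energy)
    if (changed / n_px < params$tol) break
  }
  list(mask = phi, state = new_contour_state(st, energy_trace = trace, iterations = iters))
}

new_contour_state <- function(st, energy_trace, iterations) {
  structure(list(c_in = st$c_in, c_out = st$c_out, energy = st$energy,
                 energy_trace = energy_trace, iterations = iterations),
            class = "contour_state")
}

#' @export
print.contour_state <- function(x, ...) {
  cat(sprintf("Chan-Vese state: c_in = %.4f, c_out = %.4f, energy = %.4f (%d iterations)\n",
              x$c_in, x$c_out, x$energy, x$iterations))
  invisible(x)
}

# bounding box of a mask, dilated by `margin_frac` of the box size
# (at least `min_margin` px), clipped to the raster
mask_bbox <- function(mask, margin_frac = 0.25, min_margin = 6L) {
  idx <- which(mask, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  mr <- max(min_margin, ceiling(margin_frac * (r2 - r1 + 1)))
  mc <- max(min_margin, ceiling(margin_frac * (c2 - c1 + 1)))
  c(r1 = max(1L, r1 - mr), r2 = min(nrow(mask), r2 + mr),
    c1 = max(1L, c1 - mc), c2 = min(ncol(mask), c2 + mc))
}

#' Propagate labelled masks through a dark period
#'
#' Each plant's binary submask is evolved independently by [chan_vese()]
#' inside its dilated bounding box, the converged mask becoming that plant's
#' initialisation for the next frame. The forward pass is seeded from the
#' last light-period mask and biases the contour to expand (plants grow
#' through the night); the reverse pass is seeded from the first mask of the
#' following light period, processes frames anti-chronologically, and biases
#' the contour to contract. A plant whose mask vanishes is recorded as an
#' empty mask with a warning and the last non-empty mask re-seeds the next
#' frame.
#'
#' @param frames List of NIR `diel_frame`s (or gray matrices), ordered in the
#'   processing direction.
#' @param seed_mask Integer label matrix seeding the first frame.
#' @param direction `"forward"` or `"reverse"` (selects the expansion or
#'   contraction bias).
#' @param params [chan_vese_params()]; its `direction` field is overridden by
#'   the pass direction.
#' @param illumination `NULL` to skip, or [illumination_params()] applied to
#'   each frame before evolution (when its `enabled` flag is set).
#' @param margin_frac Bounding-box dilation fraction.
#' @return List of integer label matrices, one per frame, in the input frame
#'   order.
#' @export
propagate_dark_period <- function(frames, seed_mask,
                                  direction = c("forward", "reverse"),
                                  params = chan_vese_params(),
                                  illumination = illumination_params(),
                                  margin_frac = 0.25) {
  direction <- match.arg(direction)
  params$direction <- if (direction == "forward") "expand" else "contract"
  plant_ids <- setdiff(sort(unique(as.vector(seed_mask))), 0L)
  current <- lapply(plant_ids, function(k) seed_mask == k)
  names(current) <- plant_ids
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    px <- if (inherits(frames[[i]], "diel_frame")) frames[[i]]$pixels else frames[[i]]
    if (!is_gray_raster(px)) stop("dark-period propagation requires single-channel frames")
    if (!is.null(illumination) && isTRUE(illumination$enabled))
      px <- correct_illumination(px, illumination)
    lab <- matrix(0L, nrow(px), ncol(px))
    for (k in seq_along(plant_ids)) {
      init <- current[[k]]
      if (!any(init)) { next }  # carried-empty guard (should not occur)
      bb <- mask_bbox(init, margin_frac)
      sub <- chan_vese(px[bb["r1"]:bb["r2"], bb["c1"]:bb["c2"]],
                       init[bb["r1"]:bb["r2"], bb["c1"]:bb["c2"]],
                       params)
      m <- matrix(FALSE, nrow(px), ncol(px))
      m[bb["r1"]:bb["r2"], bb["c1"]:bb["c2"]] <- sub$mask
      if (!any(m)) {
        warning(sprintf("plant %s vanished at propagated frame %d; carrying last mask",
                        plant_ids[k], i))
      } else {
        lab[m & lab == 0L] <- plant_ids[k]
        current[[k]] <- m
      }
    }
    out[[i]] <- lab
  }
  out
}

#' Average forward and reverse dark-period PRA series
#'
#' Per plant and frame, the arithmetic mean of the two PRA values; where one
#' pass recorded a missing (vanished) mask, the other pass's value is used
#' alone. Both inputs must cover the same plants and frames.
#'
#' @param forward_areas,reverse_areas Tibbles with columns `plant_id`,
#'   `frame_index`, `pra_px` and `missing`.
#' @return Tibble with the same keys and the averaged `pra_px` + combined
#'   `missing` flag.
#' @export
average_passes <- function(forward_areas, reverse_areas) {
  req <- c("plant_id", "frame_index", "pra_px", "missing")
  stopifnot(all(req %in% names(forward_areas)), all(req %in% names(reverse_areas)))
  f <- dplyr::select(forward_areas, dplyr::all_of(req))
  r <- dplyr::select(reverse_areas, dplyr::all_of(req))
  j <- dplyr::full_join(f, r, by = c("plant_id", "frame_index"),
                        suffix = c("_fwd", "_rev"))
  if (anyNA(j$pra_px_fwd) || anyNA(j$pra_px_rev))
    stop("forward and reverse series cover different plant/frame sets")
  dplyr::transmute(j,
    plant_id = .data$plant_id,
    frame_index = .data$frame_index,
    pra_px = dplyr::case_when(
      .data$missing_fwd & .data$missing_rev ~ 0,
      .data$missing_fwd ~ .data$pra_px_rev,
      .data$missing_rev ~ .data$pra_px_fwd,
      TRUE ~ (.data$pra_px_fwd + .data$pra_px_rev) / 2
    ),
    missing = .data$missing_fwd & .data$missing_rev
  )
}
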