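# Internal raster helpers. Convention throughout the package: a grayscale
# raster is a numeric/integer matrix with rows = y (origin top-left, 0-based
# coordinates at the user surface), an RGB raster is an h x w x 3 array;
# intensities live on [0, 255].

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_gray_raster <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_raster <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

raster_dim <- function(x) {
  d <- dim(x)
  c(h = d[1], w = d[2])
}

# count of inside (TRUE) 4-neighbours per pixel, zero outside the raster
nbr_count4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- matrix(0, h, w)
  up <- z; up[-h, ] <- m[-1, ]
  dn <- z; dn[-1, ] <- m[-h, ]
  lf <- z; lf[, -w] <- m[, -1]
  rt <- z; rt[, -1] <- m[, -w]
  up + dn + lf + rt
}

# number of in-raster 4-neighbours per pixel (2 at corners, 3 at edges, 4 inside)
nbr_total4 <- function(h, w) {
  ones <- matrix(1, h, w)
  nbr_count4(ones)
}

# perimeter = number of 4-adjacent pixel pairs with differing labels
mask_perimeter <- function(mask) {
  m <- mask * 1L
  sum(abs(m[-1, ] - m[-nrow(m), ])) + sum(abs(m[, -1] - m[, -ncol(m)]))
}

# 8-connectivity connected components. EBImage::bwlabel is 4-connective, so
# labels touching diagonally are merged afterwards with union-find.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(t(mask * 1))  # EBImage is x,y ordered
  lab <- t(as.matrix(lab))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]
      i
    }
    h <- nrow(lab); w <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # \ diagonal
      cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))    # / diagonal
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(n), find, integer(1))
      relab <- match(root, sort(unique(root)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

# centroids of positive labels; returns tibble(label, x, y, area) with 0-based
# x = column, y = row coordinates
component_centroids <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(tibble::tibble(label = integer(), x = double(), y = double(), area = integer()))
  }
  h <- nrow(lab)
  l <- lab[idx]
  row0 <- (idx - 1L) %% h          # 0-based row
  col0 <- (idx - 1L) %/% h         # 0-based column
  area <- tabulate(l)
  keep <- which(area > 0L)
  sx <- vapply(split(col0, l), sum, double(1))
  sy <- vapply(split(row0, l), sum, double(1))
  labs <- as.integer(names(sx))
  tibble::tibble(
    label = labs,
    x = unname(sx) / area[labs],
    y = unname(sy) / area[labs],
    area = area[labs]
  )
}

fill_mask_holes <- function(mask) {
  out <- EBImage::fillHull(t(mask * 1))
  t(as.matrix(out)) > 0
}

# Gaussian low-pass with reflective boundary handling: the raster is padded by
# mirror reflection (kernel radius on each side) and convolved with a
# normalised Gaussian kernel via EBImage's FFT filter, then cropped.
gaussian_blur <- function(x, sigma) {
  stopifnot(sigma > 0)
  h <- nrow(x); w <- ncol(x)
  r <- min(as.integer(ceiling(3 * sigma)), h - 1L, w - 1L)
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  g <- g / sum(g)
  k <- outer(g, g)
  reflect_idx <- function(n, r) c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  xp <- x[reflect_idx(h, r), reflect_idx(w, r)]
  yp <- EBImage::filter2(t(xp), t(k), boundary = "circular")
  y <- t(as.matrix(yp))
  y[r + seq_len(h), r + seq_len(w)]
}

# vectorised HSV -> RGB on [0,255]; h in degrees, s/v in [0,1]
hsv_to_rgb255 <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(i0) i == i0
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r, g, b) * 255
}

dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
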