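#' Automatic left-to-right plant labelling
#'
#' Connected components of the cleaned binary mask (8-connectivity) are
#' numbered 1..n by ascending centroid x (column), ties broken by ascending
#' centroid y. An empty mask yields a valid labelling with zero plants.
#'
#' @param mask Logical foreground mask (speckle already removed, see
#'   [clean_mask()]).
#' @return Integer label matrix (0 = background) with attribute `n_plants`.
#' @export
label_auto <- function(mask) {
  lab <- label_components8(mask)
  cents <- component_centroids(lab)
  if (nrow(cents) == 0) {
    attr(lab, "n_plants") <- 0L
    return(lab)
  }
  ord <- order(cents$x, cents$y)
  relab <- integer(max(cents$label))
  relab[cents$label[ord]] <- seq_along(ord)
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  attr(out, "n_plants") <- length(ord)
  out
}

#' Read plant seeds from a whitespace-delimited text file
#'
#' Three columns per line: `plant_id x y` (0-based pixel coordinates,
#' x = column, origin top-left). Lines starting with `#` are skipped.
#'
#' @param path Seed file path.
#' @return Tibble with `plant_id`, `x`, `y`.
#' @export
read_seeds <- function(path) {
  df <- utils::read.table(path, col.names = c("plant_id", "x", "y"),
                          comment.char = "#")
  tibble::as_tibble(df)
}

#' Seeded plant labelling
#'
#' Each connected component takes the `plant_id` of the nearest seed
#' (Euclidean centroid-to-seed distance). Components farther than `max_dist`
#' from every seed are dropped; a seed matching no component produces an
#' empty label with a warning.
#'
#' @param mask Logical foreground mask.
#' @param seeds Tibble/data frame with unique `plant_id` and 0-based `x`, `y`
#'   coordinates (see [read_seeds()]).
#' @param max_dist Maximum seed-to-centroid distance in pixels (default
#'   unlimited).
#' @return Integer label matrix with attribute `n_plants` (the number of
#'   declared seeds).
#' @export
label_seeded <- function(mask, seeds, max_dist = Inf) {
  stopifnot(nrow(seeds) > 0, all(c("plant_id", "x", "y") %in% names(seeds)))
  if (anyDuplicated(seeds$plant_id)) stop("duplicate plant_ids in seeds")
  lab <- label_components8(mask)
  cents <- component_centroids(lab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  assigned <- integer(0)
  if (nrow(cents)) {
    d <- outer(seq_len(nrow(cents)), seq_len(nrow(seeds)),
               function(i, j) sqrt((cents$x[i] - seeds$x[j])^2 +
                                   (cents$y[i] - seeds$y[j])^2))
    nearest <- apply(d, 1, which.min)
    mind <- d[cbind(seq_len(nrow(cents)), nearest)]
    for (i in seq_len(nrow(cents))) {
      if (mind[i] <= max_dist) {
        id <- seeds$plant_id[nearest[i]]
        out[lab == cents$label[i]] <- id
        assigned <- union(assigned, id)
      }
    }
  }
  unmatched <- setdiff(seeds$plant_id, assigned)
  if (length(unmatched))
    warning("seeds matched no component: plant ", paste(unmatched, collapse = ", "))
  attr(out, "n_plants") <- nrow(seeds)
  out
}

#' Measure per-plant projected rosette area
#'
#' One record per declared plant: `pra_px` is the count of pixels carrying
#' that label and `pra_mm2 = pra_px * mm_per_pixel^2` exactly. A declared
#' plant with no pixels is flagged `missing` with zero area.
#'
#' @param labeled Integer label matrix.
#' @param frame A `diel_frame` supplying timestamp/index metadata (optional).
#' @param calib A [calibration_spec()].
#' @param plant_ids Plants to report; defaults to the labels present.
#' @return Tibble of trait records.
#' @export
measure_pra <- function(labeled, frame = NULL, calib = calibration_spec(1),
                        plant_ids = NULL) {
  present <- setdiff(sort(unique(as.vector(labeled))), 0L)
  if (is.null(plant_ids)) plant_ids <- present
  counts <- tabulate(labeled[labeled > 0L], nbins = max(c(plant_ids, 1L)))
  px <- ifelse(plant_ids %in% present, counts[plant_ids], 0L)
  tibble::tibble(
    plant_id = as.integer(plant_ids),
    timestamp = if (!is.null(frame)) frame$timestamp else as.POSIXct(NA),
    frame_index = if (!is.null(frame)) frame$frame_index else NA_integer_,
    pra_px = as.numeric(px),
    pra_mm2 = as.numeric(px) * calib$mm_per_pixel^2,
    missing = px == 0
  )
}

# Match the components of a labelled/binary mask to reference plant centroids:
# every component is merged into the label of the nearest reference centroid
# (fragments of a split plant keep one id). Components beyond max_dist are
# dropped. Returns the relabelled mask; reference centroids should then be
# refreshed from it.
match_to_centroids <- function(mask, ref, max_dist = Inf) {
  lab <- label_components8(mask)
  cents <- component_centroids(lab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!nrow(cents) || !nrow(ref)) return(out)
  for (i in seq_len(nrow(cents))) {
    d <- sqrt((cents$x[i] - ref$x)^2 + (cents$y[i] - ref$y)^2)
    j <- which.min(d)
    if (d[j] <= max_dist) out[lab == cents$label[i]] <- ref$plant_id[j]
  }
  out
}

# per-plant centroids of a labelled mask: tibble(plant_id, x, y, area)
label_centroids <- function(labeled) {
  cents <- component_centroids(labeled)  # here labels are plant ids
  names(cents)[names(cents) == "label"] <- "plant_id"
  cents
}
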