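# Post-processing: reduce a raw segmentation map to individual dot
# coordinates by binarization and the watershed transform, with an area
# rule on the resulting clusters.

#' Dot-calling configuration
#'
#' @param grey_threshold 8-bit cutoff binarizing the map (pixels survive if
#'   strictly above it).
#' @param area_threshold minimum pixel count a cluster needs to be reported
#'   (inclusive; 0 keeps all clusters).
#' @param pre_blur optional circular Gaussian kernel size applied before
#'   binarization (`NULL` for none).
#' @export
dotcall_config <- function(grey_threshold = 254, area_threshold = 0,
                           pre_blur = NULL) {
  stopifnot(grey_threshold >= 0, grey_threshold <= 255, area_threshold >= 0)
  structure(list(grey_threshold = grey_threshold,
                 area_threshold = area_threshold, pre_blur = pre_blur),
            class = "dotcall_config")
}

#' Binarize a segmentation map
#'
#' Maps with values in `[0,1]` are scaled by 255 first; a pixel is positive
#' iff its scaled value is strictly greater than the grey threshold.
#'
#' @param map single-channel matrix (8-bit 0-255 or probabilities in
#'   `[0,1]`).
#' @param grey_threshold 8-bit cutoff.
#' @return logical HxW matrix.
#' @export
binarize <- function(map, grey_threshold) {
  if (length(dim(map)) > 2) stop("binarize expects a single-channel map")
  stopifnot(grey_threshold >= 0, grey_threshold <= 255)
  v <- map
  if (max(v) <= 1) v <- v * 255
  v > grey_threshold
}

# Watershed labelling of a binary mask: split touching clusters via the
# distance transform. Returns an HxW integer label matrix.
watershed_labels <- function(mask) {
  img <- EBImage::Image(t(mask) * 1)
  dm <- EBImage::distmap(img)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  t(EBImage::imageData(ws))
}

#' Call dots from a binary mask
#'
#' Applies the watershed transform over the distance map of the mask so
#' touching clusters are split, keeps clusters whose pixel count meets the
#' area threshold, and reports one coordinate per cluster (rounded
#' centroid).
#'
#' @param mask logical/binary HxW matrix.
#' @param area_threshold minimum cluster pixel count (inclusive; 0 keeps
#'   all).
#' @return object of class `detection`: `coords` (data frame `x`, `y`,
#'   0-based integers) and `cluster_areas`.
#' @export
call_dots <- function(mask, area_threshold = 0) {
  lab <- watershed_labels(mask)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(structure(list(coords = data.frame(x = integer(0), y = integer(0)),
                          cluster_areas = integer(0)),
                     class = "detection"))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  areas <- as.integer(table(factor(labv, levels = ids)))
  cx <- tapply(idx[, 2] - 1, labv, mean)
  cy <- tapply(idx[, 1] - 1, labv, mean)
  keep <- areas >= area_threshold
  structure(list(coords = data.frame(x = as.integer(floor(cx[keep] + 0.5)),
                                     y = as.integer(floor(cy[keep] + 0.5))),
                 cluster_areas = areas[keep]),
            class = "detection")
}

# Circular Gaussian blur of a single-channel map (zero boundary).
blur_map <- function(map, kernel_size) {
  k <- circular_gaussian_kernel(kernel_size)
  img <- EBImage::Image(t(map))
  t(EBImage::imageData(EBImage::filter2(img, k, boundary = 0)))
}

#' Dot calling, data-generation variant
#'
#' The stricter fixed pipeline used when harvesting natural dots for
#' synthetic training data: a 5x5 circular Gaussian blur, a binary
#' threshold at 148, then watershed dot calling with area threshold 0.
#'
#' @param map 8-bit single-channel matrix.
#' @return a `detection`, with the thresholds used attached as
#'   `attr(, "config")`.
#' @export
call_dots_generation_variant <- function(map) {
  blurred <- blur_map(map, 5)
  det <- call_dots(binarize(blurred, 148), area_threshold = 0)
  attr(det, "config") <- c(grey_threshold = 148, area_threshold = 0)
  det
}

#' F1 surface over grey and area thresholds
#'
#' For every (grey, area) pair, binarizes each map, calls dots, scores
#' against ground truth at the given pixel tolerance (micro-aggregated over
#' patches), and returns the dense F1 grid with its argmax (ties broken
#' toward smaller area, then smaller grey).
#'
#' @param maps list of single-channel maps.
#' @param gts list of ground-truth coordinate data frames (`x`, `y`).
#' @param grey_range,area_range integer vectors of thresholds to sweep.
#' @param tolerance matching tolerance in pixels.
#' @return list with `f1` (|grey| x |area| matrix, dimnames set),
#'   `grey_range`, `area_range`, and `best` (`grey`, `area`, `f1`).
#' @export
threshold_surface <- function(maps, gts, grey_range, area_range,
                              tolerance = 5) {
  if (length(grey_range) == 0 || length(area_range) == 0) {
    stop("empty threshold range")
  }
  if (length(maps) != length(gts)) stop("maps and gts must pair up")
  f1 <- matrix(0, length(grey_range), length(area_range),
               dimnames = list(grey_range, area_range))
  for (gi in seq_along(grey_range)) {
    dets <- lapply(maps, function(m) call_dots(binarize(m, grey_range[gi]), 0))
    for (ai in seq_along(area_range)) {
      reports <- lapply(seq_along(dets), function(i) {
        d <- dets[[i]]
        keep <- d$cluster_areas >= area_range[ai]
        match_dots(d$coords[keep, , drop = FALSE], gts[[i]],
                   tolerance = tolerance)
      })
      f1[gi, ai] <- aggregate_reports(reports)$f1
    }
  }
  best_val <- max(f1)
  cand <- which(f1 == best_val, arr.ind = TRUE)
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  list(f1 = f1, grey_range = grey_range, area_range = area_range,
       best = list(grey = grey_range[cand[1, 1]],
                   area = area_range[cand[1, 2]],
                   f1 = best_val))
}
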