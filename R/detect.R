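# Hot-spot detection: locally adaptive thresholding inside the segmented
# skeleton, 8-connected component extraction, and per-hot-spot features.

#' Detection tuning parameters
#'
#' @param k threshold proportionality factor (> 1): a pixel is supra-threshold
#'   when its (smoothed) counts exceed `k` times the robust local background.
#' @param neighborhood_radius radius (pixels) of the disc over which the local
#'   background is estimated.
#' @param min_area minimum hot-spot area in pixels.
#' @param smooth_sigma Gaussian presmoothing (pixels) applied to the count
#'   image before thresholding; tempers Poisson noise while preserving the
#'   linear scaling that makes detection invariant to global intensity.
#' @param grid_stride stride of the coarse grid on which the local background
#'   median is evaluated (it is nearest-interpolated in between).
#' @return list of class `detect_control`.
#' @export
detect_control <- function(k = 1.5, neighborhood_radius = 40, min_area = 4L,
                           smooth_sigma = 1.5, grid_stride = 8L) {
  stopifnot(k > 1, neighborhood_radius > 0, min_area >= 1)
  structure(list(k = k, neighborhood_radius = neighborhood_radius,
                 min_area = as.integer(min_area), smooth_sigma = smooth_sigma,
                 grid_stride = as.integer(grid_stride)),
            class = "detect_control")
}

#' Locally adaptive threshold map
#'
#' Computes, for every skeletal pixel, `k` times a robust local background:
#' the median of (smoothed) skeletal-pixel counts of the same anatomical
#' region within a disc of `neighborhood_radius` pixels. Estimating the
#' background per region keeps the detector equally sensitive in low-uptake
#' regions (ribs) and high-uptake regions (lumbar spine); the median resists
#' contamination by the lesion itself. Medians are evaluated on a coarse grid
#' and nearest-interpolated for speed. Grid points whose neighborhood holds
#' fewer than 10 skeletal pixels fall back to the whole-region median and are
#' flagged.
#'
#' @param image count matrix (one view), aligned with `segmentation`.
#' @param segmentation a `segmentation_result`.
#' @param view `"anterior"` or `"posterior"`.
#' @param control a [detect_control()].
#' @return list: `threshold` (matrix, `NA` off-skeleton), `background`
#'   (matrix of local background estimates), `smoothed` (presmoothed image),
#'   `flags` (character).
#' @export
threshold_map <- function(image, segmentation, view = c("anterior", "posterior"),
                          control = detect_control()) {
  view <- match.arg(view)
  stopifnot(inherits(segmentation, "segmentation_result"))
  labels <- segmentation$labels[[view]]
  stopifnot(identical(dim(image), dim(labels)))
  nr <- nrow(image)
  sm <- gauss_smooth(image, control$smooth_sigma)
  thr <- matrix(NA_real_, nr, ncol(image))
  bg <- matrix(NA_real_, nr, ncol(image))
  flags <- character(0)
  R <- control$neighborhood_radius
  stride <- max(1L, control$grid_stride)
  for (id in sort(unique(labels[labels > 0]))) {
    px <- which(labels == id)
    vals <- sm[px]
    pr <- ((px - 1L) %% nr) + 1L
    pc <- ((px - 1L) %/% nr) + 1L
    region_med <- stats::median(vals)
    gsel <- which(pr %% stride == 0L & pc %% stride == 0L)
    if (length(gsel) == 0L) gsel <- 1L
    # squared distances pixel x grid-point, reused for medians and assignment
    D2 <- outer(pr, pr[gsel], "-")^2 + outer(pc, pc[gsel], "-")^2
    gmed <- vapply(seq_along(gsel), function(j) {
      v <- vals[D2[, j] <= R^2]
      if (length(v) < 10L) return(NA_real_)
      # deterministic 2-fold subsample: halves the sort cost, leaves the
      # median estimate (and its linear scaling) intact
      if (length(v) > 200L) v <- v[seq(1L, length(v), 2L)]
      stats::median(v)
    }, numeric(1))
    if (anyNA(gmed)) {
      flags <- c(flags, paste0("empty_neighborhood_", view, "_region", id))
      gmed[is.na(gmed)] <- region_med
    }
    gi <- max.col(-D2, ties.method = "first")
    bg[px] <- gmed[gi]
    thr[px] <- control$k * gmed[gi]
  }
  list(threshold = thr, background = bg, smoothed = sm, flags = flags)
}

#' Detect hot spots in one view
#'
#' Thresholds the (smoothed) image against a locally adaptive threshold map,
#' extracts 8-connected components of supra-threshold skeletal pixels, drops
#' components smaller than `min_area` or containing no local maximum of the
#' smoothed image (which rejects monotone spill ramps at boundaries between
#' bones of different brightness), and assigns each component to the
#' anatomical region holding the majority of its pixels (ties broken toward
#' the region with the larger skeletal mass fraction).
#'
#' @inheritParams threshold_map
#' @param atlas a `skeletal_atlas` (for the tie-breaking mass fractions).
#' @param thresholds optional precomputed result of [threshold_map()].
#' @return tibble with one row per hot spot: `view`, `region`, `area_px`,
#'   centroid (`row`, `col`) and the pixel `mask` (list-column of image
#'   indices). Empty tibble when nothing exceeds threshold.
#' @export
detect_hotspots <- function(image, segmentation, view = c("anterior", "posterior"),
                            atlas, control = detect_control(), thresholds = NULL) {
  view <- match.arg(view)
  if (is.null(thresholds)) thresholds <- threshold_map(image, segmentation, view, control)
  labels <- segmentation$labels[[view]]
  nr <- nrow(image)
  sm <- thresholds$smoothed
  supra <- !is.na(thresholds$threshold) & sm > thresholds$threshold
  # regional-maximum gate: intensity ramps spilling across a boundary from a
  # brighter neighbouring bone rise monotonically toward that boundary and so
  # contain no local maximum of the smoothed image; genuine focal uptake does
  nbmax <- matrix(-Inf, nrow(sm), ncol(sm))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbmax <- pmax(nbmax, shift_mat(sm, dr, dc, fill = -Inf))
  }
  peaks <- sm >= nbmax
  comp <- label_components(supra, connectivity = 8)
  n <- max(comp)
  empty <- tibble::tibble(view = character(), region = character(),
                          area_px = integer(), row = numeric(), col = numeric(),
                          mask = list())
  if (n == 0L) return(empty)
  mf <- atlas$mass_fraction
  ids <- segmentation$regions
  out <- purrr::map(seq_len(n), function(i) {
    px <- which(comp == i)
    if (length(px) < control$min_area) return(NULL)
    if (!any(peaks[px])) return(NULL)
    # the smoothed image decides detection; the lesion extent is re-measured
    # on the raw image at the same threshold, undoing the area inflation the
    # presmoothing would otherwise cause (exact on noise-free input)
    raw <- px[image[px] > thresholds$threshold[px]]
    if (length(raw) >= control$min_area) {
      refined <- largest_connected_subset(raw, nr)
      if (length(refined) >= control$min_area) px <- refined
    }
    reg_ids <- labels[px]
    tab <- table(reg_ids)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) > 1L) {
      masses <- mf[ids$region[match(top, ids$id)]]
      top <- top[which.max(masses)]
    }
    tibble::tibble(view = view,
                   region = ids$region[match(top, ids$id)],
                   area_px = length(px),
                   row = mean(((px - 1L) %% nr) + 1L),
                   col = mean(((px - 1L) %/% nr) + 1L),
                   mask = list(px))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) empty else out
}

# convex hull area of a pixel set (shoelace on hull of pixel centres);
# degenerate (collinear) sets get their pixel count so solidity is 1
hull_area <- function(r, c) {
  if (length(r) < 3L) return(length(r))
  h <- grDevices::chull(c, r)
  x <- c[h]
  y <- r[h]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  max(a, length(r) * 1e-9)
}

#' Extract the feature vector of a hot spot
#'
#' Size, shape, intensity and localization descriptors used by the per-region
#' classifiers. Intensity features are ratios against the local regional
#' background, and shape/localization features depend only on the mask, so
#' the whole vector is invariant to global rescaling of the image.
#'
#' @param hotspots tibble from [detect_hotspots()] (any subset of rows).
#' @param image the count matrix of the same view.
#' @param segmentation a `segmentation_result`.
#' @param atlas a `skeletal_atlas`.
#' @param thresholds optional precomputed [threshold_map()] result (recomputed
#'   if missing).
#' @param control a [detect_control()].
#' @return the input tibble with feature columns added: `area_px`,
#'   `region_fraction`, `eccentricity`, `solidity`, `boundary_irregularity`,
#'   `intensity_max_rel`, `intensity_mean_rel`, `contrast`, `centroid_x_norm`,
#'   `centroid_y_norm`, plus one indicator column `loc_<region>` per atlas
#'   region.
#' @export
extract_features <- function(hotspots, image, segmentation, atlas,
                             thresholds = NULL, control = detect_control()) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  if (nrow(hotspots) == 0L) return(hotspots)
  view <- hotspots$view[1]
  if (is.null(thresholds)) thresholds <- threshold_map(image, segmentation, view, control)
  sm <- thresholds$smoothed
  bg <- thresholds$background
  labels <- segmentation$labels[[view]]
  nr <- nrow(image)
  ids <- segmentation$regions

  feats <- purrr::map_dfr(seq_len(nrow(hotspots)), function(i) {
    px <- hotspots$mask[[i]]
    region <- hotspots$region[i]
    rid <- ids$id[ids$region == region]
    reg_px <- which(labels == rid)
    pr <- ((px - 1L) %% nr) + 1L
    pc <- ((px - 1L) %/% nr) + 1L
    # shape from the pixel-coordinate covariance (degenerate: single pixel)
    if (length(px) > 1L) {
      ev <- eigen(stats::cov(cbind(pr, pc)), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      ecc <- if (ev[1] <= 0) 0 else sqrt(1 - min(ev[2] / ev[1], 1))
    } else ecc <- 0
    solidity <- min(length(px) / hull_area(pr, pc), 1)
    # perimeter = exposed 4-neighbour edges
    per <- sum(pr == 1L | is.na(match(px - 1L, px))) +
      sum(pr == nr | is.na(match(px + 1L, px))) +
      sum(pc == 1L | is.na(match(px - nr, px))) +
      sum(pc == ncol(image) | is.na(match(px + nr, px)))
    irregularity <- per^2 / (4 * pi * length(px))
    local_bg <- stats::median(bg[px])
    rbr <- range(((reg_px - 1L) %% nr) + 1L)
    rbc <- range(((reg_px - 1L) %/% nr) + 1L)
    tibble::tibble(
      region_fraction = length(px) / length(reg_px),
      eccentricity = ecc,
      solidity = solidity,
      boundary_irregularity = irregularity,
      intensity_max_rel = max(sm[px]) / local_bg,
      intensity_mean_rel = mean(sm[px]) / local_bg,
      contrast = (mean(sm[px]) - local_bg) / (mean(sm[px]) + local_bg),
      centroid_x_norm = (mean(pc) - rbc[1]) / max(diff(rbc), 1),
      centroid_y_norm = (mean(pr) - rbr[1]) / max(diff(rbr), 1)
    )
  })
  onehot <- purrr::map_dfc(stats::setNames(ids$region, paste0("loc_", ids$region)),
                           function(rn) as.numeric(hotspots$region == rn))
  dplyr::bind_cols(hotspots, feats, onehot)
}

#' Names of the classifier feature columns
#' @return character vector of feature column names in canonical order.
#' @export
feature_names <- function() {
  c("area_px", "region_fraction", "eccentricity", "solidity",
    "boundary_irregularity", "intensity_max_rel", "intensity_mean_rel",
    "contrast", "centroid_x_norm", "centroid_y_norm",
    paste0("loc_", uptake_table()$region))
}

#' Detect and featurize hot spots in both views
#'
#' Convenience wrapper running [threshold_map()], [detect_hotspots()] and
#' [extract_features()] on the anterior and posterior views of a scan.
#'
#' @param pair a `scintigram_pair`.
#' @param segmentation a `segmentation_result` aligned with `pair`.
#' @param atlas a `skeletal_atlas`.
#' @param control a [detect_control()].
#' @return tibble of featurized hot spots from both views.
#' @export
detect_scan <- function(pair, segmentation, atlas, control = detect_control()) {
  stopifnot(inherits(pair, "scintigram_pair"))
  purrr::map_dfr(c("anterior", "posterior"), function(v) {
    thr <- threshold_map(pair[[v]], segmentation, v, control)
    hs <- detect_hotspots(pair[[v]], segmentation, v, atlas, control, thresholds = thr)
    extract_features(hs, pair[[v]], segmentation, atlas, thresholds = thr,
                     control = control)
  })
}
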