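# Bone scan index: per-hot-spot skeletal involvement and its sum over hot
# spots classified as metastatic.

# each region is quantified from a primary view to avoid double counting the
# anterior/posterior projections of the same lesion; "average" regions take
# half of each view's involvement
view_policy <- function(regions) {
  stats::setNames(regions$primary_view, regions$region)
}

#' Skeletal involvement of hot spots
#'
#' The percentage of total skeletal mass one hot spot represents: its pixel
#' area as a fraction of its region's pixel area in the same view, weighted by
#' the region's skeletal mass fraction.
#'
#' @param hotspots hot-spot tibble (needs `region`, `view`, `area_px`).
#' @param segmentation a `segmentation_result` (denominator region areas).
#' @param atlas a `skeletal_atlas` (mass fractions).
#' @return `hotspots` with an `involvement_pct` column.
#' @export
skeletal_involvement <- function(hotspots, segmentation, atlas) {
  stopifnot(inherits(segmentation, "segmentation_result"),
            inherits(atlas, "skeletal_atlas"))
  if (nrow(hotspots) == 0L)
    return(dplyr::mutate(hotspots, involvement_pct = numeric(0)))
  inv <- vapply(seq_len(nrow(hotspots)), function(i) {
    region <- hotspots$region[i]
    view <- hotspots$view[i]
    area <- region_pixel_area(segmentation, region, view)
    if (area == 0L)
      stop("region '", region, "' has zero pixel area in the ", view,
           " view; involvement undefined", call. = FALSE)
    if (hotspots$area_px[i] < 1L)
      stop("hot spot with empty mask", call. = FALSE)
    100 * min(hotspots$area_px[i] / area, 1) * atlas$mass_fraction[[region]]
  }, numeric(1))
  dplyr::mutate(hotspots, involvement_pct = inv)
}

#' Compute the bone scan index for one patient
#'
#' Sums the skeletal involvement of all hot spots whose metastasis probability
#' reaches `metastasis_threshold`. Anterior/posterior duplication is resolved
#' by each region's primary-view policy: posterior for spine and scapulae,
#' anterior for skull, sternum and clavicles, and the average of the two
#' views for ribs, humeri, pelvis and femora (a lesion of an averaged region
#' seen in only one view contributes half). The patient-level abnormality
#' score is the maximum hot-spot probability ([patient_ann_value()]).
#'
#' @param hotspots tibble with `region`, `view`, `involvement_pct` and
#'   `probability` columns (as produced by the detection, involvement and
#'   classification steps).
#' @param segmentation the `segmentation_result` used (for quality flags);
#'   optional.
#' @param metastasis_threshold probability cutoff above which a hot spot
#'   counts as metastatic.
#' @return a `patient_result`: `ann_value`, `bsi` (clamped to `[0, 100]`,
#'   with a `clamped` flag if the raw sum overran), the per-hot-spot table
#'   with `metastatic` flags and view-policy weights, and `flags`.
#' @export
compute_bsi <- function(hotspots, segmentation = NULL, metastasis_threshold = 0.5) {
  flags <- character(0)
  if (!is.null(segmentation)) flags <- segmentation$flags
  if (nrow(hotspots) == 0L) {
    return(structure(list(ann_value = 0, bsi = 0,
                          hotspots = dplyr::mutate(hotspots,
                                                   metastatic = logical(0),
                                                   view_weight = numeric(0)),
                          metastasis_threshold = metastasis_threshold,
                          flags = flags),
                     class = "patient_result"))
  }
  stopifnot(all(c("region", "view", "involvement_pct", "probability") %in% names(hotspots)))
  if (anyNA(hotspots$probability) ||
      any(hotspots$probability < 0 | hotspots$probability > 1))
    stop("hot-spot probabilities must lie in [0, 1]", call. = FALSE)
  policy <- view_policy(if (!is.null(segmentation)) segmentation$regions else
    render_region_table())
  hotspots <- dedupe_cross_view(hotspots, policy)
  hs <- dplyr::mutate(
    hotspots,
    metastatic = .data$probability >= metastasis_threshold,
    view_weight = dplyr::case_when(
      policy[.data$region] == "average" ~ 0.5,
      policy[.data$region] == .data$view ~ 1,
      TRUE ~ 0
    )
  )
  raw <- sum(hs$involvement_pct * hs$view_weight * hs$metastatic)
  if (raw > 100) flags <- c(flags, "bsi_clamped")
  structure(list(
    ann_value = patient_ann_value(hs$probability),
    bsi = min(max(raw, 0), 100),
    bsi_raw = raw,
    hotspots = hs,
    metastasis_threshold = metastasis_threshold,
    flags = flags
  ), class = "patient_result")
}

# Cross-view duplicate resolution. The two views are co-registered planar
# projections, so a deep midline lesion can surface in both views under
# *different* anatomical labels (e.g. sternum anteriorly, thoracic spine
# posteriorly); counting both would double its involvement. Overlapping
# hot spots from opposite views with different regions are merged into one
# instance, preferring the hot spot whose region's primary view matches its
# own view, then the larger area, then the posterior view. Same-region pairs
# are left alone (the averaging policy handles them).
dedupe_cross_view <- function(hotspots, policy) {
  if (!"mask" %in% names(hotspots) || nrow(hotspots) < 2L) return(hotspots)
  pref <- function(i) {
    pol <- policy[[hotspots$region[i]]]
    if (identical(pol, hotspots$view[i])) 2 else if (identical(pol, "average")) 1 else 0
  }
  ant <- which(hotspots$view == "anterior")
  post <- which(hotspots$view == "posterior")
  drop <- rep(FALSE, nrow(hotspots))
  for (i in ant) for (j in post) {
    if (drop[i] || drop[j]) next
    if (identical(hotspots$region[i], hotspots$region[j])) next
    if (!any(hotspots$mask[[i]] %in% hotspots$mask[[j]])) next
    ki <- c(pref(i), hotspots$area_px[i], 0)
    kj <- c(pref(j), hotspots$area_px[j], 1)   # posterior wins exact ties
    keep_i <- ki[1] > kj[1] || (ki[1] == kj[1] && (ki[2] > kj[2] ||
                                                     (ki[2] == kj[2] && ki[3] > kj[3])))
    drop[if (keep_i) j else i] <- TRUE
  }
  hotspots[!drop, , drop = FALSE]
}

# region table without rendering a full template (policy lookups only)
render_region_table <- function() {
  up <- uptake_table()
  tibble::tibble(id = seq_len(nrow(up)), region = up$region,
                 primary_view = up$primary_view)
}

#' @export
print.patient_result <- function(x, ...) {
  cat("patient_result: ANN value ", round(x$ann_value, 3), ", BSI ",
      round(x$bsi, 2), "% (", sum(x$hotspots$metastatic), " of ",
      nrow(x$hotspots), " hot spots metastatic)",
      if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
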