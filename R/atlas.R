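#' Load the sex-specific skeletal atlas
#'
#' Returns the packaged atlas for one sex: a procedurally generated reference
#' scan (noise-free expected-count template per view), per-view anatomical
#' label templates, and the per-region skeletal mass fractions that form the
#' denominator of skeletal involvement. Deterministic: the atlas is rendered
#' from the versioned geometry and uptake tables shipped with the package.
#'
#' @param sex `"male"` or `"female"`.
#' @return a `skeletal_atlas`: `reference` (list of anterior/posterior
#'   expected-count matrices), `labels` (list of per-view integer label
#'   matrices), `regions` (region table with ids and primary views),
#'   `mass_fraction` (named numeric summing to 1) and `sex`.
#' @examples
#' atl <- load_atlas("male")
#' sum(atl$mass_fraction)  # 1
#' @export
load_atlas <- function(sex) {
  if (!is.character(sex) || length(sex) != 1 || !sex %in% c("male", "female"))
    stop("unknown sex: must be \"male\" or \"female\"", call. = FALSE)
  tpl <- render_template(sex, 1)
  mf <- mass_fractions()
  mass <- stats::setNames(mf$mass_fraction, mf$region)
  stopifnot(abs(sum(mass) - 1) < 1e-9, all(mass > 0))
  structure(list(
    sex = sex,
    # reference carries the same system-resolution blur as acquired scans
    reference = list(anterior = gauss_smooth(tpl$anterior, 2),
                     posterior = gauss_smooth(tpl$posterior, 2)),
    labels = list(anterior = tpl$labels_anterior, posterior = tpl$labels_posterior),
    regions = tpl$regions,
    region_masks = tpl$region_masks,
    mass_fraction = mass
  ), class = "skeletal_atlas")
}

#' @export
print.skeletal_atlas <- function(x, ...) {
  cat("skeletal_atlas (", x$sex, "): ", nrow(x$regions),
      " regions, mass fractions sum ", format(sum(x$mass_fraction)), "\n", sep = "")
  invisible(x)
}

#' Pixel area of a region in a segmentation
#'
#' @param segmentation a `segmentation_result` from [register_atlas()].
#' @param region region name (must exist in the atlas region set;
#'   `"background"` is not a region).
#' @param view `"anterior"` or `"posterior"`.
#' @return integer pixel count (possibly 0 for regions occluded in that view).
#' @export
region_pixel_area <- function(segmentation, region, view = c("anterior", "posterior")) {
  view <- match.arg(view)
  stopifnot(inherits(segmentation, "segmentation_result"))
  ids <- segmentation$regions
  if (!region %in% ids$region)
    stop("unknown region: ", region, call. = FALSE)
  id <- ids$id[ids$region == region]
  sum(segmentation$labels[[view]] == id)
}

#' Summarize per-region areas of a segmentation
#'
#' @param segmentation a `segmentation_result`.
#' @return tibble with one row per region and view: `region`, `view`,
#'   `area_px`.
#' @export
segmentation_areas <- function(segmentation) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  ids <- segmentation$regions
  purrr::map_dfr(c("anterior", "posterior"), function(v) {
    tab <- tabulate(segmentation$labels[[v]], nbins = max(ids$id))
    tibble::tibble(region = ids$region, view = v, area_px = tab[ids$id])
  })
}
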