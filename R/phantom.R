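#' @importFrom rlang .data
NULL

# cached loaders for the packaged configuration tables -------------------

pkg_table <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache)) {
      path <- system.file("extdata", paste0(name, ".csv"), package = "bsiquant")
      if (path == "") stop("packaged table not found: ", name)
      assign(name, tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)),
             envir = cache)
    }
    get(name, envir = cache)
  }
})

uptake_table <- function() pkg_table("uptake_factors")

#' Per-region skeletal mass fractions
#'
#' Approximate adult reference-skeleton bone-mass fractions for the regions
#' the atlas segments, renormalized so the rendered regions sum to 1 (bones
#' outside the rendered field such as forearms, tibiae and feet are dropped
#' and their mass redistributed proportionally).
#'
#' @return tibble with columns `region` and `mass_fraction` (sums to 1).
#' @export
mass_fractions <- function() {
  mf <- pkg_table("mass_fractions")
  mf$mass_fraction <- mf$mass_fraction / sum(mf$mass_fraction)
  mf
}

# --------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' Bundles every tunable of the synthetic whole-body scintigram generator.
#' The matrix size is fixed at 256 columns x 1024 rows per view; it is part
#' of the acquisition contract, not a parameter.
#'
#' @param sex `"male"` or `"female"`.
#' @param stature_scale multiplicative body-size factor in `[0.8, 1.2]`.
#' @param n_metastases number of focal metastatic lesions (>= 0).
#' @param n_benign number of benign degenerative lesions placed at
#'   joint/vertebral-margin candidate sites (>= 0).
#' @param lesion_amplitude_range length-2 numeric, multiplicative uptake
#'   factor range for metastatic lesions; minimum must exceed 1.
#' @param benign_amplitude_range amplitude range for benign lesions.
#' @param total_counts expected total counts per view (counting statistics).
#' @param seed integer seed controlling lesion placement and Poisson noise.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(sex = "male", stature_scale = 1,
                           n_metastases = 5L, n_benign = 3L,
                           lesion_amplitude_range = c(3, 5),
                           benign_amplitude_range = c(1.6, 2.8),
                           total_counts = 1e6, seed = 1L) {
  sex <- match.arg(sex, c("male", "female"))
  if (stature_scale < 0.8 || stature_scale > 1.2)
    stop("stature_scale must lie in [0.8, 1.2]", call. = FALSE)
  if (n_metastases < 0 || n_benign < 0)
    stop("lesion counts must be non-negative", call. = FALSE)
  # min > 1.5 so every lesion has a non-empty 50%-excess truth contour
  if (length(lesion_amplitude_range) != 2 || lesion_amplitude_range[1] <= 1.5 ||
      diff(lesion_amplitude_range) < 0)
    stop("lesion_amplitude_range must be (min, max) with min > 1.5", call. = FALSE)
  if (length(benign_amplitude_range) != 2 || benign_amplitude_range[1] <= 1.5 ||
      diff(benign_amplitude_range) < 0)
    stop("benign_amplitude_range must be (min, max) with min > 1.5", call. = FALSE)
  if (total_counts < 0) stop("total_counts must be >= 0", call. = FALSE)
  structure(list(sex = sex, stature_scale = stature_scale,
                 n_metastases = as.integer(n_metastases),
                 n_benign = as.integer(n_benign),
                 lesion_amplitude_range = as.numeric(lesion_amplitude_range),
                 benign_amplitude_range = as.numeric(benign_amplitude_range),
                 total_counts = as.numeric(total_counts),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Render the noise-free skeletal template
#'
#' Draws the procedural 2D skeleton for one sex at a given body size and
#' returns noise-free expected-count maps for the anterior and posterior
#' views together with per-view anatomical label maps. Each view's label map
#' resolves projection overlaps in favour of the structures that view images
#' best: sternum and clavicles anteriorly, spine and scapulae posteriorly.
#'
#' @param sex `"male"` or `"female"`.
#' @param stature_scale body-size factor in `[0.8, 1.2]`.
#' @return a `phantom_template`: expected-count matrices `anterior` /
#'   `posterior`, integer label matrices `labels_anterior` /
#'   `labels_posterior` (0 = background, values index `regions$id`), the
#'   per-region full pixel masks `region_masks` (named list of pixel indices,
#'   before per-view overlap resolution), the `regions` table and acquisition
#'   metadata.
#' @export
render_template <- function(sex, stature_scale = 1) {
  sex <- match.arg(sex, c("male", "female"))
  if (stature_scale < 0.8 || stature_scale > 1.2)
    stop("stature_scale must lie in [0.8, 1.2]", call. = FALSE)
  s <- stature_scale
  up <- uptake_table()
  regions <- tibble::tibble(
    id = seq_len(nrow(up)),
    region = up$region,
    uptake = if (sex == "male") up$uptake_male else up$uptake_female,
    emphasis_anterior = up$emphasis_anterior,
    emphasis_posterior = up$emphasis_posterior,
    lesion_fwhm_px = up$lesion_fwhm_px,
    primary_view = up$primary_view
  )

  shapes <- skeleton_shapes(sex)
  region_masks <- lapply(shapes, shapes_to_idx, s = s)
  body <- silhouette_idx(sex, s)

  maps <- list()
  labels <- list()
  for (view in c("anterior", "posterior")) {
    lab <- matrix(0L, IMG_NROW, IMG_NCOL)
    for (rn in paint_order(view)) {
      lab[region_masks[[rn]]] <- regions$id[regions$region == rn]
    }
    img <- matrix(0, IMG_NROW, IMG_NCOL)
    img[body] <- SOFT_TISSUE_UPTAKE
    emph <- if (view == "anterior") regions$emphasis_anterior else regions$emphasis_posterior
    for (i in regions$id) {
      px <- which(lab == i)
      img[px] <- regions$uptake[i] * emph[i]
    }
    for (blob in physiology_blobs(s)) {
      img[blob$idx] <- img[blob$idx] + blob[[view]]
    }
    maps[[view]] <- img
    labels[[view]] <- lab
  }

  structure(list(
    anterior = maps$anterior, posterior = maps$posterior,
    labels_anterior = labels$anterior, labels_posterior = labels$posterior,
    region_masks = region_masks, regions = regions,
    silhouette = body, sex = sex, stature_scale = s,
    pixel_spacing_mm = 2.2
  ), class = "phantom_template")
}

#' @export
print.phantom_template <- function(x, ...) {
  cat("phantom_template:", x$sex, "stature", x$stature_scale, "-",
      nrow(x$regions), "regions,",
      format(sum(lengths(x$region_masks))), "skeletal px\n")
  invisible(x)
}

# Draw one lesion into both views as a multiplicative Gaussian bump
# restricted to the lesion's region mask. The lesion's contrast is
# view-dependent: bone close to the anterior detector (sternum, clavicles)
# shows a stronger anterior excess, posterior bone (spine, scapulae) a
# stronger posterior excess, with the region's view-emphasis ratio as the
# depth proxy (fourth-root weighting, geometric mean 1, so the average
# contrast equals the drawn amplitude).
render_lesion <- function(template, center_idx, region, amplitude, fwhm) {
  nr <- IMG_NROW
  r0 <- ((center_idx - 1L) %% nr) + 1L
  c0 <- ((center_idx - 1L) %/% nr) + 1L
  sigma <- fwhm / 2.355
  px <- template$region_masks[[region]]
  pr <- ((px - 1L) %% nr) + 1L
  pc <- ((px - 1L) %/% nr) + 1L
  d2 <- (pr - r0)^2 + (pc - c0)^2
  near <- d2 <= (3 * sigma)^2
  target <- px[near]

  reg <- template$regions[template$regions$region == region, ]
  w_ant <- (reg$emphasis_anterior / reg$emphasis_posterior)^0.25
  w_post <- 1 / w_ant
  gauss <- exp(-d2[near] / (2 * sigma^2))
  template$anterior[target] <- template$anterior[target] *
    (1 + (amplitude - 1) * w_ant * gauss)
  template$posterior[target] <- template$posterior[target] *
    (1 + (amplitude - 1) * w_post * gauss)

  # true lesion extent per view: pixels whose uptake exceeds normal by >= 50%
  # (multiplicative excess >= 0.5 in that view)
  r2_contour <- function(w) {
    excess <- w * (amplitude - 1)
    if (excess <= 0.5) -1 else 2 * sigma^2 * log(2 * excess)
  }
  mask_ant <- px[d2 <= r2_contour(w_ant)]
  mask_post <- px[d2 <= r2_contour(w_post)]
  # effective quantified area follows the region's primary-view policy
  area_eff <- switch(reg$primary_view,
                     anterior = length(mask_ant),
                     posterior = length(mask_post),
                     average = (length(mask_ant) + length(mask_post)) / 2)
  list(template = template, mask = sort(union(mask_ant, mask_post)),
       area_eff = area_eff, row = r0, col = c0,
       truth_view = if (reg$primary_view == "average") "both" else reg$primary_view)
}

#' Inject focal lesions into a rendered template
#'
#' Adds `n_metastases` metastatic lesions at random skeletal sites (regions
#' sampled proportionally to pixel area) and `n_benign` benign degenerative
#' lesions restricted to joint and vertebral-margin candidate sites, mimicking
#' the arthritis/degeneration pattern that confounds visual reading. Lesions
#' are isotropic Gaussian multiplicative bumps with region-dependent size
#' (full width at half maximum small in ribs, large in pelvis). Uses the
#' current RNG state; seed upstream (or use [generate_phantom()]).
#'
#' @param template a `phantom_template` from [render_template()].
#' @param config a [phantom_config()].
#' @return list with the modified `template` and `truth`, a tibble with one
#'   row per lesion: class, region, centre, amplitude, pixel `mask`
#'   (list-column of image indices), area and true skeletal involvement (%).
#' @export
inject_lesions <- function(template, config) {
  stopifnot(inherits(template, "phantom_template"), inherits(config, "phantom_config"))
  mf <- mass_fractions()
  regions <- template$regions
  truth <- list()
  centers <- matrix(numeric(0), ncol = 3)  # row, col, fwhm

  too_close <- function(r, c, fwhm) {
    if (nrow(centers) == 0) return(FALSE)
    any(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2) <
          1.2 * (centers[, 3] + fwhm))
  }

  place_metastasis <- function() {
    areas <- lengths(template$region_masks)
    for (try in 1:200) {
      region <- sample(regions$region, 1, prob = areas[regions$region])
      center <- sample(template$region_masks[[region]], 1)
      fwhm <- regions$lesion_fwhm_px[regions$region == region] * template$stature_scale
      r0 <- ((center - 1L) %% IMG_NROW) + 1L
      c0 <- ((center - 1L) %/% IMG_NROW) + 1L
      if (!too_close(r0, c0, fwhm)) return(list(region = region, center = center, fwhm = fwhm))
    }
    stop("could not place a metastatic lesion with the required separation; ",
         "fewer candidate sites than lesions requested", call. = FALSE)
  }

  lesion_record <- function(class, region, amplitude, fwhm, placed) {
    involvement <- 100 * placed$area_eff /
      length(template$region_masks[[region]]) *
      mf$mass_fraction[mf$region == region]
    tibble::tibble(class = class, region = region, view = placed$truth_view,
                   row = placed$row, col = placed$col,
                   amplitude = amplitude, fwhm_px = fwhm,
                   mask = list(placed$mask), area_px = placed$area_eff,
                   involvement_pct = involvement)
  }

  for (i in seq_len(config$n_metastases)) {
    site <- place_metastasis()
    amp <- stats::runif(1, config$lesion_amplitude_range[1], config$lesion_amplitude_range[2])
    placed <- render_lesion(template, site$center, site$region, amp, site$fwhm)
    template <- placed$template
    centers <- rbind(centers, c(placed$row, placed$col, site$fwhm))
    truth[[length(truth) + 1L]] <- lesion_record("metastatic", site$region, amp, site$fwhm, placed)
  }

  sites <- benign_candidate_sites(template$sex)
  if (config$n_benign > nrow(sites))
    stop("n_benign = ", config$n_benign, " exceeds the ", nrow(sites),
         " joint/vertebral candidate sites", call. = FALSE)
  if (config$n_benign > 0) {
    pick <- sample(nrow(sites), config$n_benign)
    for (j in pick) {
      site <- sites[j, ]
      p <- scale_pt(site$x, site$y, template$stature_scale)
      # snap the site to the nearest pixel of its region mask
      px <- template$region_masks[[site$region]]
      pr <- ((px - 1L) %% IMG_NROW) + 1L
      pc <- ((px - 1L) %/% IMG_NROW) + 1L
      center <- px[which.min((pr - p$y)^2 + (pc - p$x)^2)]
      amp <- stats::runif(1, config$benign_amplitude_range[1], config$benign_amplitude_range[2])
      fwhm <- 5 * template$stature_scale
      placed <- render_lesion(template, center, site$region, amp, fwhm)
      template <- placed$template
      truth[[length(truth) + 1L]] <- lesion_record("benign_degenerative", site$region,
                                                   amp, fwhm, placed)
    }
  }

  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(class = character(), region = character(), view = character(),
                   row = integer(), col = integer(), amplitude = numeric(),
                   fwhm_px = numeric(), mask = list(), area_px = integer(),
                   involvement_pct = numeric())
  list(template = template, truth = truth_tbl)
}

#' Apply Poisson counting noise to expected-count maps
#'
#' Scales each view so its expected total equals `total_counts` and draws
#' every pixel independently from a Poisson law, the standard counting model
#' for gamma-camera acquisitions. Uses the current RNG state.
#'
#' Before the draw, the expected-count maps are convolved with a Gaussian of
#' `psf_sigma` pixels emulating the gamma camera's system resolution (~10 mm
#' FWHM at 2.2 mm pixels), so rendered region edges blur the way acquired
#' scans do.
#'
#' @param template a `phantom_template` (possibly with lesions injected).
#' @param total_counts expected whole-image counts per view.
#' @param psf_sigma system-resolution blur in pixels (0 disables).
#' @return a `scintigram_pair`: integer count matrices `anterior` and
#'   `posterior` (1024 rows x 256 columns), `sex`, `pixel_spacing_mm` and a
#'   free-form `meta` list.
#' @export
apply_counting_noise <- function(template, total_counts, psf_sigma = 2) {
  stopifnot(inherits(template, "phantom_template"))
  if (!all(is.finite(template$anterior)) || !all(is.finite(template$posterior)))
    stop("expected-count maps contain non-finite values", call. = FALSE)
  if (total_counts < 0) stop("total_counts must be >= 0", call. = FALSE)
  draw <- function(map) {
    if (psf_sigma > 0) map <- gauss_smooth(map, psf_sigma)
    tot <- sum(map)
    lambda <- if (tot > 0 && total_counts > 0) map * (total_counts / tot) else map * 0
    matrix(stats::rpois(length(lambda), lambda), IMG_NROW, IMG_NCOL)
  }
  new_scintigram_pair(draw(template$anterior), draw(template$posterior),
                      sex = template$sex,
                      pixel_spacing_mm = template$pixel_spacing_mm,
                      meta = list(stature_scale = template$stature_scale,
                                  total_counts = total_counts))
}

new_scintigram_pair <- function(anterior, posterior, sex, pixel_spacing_mm = 2.2,
                                meta = list()) {
  stopifnot(identical(dim(anterior), c(IMG_NROW, IMG_NCOL)),
            identical(dim(posterior), c(IMG_NROW, IMG_NCOL)))
  if (any(anterior < 0) || any(posterior < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(anterior = anterior, posterior = posterior, sex = sex,
                 pixel_spacing_mm = pixel_spacing_mm, meta = meta),
            class = "scintigram_pair")
}

#' @export
print.scintigram_pair <- function(x, ...) {
  cat("scintigram_pair (", x$sex, "): 256 x 1024 per view; counts ant/post = ",
      format(sum(x$anterior)), " / ", format(sum(x$posterior)), "\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic phantom
#'
#' One-call wrapper: seeds the RNG from `config$seed`, renders the template,
#' injects lesions and applies counting noise. Identical configurations give
#' bit-identical phantoms.
#'
#' @param config a [phantom_config()].
#' @param keep_template keep the noise-free lesion-bearing template in the
#'   result (needed for noise-free analyses; adds ~8 MB per phantom).
#' @return a `bone_phantom`: `pair` (scintigram_pair), `truth` (lesion
#'   tibble), `config`, and optionally `template`.
#' @examples
#' ph <- generate_phantom(phantom_config(n_metastases = 2, n_benign = 1, seed = 7))
#' ph$truth[, c("class", "region", "involvement_pct")]
#' @export
generate_phantom <- function(config = phantom_config(), keep_template = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  template <- render_template(config$sex, config$stature_scale)
  inj <- inject_lesions(template, config)
  pair <- apply_counting_noise(inj$template, config$total_counts)
  out <- list(pair = pair, truth = inj$truth, config = config)
  if (keep_template) out$template <- inj$template
  structure(out, class = "bone_phantom")
}

#' @export
print.bone_phantom <- function(x, ...) {
  cat("bone_phantom: seed", x$config$seed, "-",
      sum(x$truth$class == "metastatic"), "metastatic +",
      sum(x$truth$class == "benign_degenerative"), "benign lesions; truth BSI",
      round(sum(x$truth$involvement_pct[x$truth$class == "metastatic"]), 2), "%\n")
  invisible(x)
}
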