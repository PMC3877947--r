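# Seeded validation experiments on the synthetic phantom population. These
# are the package's reference study conditions; tests and the acceptance
# script call them unchanged.

# sub-seeds derived reproducibly from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Match detected hot spots to phantom ground truth
#'
#' Labels each detected hot spot `metastatic` when its mask overlaps any
#' metastatic truth lesion (otherwise `non_metastatic`, covering benign
#' lesions and spurious detections), and reports which truth lesions were
#' recovered.
#'
#' @param hotspots detected hot-spot tibble (with `mask` list-column).
#' @param truth phantom truth tibble.
#' @return list: `hotspots` (with `label` column), `lesion_detected` (logical
#'   per truth row), `n_false` (hot spots overlapping no truth lesion).
#' @export
match_hotspots_truth <- function(hotspots, truth) {
  met_masks <- truth$mask[truth$class == "metastatic"]
  all_masks <- truth$mask
  overlaps_any <- function(m, masks)
    length(masks) > 0 && any(vapply(masks, function(t) any(m %in% t), logical(1)))
  lab <- vapply(hotspots$mask, function(m)
    if (overlaps_any(m, met_masks)) "metastatic" else "non_metastatic",
    character(1))
  lesion_detected <- vapply(all_masks, function(t)
    nrow(hotspots) > 0 && any(vapply(hotspots$mask, function(m) any(m %in% t),
                                     logical(1))), logical(1))
  n_false <- sum(vapply(hotspots$mask, function(m) !overlaps_any(m, all_masks),
                        logical(1)))
  list(hotspots = dplyr::mutate(hotspots, label = lab),
       lesion_detected = lesion_detected, n_false = n_false)
}

#' Detection recovery sweep
#'
#' Generates seeded phantoms carrying metastatic lesions of amplitude >= 3x
#' local uptake at realistic counting statistics, runs the adaptive detector
#' against the true segmentation, and measures lesion-level sensitivity and
#' the number of spurious hot spots per phantom.
#'
#' @param n_phantoms number of phantoms.
#' @param n_metastases lesions per phantom.
#' @param seed master seed.
#' @param lesion_amplitude_range amplitude range (default the 3-5x regime).
#' @param total_counts expected counts per view.
#' @param control a [detect_control()].
#' @return list: `per_phantom` tibble (`seed`, `n_truth`, `n_detected`,
#'   `n_false`), `sensitivity` (pooled lesion-level), `false_per_phantom`.
#' @export
run_detection_sweep <- function(n_phantoms = 20, n_metastases = 5, seed = 1L,
                                lesion_amplitude_range = c(3, 5),
                                total_counts = 1e6,
                                control = detect_control()) {
  seeds <- derive_seeds(seed, n_phantoms)
  atlases <- list(male = load_atlas("male"), female = load_atlas("female"))
  rows <- purrr::map(seq_len(n_phantoms), function(i) {
    sx <- if (i %% 2 == 0) "female" else "male"
    cfg <- phantom_config(sex = sx, n_metastases = n_metastases, n_benign = 0,
                          lesion_amplitude_range = lesion_amplitude_range,
                          total_counts = total_counts, seed = seeds[i])
    ph <- generate_phantom(cfg, keep_template = TRUE)
    seg <- truth_segmentation(ph$template)
    hs <- detect_scan(ph$pair, seg, atlases[[sx]], control)
    m <- match_hotspots_truth(hs, ph$truth)
    tibble::tibble(seed = seeds[i], sex = sx, n_truth = nrow(ph$truth),
                   n_detected = sum(m$lesion_detected), n_false = m$n_false)
  })
  per <- dplyr::bind_rows(rows)
  list(per_phantom = per,
       sensitivity = sum(per$n_detected) / sum(per$n_truth),
       false_per_phantom = mean(per$n_false))
}

#' Apply a synthetic affine + smooth deformation to a template
#'
#' Test-harness transform with known ground truth: a global affine
#' (translation, per-axis scale, rotation about the image centre) composed
#' with a smooth random displacement field, applied by backward warping to
#' the expected-count maps (bilinear) and label maps (nearest-neighbour).
#'
#' @param template a `phantom_template`.
#' @param translation length-2 (rows, cols) pixels.
#' @param scale length-2 per-axis scale factors.
#' @param rotation radians.
#' @param smooth_amplitude peak smooth-field displacement in pixels (0 = none).
#' @param seed seed for the smooth field.
#' @return the deformed `phantom_template`.
#' @export
deform_template <- function(template, translation = c(0, 0), scale = c(1, 1),
                            rotation = 0, smooth_amplitude = 0, seed = 1L) {
  stopifnot(inherits(template, "phantom_template"))
  nr <- IMG_NROW
  nc <- IMG_NCOL
  theta <- c(translation[1], translation[2], log(scale[1]), log(scale[2]), rotation)
  gr <- matrix(seq_len(nr), nr, nc)
  gc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  w <- affine_map(as.numeric(gr), as.numeric(gc), theta, nr, nc)
  pr <- w$r
  pc <- w$c
  if (smooth_amplitude > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    mk <- function() {
      f <- gauss_smooth(matrix(stats::rnorm(32 * 8), 32, 8), 2)
      f <- upsample_field(f, 32, nr, nc)
      f * (smooth_amplitude / max(abs(f)))
    }
    pr <- pr + as.numeric(mk())
    pc <- pc + as.numeric(mk())
  }
  out <- template
  for (fld in c("anterior", "posterior"))
    out[[fld]] <- matrix(bilinear_sample(template[[fld]], pr, pc), nr, nc)
  for (fld in c("labels_anterior", "labels_posterior"))
    out[[fld]] <- matrix(nearest_sample(template[[fld]], pr, pc), nr, nc)
  out
}

#' Registration recovery sweep
#'
#' Applies random small affine + smooth deformations to the atlas reference,
#' adds counting noise, registers the atlas back, and scores per-pixel label
#' agreement against the known deformed labels.
#'
#' @param n_trials number of seeded trials.
#' @param seed master seed.
#' @param total_counts counts per view for the noisy target.
#' @param control a [register_control()].
#' @return list: `per_trial` tibble (`label_agreement`, `quality`),
#'   `mean_agreement`.
#' @export
run_registration_sweep <- function(n_trials = 20, seed = 1L, total_counts = 1e6,
                                   control = register_control()) {
  seeds <- derive_seeds(seed, n_trials)
  atlas <- load_atlas("male")
  tpl <- render_template("male", 1)
  rows <- purrr::map(seq_len(n_trials), function(i) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seeds[i])
    wt <- deform_template(tpl,
                          translation = stats::runif(2, -6, 6),
                          scale = stats::runif(2, 0.95, 1.05),
                          rotation = stats::runif(1, -0.035, 0.035),
                          smooth_amplitude = stats::runif(1, 2, 5),
                          seed = seeds[i])
    pair <- apply_counting_noise(wt, total_counts)
    seg <- register_atlas(atlas, pair, control)
    ag <- vapply(c("anterior", "posterior"), function(v) {
      truth <- wt[[paste0("labels_", v)]]
      skel <- truth > 0
      mean(seg$labels[[v]][skel] == truth[skel])
    }, numeric(1))
    tibble::tibble(seed = seeds[i], label_agreement = mean(ag),
                   quality = mean(seg$quality))
  })
  per <- dplyr::bind_rows(rows)
  list(per_trial = per, mean_agreement = mean(per$label_agreement))
}

# one training/evaluation phantom configuration drawn from the population mix
draw_population_config <- function(sub_seed, positive = NA) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed)
  sx <- sample(c("male", "female"), 1)
  if (is.na(positive)) positive <- stats::runif(1) < 0.5
  phantom_config(
    sex = sx,
    stature_scale = stats::runif(1, 0.9, 1.1),
    n_metastases = if (positive) sample(1:6, 1) else 0L,
    n_benign = sample(0:5, 1) + if (positive) 0L else 1L,
    lesion_amplitude_range = c(3, 5),
    benign_amplitude_range = c(1.6, 2.8),
    total_counts = 1e6,
    seed = sub_seed
  )
}

#' Build a hot-spot training set from seeded phantoms
#'
#' Generates phantoms, detects hot spots against the true segmentation and
#' labels them by overlap with the metastatic truth masks.
#'
#' @param n_phantoms phantoms to simulate.
#' @param seed master seed.
#' @param control a [detect_control()].
#' @return tibble of featurized, labelled hot spots with `sex` and `region`.
#' @export
build_training_set <- function(n_phantoms = 300, seed = 1L,
                               control = detect_control()) {
  seeds <- derive_seeds(seed, n_phantoms)
  atlases <- list(male = load_atlas("male"), female = load_atlas("female"))
  purrr::map_dfr(seq_len(n_phantoms), function(i) {
    cfg <- draw_population_config(seeds[i])
    ph <- generate_phantom(cfg, keep_template = TRUE)
    seg <- truth_segmentation(ph$template)
    hs <- detect_scan(ph$pair, seg, atlases[[cfg$sex]], control)
    if (nrow(hs) == 0L) return(NULL)
    m <- match_hotspots_truth(hs, ph$truth)
    dplyr::mutate(m$hotspots, sex = cfg$sex, phantom = i)
  })
}

#' End-to-end discrimination experiment
#'
#' Trains the classifier registry on hot spots from `n_train` seeded phantoms
#' (true segmentation, truth-labelled), then evaluates the patient-level
#' abnormality score on `n_eval` held-out phantoms - half with at least one
#' metastatic lesion, half with benign lesions only - running the full
#' pipeline including atlas registration. Reports the patient-level ROC.
#'
#' @param n_train training phantoms.
#' @param n_eval held-out evaluation phantoms (half positive).
#' @param seed master seed.
#' @param control a [detect_control()].
#' @param register a [register_control()].
#' @return list: `auc`, `roc` (`roc_result`), `cohort` (per-patient tibble
#'   with `ann_value`, `bsi`, `label`), `registry`, `n_train_hotspots`.
#' @export
run_discrimination_experiment <- function(n_train = 300, n_eval = 100, seed = 1L,
                                          control = detect_control(),
                                          register = register_control()) {
  training <- build_training_set(n_train, seed = seed, control = control)
  registry <- train_classifiers(training, seed = seed)

  eval_seeds <- derive_seeds(seed + 1L, n_eval)
  atlases <- list(male = load_atlas("male"), female = load_atlas("female"))
  positives <- rep(c(TRUE, FALSE), length.out = n_eval)
  cohort <- purrr::map_dfr(seq_len(n_eval), function(i) {
    cfg <- draw_population_config(eval_seeds[i], positive = positives[i])
    ph <- generate_phantom(cfg)
    res <- run_pipeline(ph$pair, registry, atlas = atlases[[cfg$sex]],
                        detect = control, register = register)
    tibble::tibble(patient = i, sex = cfg$sex,
                   label = as.integer(positives[i]),
                   ann_value = res$ann_value, bsi = res$bsi,
                   n_hotspots = nrow(res$hotspots),
                   truth_bsi = sum(ph$truth$involvement_pct[ph$truth$class == "metastatic"]))
  })
  roc <- roc_analysis(cohort, score = "ann_value", label = "label")
  list(auc = roc$auc, roc = roc, cohort = cohort, registry = registry,
       n_train_hotspots = nrow(training))
}

#' Type-I error calibration of the paired AUC test
#'
#' Simulates paired predictors with equal true AUC (both equal to a shared
#' latent signal plus independent noise) and measures the rejection rate of
#' [compare_auc()] at level `alpha`.
#'
#' @param n_reps null replicates.
#' @param n patients per replicate (half events).
#' @param alpha nominal level.
#' @param seed master seed.
#' @return list: `rejection_rate`, `n_reps`, `alpha`.
#' @export
run_auc_null_calibration <- function(n_reps = 2000, n = 60, alpha = 0.05,
                                     seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rejections <- vapply(seq_len(n_reps), function(i) {
    y <- rep(c(0, 1), each = n / 2)
    latent <- y * 0.8
    a <- latent + stats::rnorm(n)
    b <- latent + stats::rnorm(n)
    compare_auc(a, b, y)$p_value < alpha
  }, logical(1))
  list(rejection_rate = mean(rejections), n_reps = n_reps, alpha = alpha)
}
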