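# small synthetic segmentations for threshold arithmetic, plus phantom cases

flat_segmentation <- function(nr = 1024, nc = 256) {
  # one-region "skeleton" strip for constant-background checks
  tpl <- fixture_template("male")
  truth_segmentation(tpl)
}

test_that("threshold is k times the background on a constant image", {
  seg <- flat_segmentation()
  img <- matrix(100, 1024, 256)
  ctrl <- detect_control(k = 1.5)
  thr <- threshold_map(img, seg, "anterior", ctrl)
  on_skel <- !is.na(thr$threshold)
  expect_true(any(on_skel))
  expect_equal(unname(range(thr$threshold[on_skel])), c(150, 150),
               tolerance = 1e-9)
})

test_that("threshold map is homogeneous of degree one in the image", {
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  set.seed(5)
  img <- apply_counting_noise(tpl, 5e5)$anterior
  t1 <- threshold_map(img, seg, "anterior")
  t10 <- threshold_map(img * 10, seg, "anterior")
  sk <- !is.na(t1$threshold)
  expect_equal(t10$threshold[sk], 10 * t1$threshold[sk], tolerance = 1e-9)
})

test_that("rib and spine thresholds scale with their local uptake", {
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  # noise-free blurred expected map: regional medians are the configured levels
  img <- gauss_smooth(tpl$posterior, 2) * 1000
  thr <- threshold_map(img, seg, "posterior")
  rib_id <- tpl$regions$id[tpl$regions$region == "ribs_left"]
  spine_id <- tpl$regions$id[tpl$regions$region == "lumbar_spine"]
  rib_med <- stats::median(thr$threshold[seg$labels$posterior == rib_id])
  spine_med <- stats::median(thr$threshold[seg$labels$posterior == spine_id])
  r <- tpl$regions
  expected <- (r$uptake[rib_id] * r$emphasis_posterior[rib_id]) /
    (r$uptake[spine_id] * r$emphasis_posterior[spine_id])
  expect_equal(rib_med / spine_med, expected, tolerance = 0.15)
})

test_that("noise-free lesion-free phantom yields zero hot spots, and lesions
          of threefold amplitude are each found once", {
  atl <- fixture_atlas("male")
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  clean <- gauss_smooth(tpl$anterior, 2) * 1e4
  hs0 <- detect_hotspots(clean, seg, "anterior", atl)
  expect_identical(nrow(hs0), 0L)

  cfg <- phantom_config(n_metastases = 3, n_benign = 0,
                        lesion_amplitude_range = c(3, 3.0001), seed = 60)
  set.seed(60)
  inj <- inject_lesions(tpl, cfg)
  img <- gauss_smooth(inj$template$anterior, 2) * 1e4
  hs <- detect_hotspots(img, seg, "anterior", atl)
  expect_identical(nrow(hs), 3L)
  hits <- vapply(seq_len(3), function(i)
    sum(vapply(ph_masks <- inj$truth$mask, function(tm)
      any(hs$mask[[i]] %in% tm), logical(1))), integer(1))
  expect_true(all(hits == 1L))

  # min_area larger than the biggest lesion suppresses everything
  big <- detect_control(min_area = max(hs$area_px) + 1L)
  expect_identical(nrow(detect_hotspots(img, seg, "anterior", atl, big)), 0L)
})

test_that("detected masks are invariant to positive global scaling", {
  atl <- fixture_atlas("male")
  ph <- generate_phantom(phantom_config(n_metastases = 4, seed = 71),
                         keep_template = TRUE)
  seg <- truth_segmentation(ph$template)
  h1 <- detect_hotspots(ph$pair$anterior, seg, "anterior", atl)
  h2 <- detect_hotspots(ph$pair$anterior * 3.7, seg, "anterior", atl)
  expect_identical(h1$mask, h2$mask)
})

test_that("raising k or min_area never increases the hot-spot count", {
  atl <- fixture_atlas("male")
  ph <- generate_phantom(phantom_config(n_metastases = 5, n_benign = 2, seed = 72),
                         keep_template = TRUE)
  seg <- truth_segmentation(ph$template)
  counts_k <- vapply(c(1.3, 1.5, 1.8, 2.2), function(k)
    nrow(detect_hotspots(ph$pair$anterior, seg, "anterior", atl,
                         detect_control(k = k))), integer(1))
  expect_true(all(diff(counts_k) <= 0))
  counts_a <- vapply(c(4L, 8L, 16L, 40L), function(a)
    nrow(detect_hotspots(ph$pair$anterior, seg, "anterior", atl,
                         detect_control(min_area = a))), integer(1))
  expect_true(all(diff(counts_a) <= 0))
})

test_that("component labelling matches a flood-fill oracle on random masks", {
  set.seed(123)
  for (trial in 1:20) {
    mask <- matrix(stats::runif(48 * 48) < 0.35, 48, 48)
    mine <- label_components(mask, 8)
    oracle <- oracle_components(mask, 8)
    expect_identical(max(mine), max(oracle))
    # same partition: component ids co-vary one-to-one
    tab <- table(mine[mask], oracle[mask])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  m4 <- label_components(matrix(c(1, 0, 0, 1), 2, 2), 4)
  expect_identical(max(m4), 2L)
})

test_that("feature vectors are scale-free and geometrically sensible", {
  atl <- fixture_atlas("male")
  ph <- generate_phantom(phantom_config(n_metastases = 4, n_benign = 1, seed = 80),
                         keep_template = TRUE)
  seg <- truth_segmentation(ph$template)
  hs <- detect_hotspots(ph$pair$anterior, seg, "anterior", atl)
  f1 <- extract_features(hs, ph$pair$anterior, seg, atl)
  f10 <- extract_features(hs, ph$pair$anterior * 10, seg, atl)
  feat_cols <- feature_names()
  expect_equal(as.data.frame(f1[, feat_cols]), as.data.frame(f10[, feat_cols]),
               tolerance = 1e-12)
  expect_true(all(f1$intensity_max_rel > 0))
  expect_true(all(f1$region_fraction > 0 & f1$region_fraction <= 1))
  expect_true(all(f1$solidity > 0 & f1$solidity <= 1))
  expect_true(all(is.finite(as.matrix(f1[, feat_cols]))))
})

test_that("a synthetic disc has low eccentricity and full solidity,
          and a single pixel takes the degenerate values", {
  atl <- fixture_atlas("male")
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  img <- gauss_smooth(tpl$anterior, 2) * 1e4
  # paint a bright disc inside the pelvis
  pelvis <- tpl$region_masks$pelvis
  nr <- 1024
  pr <- ((pelvis - 1) %% nr) + 1
  pc <- ((pelvis - 1) %/% nr) + 1
  ctr <- pelvis[which.min((pr - 610)^2 + (pc - 97)^2)]
  disc <- disc_indices(1024, 256, 610, 97, 6)
  disc <- intersect(disc, pelvis)
  img[disc] <- img[disc] * 5
  hs <- detect_hotspots(img, seg, "anterior", atl)
  expect_identical(nrow(hs), 1L)
  f <- extract_features(hs, img, seg, atl)
  expect_lt(f$eccentricity, 0.35)
  expect_gt(f$solidity, 0.9)

  single <- tibble::tibble(view = "anterior", region = "pelvis",
                           area_px = 1L, row = 610, col = 97,
                           mask = list(ctr))
  fs <- extract_features(single, img, seg, atl)
  expect_identical(fs$eccentricity, 0)
  expect_identical(fs$solidity, 1)
})

test_that("hot spots stay inside their assigned region's labelled pixels
          in the majority-vote sense", {
  atl <- fixture_atlas("male")
  ph <- generate_phantom(phantom_config(n_metastases = 6, n_benign = 2, seed = 90),
                         keep_template = TRUE)
  seg <- truth_segmentation(ph$template)
  hs <- detect_scan(ph$pair, seg, atl)
  ids <- seg$regions
  for (i in seq_len(nrow(hs))) {
    lab <- seg$labels[[hs$view[i]]][hs$mask[[i]]]
    maj <- as.integer(names(which.max(table(lab))))
    expect_identical(ids$region[match(maj, ids$id)], hs$region[i])
  }
})
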