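make_hotspot_row <- function(region, view, area, prob = 1) {
  tibble::tibble(view = view, region = region, area_px = as.integer(area),
                 row = 0, col = 0, mask = list(integer(0)), probability = prob)
}

test_that("involvement follows the area-fraction x mass-fraction arithmetic", {
  atl <- fixture_atlas("male")
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  pelvis_area <- region_pixel_area(seg, "pelvis", "anterior")
  hs <- make_hotspot_row("pelvis", "anterior", 50)
  out <- skeletal_involvement(hs, seg, atl)
  expect_equal(out$involvement_pct,
               100 * 50 / pelvis_area * atl$mass_fraction[["pelvis"]],
               tolerance = 1e-12)
  # full region -> 100 x mass fraction
  full <- skeletal_involvement(make_hotspot_row("pelvis", "anterior", pelvis_area),
                               seg, atl)
  expect_equal(full$involvement_pct, 100 * atl$mass_fraction[["pelvis"]],
               tolerance = 1e-12)
  # occluded region (sternum has no posterior pixels) -> explicit data error
  expect_error(skeletal_involvement(make_hotspot_row("sternum", "posterior", 5),
                                    seg, atl),
               "zero pixel area")
})

test_that("the worked 50-pixel example gives 1.1 percent", {
  # 50 px in a 500-px pelvis with mass fraction 0.11: 50/500 * 0.11 * 100
  atl <- fixture_atlas("male")
  atl$mass_fraction[] <- 0
  atl$mass_fraction[["pelvis"]] <- 0.11
  seg <- truth_segmentation(fixture_template("male"))
  # synthesize the denominator: shrink the segmentation to 500 pelvis pixels
  pel_id <- seg$regions$id[seg$regions$region == "pelvis"]
  px <- which(seg$labels$anterior == pel_id)
  seg$labels$anterior[px[-seq_len(500)]] <- 0L
  out <- skeletal_involvement(make_hotspot_row("pelvis", "anterior", 50), seg, atl)
  expect_equal(out$involvement_pct, 1.1, tolerance = 1e-12)
})

test_that("BSI of an empty hot-spot set is exactly zero", {
  res <- compute_bsi(make_hotspot_row("pelvis", "anterior", 1)[0, ])
  expect_identical(res$bsi, 0)
  expect_identical(res$ann_value, 0)
})

test_that("full involvement of every region at probability one gives BSI 100", {
  atl <- fixture_atlas("male")
  tpl <- fixture_template("male")
  seg <- truth_segmentation(tpl)
  hs <- purrr::map_dfr(seg$regions$region, function(rg) {
    purrr::map_dfr(c("anterior", "posterior"), function(v) {
      a <- region_pixel_area(seg, rg, v)
      if (a == 0) return(NULL)
      make_hotspot_row(rg, v, a)
    })
  })
  hs <- skeletal_involvement(hs, seg, atl)
  res <- compute_bsi(hs, seg)
  expect_equal(res$bsi, 100, tolerance = 1e-6)
})

test_that("BSI is additive over disjoint-region lesion sets", {
  atl <- fixture_atlas("male")
  seg <- truth_segmentation(fixture_template("male"))
  set_a <- skeletal_involvement(dplyr::bind_rows(
    make_hotspot_row("pelvis", "anterior", 80),
    make_hotspot_row("skull", "anterior", 40)), seg, atl)
  set_b <- skeletal_involvement(dplyr::bind_rows(
    make_hotspot_row("lumbar_spine", "posterior", 60),
    make_hotspot_row("femur_left", "anterior", 30)), seg, atl)
  both <- dplyr::bind_rows(set_a, set_b)
  expect_equal(compute_bsi(both, seg)$bsi,
               compute_bsi(set_a, seg)$bsi + compute_bsi(set_b, seg)$bsi,
               tolerance = 1e-9)
})

test_that("three metastatic lesions sum their involvements", {
  hs <- dplyr::bind_rows(
    make_hotspot_row("lumbar_spine", "posterior", 10),
    make_hotspot_row("thoracic_spine", "posterior", 10),
    make_hotspot_row("sternum", "anterior", 10))
  hs$involvement_pct <- c(1.2, 0.4, 2.1)
  res <- compute_bsi(hs, NULL)
  expect_equal(res$bsi, 3.7, tolerance = 1e-12)
})

test_that("lowering the metastasis threshold never decreases BSI", {
  hs <- dplyr::bind_rows(
    make_hotspot_row("lumbar_spine", "posterior", 10, prob = 0.3),
    make_hotspot_row("thoracic_spine", "posterior", 10, prob = 0.6),
    make_hotspot_row("sternum", "anterior", 10, prob = 0.9))
  hs$involvement_pct <- c(1, 1, 1)
  bsis <- vapply(c(0.95, 0.7, 0.5, 0.2, 0),
                 function(t) compute_bsi(hs, NULL, metastasis_threshold = t)$bsi,
                 numeric(1))
  expect_true(all(diff(bsis) >= 0))
})

test_that("averaged regions weight the two views by half, single-view regions
          use only their primary view", {
  hs <- dplyr::bind_rows(
    make_hotspot_row("pelvis", "anterior", 10),
    make_hotspot_row("pelvis", "posterior", 10),
    make_hotspot_row("lumbar_spine", "anterior", 10),   # off-policy view
    make_hotspot_row("lumbar_spine", "posterior", 10))
  hs$involvement_pct <- c(2, 2, 5, 3)
  res <- compute_bsi(hs, NULL)
  # pelvis: (2 + 2)/2 = 2; lumbar: posterior only = 3
  expect_equal(res$bsi, 5, tolerance = 1e-12)
})

test_that("computed BSI tracks phantom truth within 20 percent on noise-free
          phantoms", {
  atl_m <- fixture_atlas("male")
  rel_err <- vapply(1:8, function(s) {
    cfg <- phantom_config(n_metastases = 4, n_benign = 0,
                          lesion_amplitude_range = c(3, 5), seed = 300 + s)
    ph <- generate_phantom(cfg, keep_template = TRUE)
    seg <- truth_segmentation(ph$template)
    # noise-free detection: ideal expected-count maps instead of Poisson draws
    clean <- ph$pair
    clean$anterior <- ph$template$anterior * 1e4
    clean$posterior <- ph$template$posterior * 1e4
    hs <- detect_scan(clean, seg, atl_m)
    hs$probability <- 1
    hs <- skeletal_involvement(hs, seg, atl_m)
    bsi <- compute_bsi(hs, seg)$bsi
    truth <- sum(ph$truth$involvement_pct)
    (bsi - truth) / truth
  }, numeric(1))
  expect_true(all(abs(rel_err) <= 0.2))
})
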