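test_that("rendered template carries the full region ontology and fixed matrix", {
  tpl <- fixture_template("male")
  expect_identical(dim(tpl$anterior), c(1024L, 256L))
  expect_identical(dim(tpl$posterior), c(1024L, 256L))
  ant_regions <- setdiff(unique(as.vector(tpl$labels_anterior)), 0L)
  post_regions <- setdiff(unique(as.vector(tpl$labels_posterior)), 0L)
  expect_gte(length(ant_regions), 12)
  expect_gte(length(post_regions), 12)
  # every skeletal pixel carries exactly one label by construction (a matrix),
  # and labels come from the region table
  expect_true(all(ant_regions %in% tpl$regions$id))
})

test_that("stature scaling strictly grows the rendered skeleton", {
  a10 <- sum(lengths(fixture_template("male", 1)$region_masks))
  a12 <- sum(lengths(fixture_template("male", 1.2)$region_masks))
  expect_gt(a12, a10)
})

test_that("regional mean expected counts follow the configured uptake table", {
  tpl <- fixture_template("female")
  skull_id <- tpl$regions$id[tpl$regions$region == "skull"]
  rib_id <- tpl$regions$id[tpl$regions$region == "ribs_left"]
  skull_mean <- mean(tpl$anterior[tpl$labels_anterior == skull_id])
  rib_mean <- mean(tpl$anterior[tpl$labels_anterior == rib_id])
  # female skull uptake is configured well above rib uptake
  expect_gt(skull_mean, rib_mean)
  # and the rendered ratio matches the configured factors (view emphasis in)
  r <- tpl$regions
  expected_ratio <- (r$uptake[r$id == skull_id] * r$emphasis_anterior[r$id == skull_id]) /
    (r$uptake[r$id == rib_id] * r$emphasis_anterior[r$id == rib_id])
  expect_equal(skull_mean / rib_mean, expected_ratio, tolerance = 1e-10)
})

test_that("configuration validation rejects out-of-contract inputs", {
  expect_error(render_template("child"), "male")
  expect_error(render_template("male", 1.5), "stature")
  expect_error(phantom_config(n_metastases = -1), "non-negative")
  expect_error(phantom_config(lesion_amplitude_range = c(0.9, 2)), "min > 1")
})

test_that("lesion injection conserves counts and restricts benign sites", {
  tpl <- fixture_template("male")
  cfg0 <- phantom_config(n_metastases = 0, n_benign = 0, seed = 3)
  inj0 <- inject_lesions(tpl, cfg0)
  expect_identical(inj0$template$anterior, tpl$anterior)
  expect_identical(nrow(inj0$truth), 0L)

  set.seed(42)
  cfg5 <- phantom_config(n_metastases = 5, n_benign = 4, seed = 42)
  inj5 <- inject_lesions(tpl, cfg5)
  expect_identical(sum(inj5$truth$class == "metastatic"), 5L)
  expect_identical(sum(inj5$truth$class == "benign_degenerative"), 4L)
  # masks lie inside the lesion's own region mask
  for (i in seq_len(nrow(inj5$truth))) {
    expect_true(all(inj5$truth$mask[[i]] %in%
                      tpl$region_masks[[inj5$truth$region[i]]]))
  }
  # benign lesions sit at joint/vertebral-margin regions only
  expect_true(all(inj5$truth$region[inj5$truth$class == "benign_degenerative"] %in%
                    unique(benign_candidate_sites("male")$region)))
  # capacity error when requesting more benign lesions than candidate sites
  expect_error(inject_lesions(tpl, phantom_config(n_benign = 100)), "candidate sites")
})

test_that("phantom generation is bit-identical under a fixed seed", {
  cfg <- phantom_config(n_metastases = 3, n_benign = 2, seed = 77)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$pair$anterior, b$pair$anterior)
  expect_identical(a$pair$posterior, b$pair$posterior)
  expect_identical(a$truth, b$truth)
})

test_that("counting noise follows the Poisson law", {
  tpl <- fixture_template("male")
  # zero requested counts -> all-zero images
  set.seed(1)
  z <- apply_counting_noise(tpl, 0)
  expect_true(all(z$anterior == 0) && all(z$posterior == 0))

  # realized totals concentrate on the configured expectation
  # (psf blur off: the counting model is what is under test)
  set.seed(99)
  sums <- replicate(100, sum(apply_counting_noise(tpl, 1e6, psf_sigma = 0)$anterior))
  expect_lt(abs(mean(sums) / 1e6 - 1), 0.01)

  # pixel variance ~ pixel mean (Poisson), within 3 standard errors
  px <- tpl$region_masks$lumbar_spine[200]
  set.seed(7)
  draws <- replicate(1000, apply_counting_noise(tpl, 1e6, psf_sigma = 0)$posterior[px])
  m <- mean(draws)
  v <- stats::var(draws)
  se <- m * sqrt(2 / (length(draws) - 1))   # var of sample variance ~ 2m^2/(n-1)
  expect_lt(abs(v - m), 3 * se)

  # integer, non-negative output
  set.seed(2)
  p <- apply_counting_noise(tpl, 1e5)
  expect_true(all(p$anterior >= 0) && all(p$anterior == round(p$anterior)))
})

test_that("truth lesions overlap the region their record names", {
  ph <- generate_phantom(phantom_config(n_metastases = 4, n_benign = 3, seed = 5),
                         keep_template = TRUE)
  tpl <- ph$template
  for (i in seq_len(nrow(ph$truth))) {
    rid <- tpl$regions$id[tpl$regions$region == ph$truth$region[i]]
    lab_hits <- c(tpl$labels_anterior[ph$truth$mask[[i]]],
                  tpl$labels_posterior[ph$truth$mask[[i]]])
    expect_true(rid %in% lab_hits)
  }
  expect_lte(sum(ph$truth$involvement_pct), 100)
})

test_that("scintigram pairs round-trip through PGM files bit-exactly", {
  ph <- generate_phantom(phantom_config(seed = 8, total_counts = 2e5))
  dir <- withr::local_tempdir()
  paths <- write_scintigram(ph$pair, dir)
  back <- read_scintigram(paths[["anterior"]], paths[["posterior"]],
                          meta = paths[["meta"]])
  expect_identical(back$anterior, ph$pair$anterior)
  expect_identical(back$posterior, ph$pair$posterior)
  expect_identical(back$sex, ph$pair$sex)
})

test_that("scintigram reader validates dimensions and promotes 8-bit input", {
  dir <- withr::local_tempdir()
  small <- matrix(5L, 512, 128)
  write_pgm(small, file.path(dir, "small.pgm"))
  expect_error(read_scintigram(file.path(dir, "small.pgm"),
                               file.path(dir, "small.pgm"), sex = "male"),
               "expected 256 x 1024")
  eight <- matrix(17L, 1024, 256)
  write_pgm(eight, file.path(dir, "eight.pgm"), maxval = 255L)
  write_pgm(eight, file.path(dir, "sixteen.pgm"))
  expect_warning(
    pair <- read_scintigram(file.path(dir, "eight.pgm"),
                            file.path(dir, "sixteen.pgm"), sex = "male"),
    "8-bit")
  expect_true(all(pair$anterior == 17L))
  expect_identical(pair$anterior, pair$posterior)
})
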