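# Multi-scale non-rigid registration of the atlas reference to a patient
# scintigram. The pipeline is a standard replacement for proprietary
# phase-based registration: a global similarity/affine stage fitted by
# normalized cross-correlation, followed by a demons-style free-form
# refinement with Gaussian smoothness regularization, run coarse-to-fine.

#' Registration tuning parameters
#'
#' @param coarse_factor integer downsampling factor for the working scale.
#' @param demons_iter iterations of the demons refinement at the working scale.
#' @param demons_sigma Gaussian smoothing (in working-scale pixels) applied to
#'   the displacement field every iteration; larger is stiffer.
#' @param affine_maxit Nelder-Mead iterations for the global affine stage.
#' @param quality_floor registration quality (NCC) below which the result is
#'   flagged `low_quality` (the pipeline warns rather than aborts).
#' @return list of class `register_control`.
#' @export
register_control <- function(coarse_factor = 4L, demons_iter = 20L,
                             demons_sigma = 1.5, affine_maxit = 100L,
                             quality_floor = 0.5) {
  structure(list(coarse_factor = as.integer(coarse_factor),
                 demons_iter = as.integer(demons_iter),
                 demons_sigma = demons_sigma,
                 affine_maxit = as.integer(affine_maxit),
                 quality_floor = quality_floor),
            class = "register_control")
}

# robust photometric normalization: images are compared on a log scale with
# zero mean / unit variance so count statistics and template units cancel
norm_image <- function(M) {
  pos <- M > 0
  if (!any(pos)) stop("degenerate image: no positive pixels; cannot register",
                      call. = FALSE)
  L <- log1p(M / mean(M[pos]))
  (L - mean(L)) / stats::sd(L)
}

# affine map of pixel coords (rows r, cols c) about the image centre:
# theta = (t_r, t_c, log s_r, log s_c, rot)
affine_map <- function(r, c, theta, nr, nc) {
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  sr <- exp(theta[3])
  sc <- exp(theta[4])
  a <- theta[5]
  yr <- r - cr
  yc <- c - cc
  list(r = cr + theta[1] + sr * (cos(a) * yr - sin(a) * yc),
       c = cc + theta[2] + sc * (sin(a) * yr + cos(a) * yc))
}

ncc <- function(a, b) {
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# register one view: returns displacement field (full resolution, pixels) and
# quality metrics. fixed = patient counts, moving = atlas reference.
register_view <- function(fixed, moving, moving_labels, control) {
  f_full <- norm_image(fixed)
  m_full <- norm_image(moving)
  k <- control$coarse_factor
  f <- downsample_mean(f_full, k)
  m <- downsample_mean(m_full, k)
  nr <- nrow(f)
  nc <- ncol(f)
  grid_r <- matrix(seq_len(nr), nr, nc)
  grid_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  obj <- function(theta, fx, mv, rr, cc) {
    w <- affine_map(as.numeric(rr), as.numeric(cc), theta, nrow(fx), ncol(fx))
    -ncc(bilinear_sample(mv, w$r, w$c), as.numeric(fx))
  }

  # coarse grid search at an extra 2x downsampling, then Nelder-Mead refine
  f8 <- downsample_mean(f, 2L)
  m8 <- downsample_mean(m, 2L)
  g8r <- matrix(seq_len(nrow(f8)), nrow(f8), ncol(f8))
  g8c <- matrix(seq_len(ncol(f8)), nrow(f8), ncol(f8), byrow = TRUE)
  cand <- expand.grid(tr = c(-6, -3, 0, 3, 6), tc = c(-4, -2, 0, 2, 4),
                      ls = log(c(0.85, 0.925, 1, 1.075, 1.15)))
  sc <- vapply(seq_len(nrow(cand)), function(i)
    obj(c(cand$tr[i] / 2, cand$tc[i] / 2, cand$ls[i], cand$ls[i], 0),
        f8, m8, g8r, g8c), numeric(1))
  best <- cand[which.min(sc), ]
  theta0 <- c(best$tr, best$tc, best$ls, best$ls, 0)
  fit <- stats::optim(theta0, obj, fx = f, mv = m, rr = grid_r, cc = grid_c,
                      method = "Nelder-Mead",
                      control = list(maxit = control$affine_maxit))
  theta <- fit$par

  # demons refinement on top of the affine initialization
  aff <- affine_map(as.numeric(grid_r), as.numeric(grid_c), theta, nr, nc)
  # photometric match: z-normalization depends on body area, so regress the
  # affinely warped moving image onto the fixed one before taking residuals
  w0 <- bilinear_sample(m, aff$r, aff$c)
  b <- stats::cov(w0, as.numeric(f)) / max(stats::var(w0), 1e-12)
  a <- mean(f) - b * mean(w0)
  m <- a + b * m
  ur <- matrix(0, nr, nc)
  uc <- matrix(0, nr, nc)
  gfr <- (shift_mat(f, -1, 0, 0) - shift_mat(f, 1, 0, 0)) / 2
  gfc <- (shift_mat(f, 0, -1, 0) - shift_mat(f, 0, 1, 0)) / 2
  g2 <- gfr^2 + gfc^2
  for (it in seq_len(control$demons_iter)) {
    w <- bilinear_sample(m, aff$r + as.numeric(ur), aff$c + as.numeric(uc))
    resid <- w - as.numeric(f)
    denom <- as.numeric(g2) + resid^2 + 1e-6
    step_r <- -resid * as.numeric(gfr) / denom
    step_c <- -resid * as.numeric(gfc) / denom
    # cap per-iteration motion at one coarse pixel for stability
    step_r <- pmin(pmax(step_r, -1), 1)
    step_c <- pmin(pmax(step_c, -1), 1)
    ur <- gauss_smooth(ur + matrix(step_r, nr, nc), control$demons_sigma)
    uc <- gauss_smooth(uc + matrix(step_c, nr, nc), control$demons_sigma)
  }

  # total coarse-scale displacement (mapping minus identity), then upsample
  disp_r_coarse <- matrix(aff$r, nr, nc) + ur - grid_r
  disp_c_coarse <- matrix(aff$c, nr, nc) + uc - grid_c
  NR <- nrow(f_full)
  NC <- ncol(f_full)
  disp_r <- upsample_field(disp_r_coarse, k, NR, NC) * k
  disp_c <- upsample_field(disp_c_coarse, k, NR, NC) * k

  # Jacobian of the mapping p + u(p) at the coarse scale (cheap, smooth field)
  drr <- 1 + (shift_mat(disp_r_coarse, -1, 0) - shift_mat(disp_r_coarse, 1, 0)) / 2
  drc <- (shift_mat(disp_r_coarse, 0, -1) - shift_mat(disp_r_coarse, 0, 1)) / 2
  dcr <- (shift_mat(disp_c_coarse, -1, 0) - shift_mat(disp_c_coarse, 1, 0)) / 2
  dcc <- 1 + (shift_mat(disp_c_coarse, 0, -1) - shift_mat(disp_c_coarse, 0, 1)) / 2
  jac <- drr * dcc - drc * dcr
  interior <- c(2:(nr - 1))
  jac_pos <- mean(jac[interior, 2:(nc - 1)] > 0)

  # warp labels (nearest-neighbour) and reference (bilinear) to patient frame
  pr <- matrix(seq_len(NR), NR, NC) + disp_r
  pc <- matrix(seq_len(NC), NR, NC, byrow = TRUE) + disp_c
  labels <- matrix(nearest_sample(moving_labels, as.numeric(pr), as.numeric(pc)),
                   NR, NC)
  warped_ref <- matrix(bilinear_sample(m_full, as.numeric(pr), as.numeric(pc)),
                       NR, NC)
  skel <- labels > 0
  quality <- if (any(skel)) ncc(warped_ref[skel], f_full[skel]) else 0

  list(labels = labels, disp_r = disp_r, disp_c = disp_c,
       quality = quality, jacobian_positive = jac_pos, affine = theta)
}

#' Fit the skeletal atlas to a patient scan
#'
#' Registers the atlas reference to each view of a patient scintigram
#' (anterior to anterior, posterior to posterior) and warps the atlas label
#' template into the patient frame, yielding a per-pixel anatomical
#' segmentation. Registration is a global affine stage (translation, scale,
#' rotation, fitted by normalized cross-correlation on a coarse grid) followed
#' by a demons-style non-rigid refinement with Gaussian regularization.
#'
#' @param atlas a `skeletal_atlas` from [load_atlas()].
#' @param pair a `scintigram_pair`; `pair$sex` must match `atlas$sex`.
#' @param control a [register_control()].
#' @return a `segmentation_result`: per-view label matrices (`labels`),
#'   displacement fields (`displacement`, full-resolution row/col offsets in
#'   pixels), per-view registration `quality` (NCC), the fraction of pixels
#'   with positive warp Jacobian, the region table, and `flags` (e.g.
#'   `"low_quality_anterior"` when NCC falls below the control floor).
#' @export
register_atlas <- function(atlas, pair, control = register_control()) {
  stopifnot(inherits(atlas, "skeletal_atlas"), inherits(pair, "scintigram_pair"))
  if (!identical(atlas$sex, pair$sex))
    stop("atlas sex (", atlas$sex, ") does not match patient sex (", pair$sex, ")",
         call. = FALSE)
  views <- c("anterior", "posterior")
  fits <- lapply(views, function(v)
    register_view(pair[[v]], atlas$reference[[v]], atlas$labels[[v]], control))
  names(fits) <- views
  flags <- character(0)
  for (v in views) {
    if (fits[[v]]$quality < control$quality_floor)
      flags <- c(flags, paste0("low_quality_", v))
    if (fits[[v]]$jacobian_positive < 0.99)
      flags <- c(flags, paste0("folding_", v))
  }
  structure(list(
    labels = list(anterior = fits$anterior$labels, posterior = fits$posterior$labels),
    displacement = lapply(fits, function(f) list(row = f$disp_r, col = f$disp_c)),
    quality = vapply(fits, function(f) f$quality, numeric(1)),
    jacobian_positive = vapply(fits, function(f) f$jacobian_positive, numeric(1)),
    affine = lapply(fits, function(f) f$affine),
    regions = atlas$regions,
    sex = atlas$sex,
    flags = flags
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result (", x$sex, "): quality ant/post = ",
      round(x$quality[["anterior"]], 3), " / ", round(x$quality[["posterior"]], 3),
      if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

# Build a segmentation directly from phantom truth (the generator's own label
# maps). Used to isolate detection/classification from registration error and
# to provide ground-truth region labels when training classifiers.
#' Segmentation from phantom ground truth
#'
#' Wraps a phantom template's own label maps in a `segmentation_result`, for
#' analyses that need the true segmentation rather than a registered one.
#'
#' @param template a `phantom_template`.
#' @return a `segmentation_result` with zero displacement and quality 1.
#' @export
truth_segmentation <- function(template) {
  stopifnot(inherits(template, "phantom_template"))
  structure(list(
    labels = list(anterior = template$labels_anterior,
                  posterior = template$labels_posterior),
    displacement = NULL,
    quality = c(anterior = 1, posterior = 1),
    jacobian_positive = c(anterior = 1, posterior = 1),
    affine = NULL,
    regions = template$regions,
    sex = template$sex,
    flags = character(0)
  ), class = "segmentation_result")
}
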