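# Low-level raster primitives shared by the phantom, registration and
# detection code. Images are plain numeric matrices, nrow = image height
# (1024 rows), ncol = image width (256 columns); row 1 is the top of the
# field of view.

# Shift a matrix by (dr, dc), zero-filling the exposed border.
shift_mat <- function(M, dr, dc, fill = 0) {
  nr <- nrow(M)
  nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0L && length(cs) > 0L) out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

# Separable Gaussian smoothing by kernel-tap accumulation of shifted copies;
# `normalize` renormalizes by the smoothed indicator so that flat fields stay
# flat at the border (no zero-padding droop).
gauss_smooth <- function(M, sigma, normalize = TRUE) {
  if (sigma <= 0) return(M)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  taps <- stats::dnorm(-r:r, sd = sigma)
  taps <- taps / sum(taps)
  pass <- function(X, along_rows) {
    acc <- matrix(0, nrow(X), ncol(X))
    for (i in seq_along(taps)) {
      d <- (-r:r)[i]
      acc <- acc + taps[i] * if (along_rows) shift_mat(X, d, 0L) else shift_mat(X, 0L, d)
    }
    acc
  }
  out <- pass(pass(M, TRUE), FALSE)
  if (normalize) {
    ones <- matrix(1, nrow(M), ncol(M))
    w <- pass(pass(ones, TRUE), FALSE)
    out <- out / w
  }
  out
}

# Block-mean downsampling by an integer factor (trailing remainder cropped).
downsample_mean <- function(M, factor) {
  stopifnot(factor >= 1)
  if (factor == 1) return(M)
  nr <- (nrow(M) %/% factor) * factor
  nc <- (ncol(M) %/% factor) * factor
  M <- M[seq_len(nr), seq_len(nc), drop = FALSE]
  # fold rows, then columns
  rowf <- matrix(colMeans(matrix(M, nrow = factor)), nrow = nr %/% factor)
  t(matrix(colMeans(matrix(t(rowf), nrow = factor)), nrow = nc %/% factor))
}

# Bilinear sampling of M at (real-valued) row/column coordinates, clamped to
# the image domain.
bilinear_sample <- function(M, r, c) {
  nr <- nrow(M)
  nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  M[i00] * (1 - fr) * (1 - fc) + M[i00 + 1] * fr * (1 - fc) +
    M[i00 + nr] * (1 - fr) * fc + M[i00 + nr + 1] * fr * fc
}

# Nearest-neighbour sampling (used for label maps, which must not blend).
nearest_sample <- function(M, r, c, outside = 0L) {
  nr <- nrow(M)
  nc <- ncol(M)
  ri <- as.integer(round(r))
  ci <- as.integer(round(c))
  ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
  out <- rep(outside, length(r))
  out[ok] <- M[(ci[ok] - 1L) * nr + ri[ok]]
  out
}

# Bilinear upsampling of a coarse field to target dimensions, matching the
# block-mean downsampling geometry (coarse pixel i covers fine pixels
# (i-1)*f+1 .. i*f, centre at (i-0.5)*f + 0.5).
upsample_field <- function(M, factor, nrow_out, ncol_out) {
  rr <- (seq_len(nrow_out) - 0.5) / factor + 0.5
  cc <- (seq_len(ncol_out) - 0.5) / factor + 0.5
  grid_r <- matrix(rr, nrow_out, ncol_out)
  grid_c <- matrix(cc, nrow_out, ncol_out, byrow = TRUE)
  matrix(bilinear_sample(M, as.numeric(grid_r), as.numeric(grid_c)),
         nrow_out, ncol_out)
}

#' Label connected components of a binary mask
#'
#' Union-find connected-component labelling with 8- (default) or
#' 4-connectivity. Foreground pixels are the non-zero / `TRUE` entries.
#'
#' @param mask logical or numeric matrix; non-zero entries are foreground.
#' @param connectivity 8 (edges + diagonals) or 4 (edges only).
#' @return integer matrix of the same dimension; background pixels are 0 and
#'   each component carries a distinct positive label, numbered in
#'   column-major order of first occurrence.
#' @examples
#' m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
#' max(label_components(m))               # one 8-connected blob
#' max(label_components(m, connectivity = 4))  # two 4-connected blobs
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)

  pos <- integer(nr * nc)           # image index -> compact id (0 = background)
  pos[fg] <- seq_along(fg)
  parent <- seq_along(fg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  fr <- ((fg - 1L) %% nr) + 1L
  fc <- ((fg - 1L) %/% nr) + 1L
  for (off in offs) {
    r2 <- fr + off[1]
    c2 <- fc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    a <- which(ok)[nb > 0L]
    b <- nb[nb > 0L]
    for (j in seq_along(a)) {
      ra <- find(a[j])
      rb <- find(b[j])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(fg), find, integer(1))
  # fg is ascending, so unique() yields first-occurrence (column-major) order
  out[fg] <- match(roots, unique(roots))
  out
}

# Largest 8-connected piece of a pixel-index set (ties: first in label order).
largest_connected_subset <- function(px, nr) {
  if (length(px) <= 1L) return(px)
  pr <- ((px - 1L) %% nr) + 1L
  pc <- ((px - 1L) %/% nr) + 1L
  r0 <- min(pr) - 1L
  c0 <- min(pc) - 1L
  sub <- matrix(FALSE, max(pr) - r0, max(pc) - c0)
  sub[cbind(pr - r0, pc - c0)] <- TRUE
  lab <- label_components(sub, 8)
  keep <- which.max(tabulate(lab[lab > 0]))
  sel <- which(lab == keep)
  sr <- ((sel - 1L) %% nrow(sub)) + 1L + r0
  sc <- ((sel - 1L) %/% nrow(sub)) + 1L + c0
  sort((sc - 1L) * nr + sr)
}

# Pixel indices within a Euclidean disc around (r0, c0), intersected with the
# image domain.
disc_indices <- function(nr, nc, r0, c0, radius) {
  rs <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(r = rs, c = cs)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * nr + g$r[keep]
}
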