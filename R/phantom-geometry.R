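# Procedural 2D skeleton used both as the phantom body and as the atlas
# reference. All coordinates are "body coordinates": pixel units on the
# 1024 x 256 grid at stature_scale 1, x = column (1..256, midline 128.5),
# y = row (1..1024, head up). Stature scaling is a similarity transform about
# the body anchor, so a rescaled body is an exact affine warp of the
# reference -- a property the registration tests rely on.

IMG_NROW <- 1024L
IMG_NCOL <- 256L
BODY_ANCHOR <- c(x = 128.5, y = 512)

# similarity transform of body coords -> pixel coords at stature s
scale_pt <- function(x, y, s) {
  list(x = BODY_ANCHOR[["x"]] + s * (x - BODY_ANCHOR[["x"]]),
       y = BODY_ANCHOR[["y"]] + s * (y - BODY_ANCHOR[["y"]]))
}

# pixel indices of an axis-aligned ellipse, body coords
ellipse_idx <- function(cx, cy, ax, ay, s = 1) {
  p <- scale_pt(cx, cy, s)
  ax <- ax * s
  ay <- ay * s
  rs <- max(1L, floor(p$y - ay)):min(IMG_NROW, ceiling(p$y + ay))
  cs <- max(1L, floor(p$x - ax)):min(IMG_NCOL, ceiling(p$x + ax))
  g <- expand.grid(r = rs, c = cs)
  keep <- ((g$c - p$x) / ax)^2 + ((g$r - p$y) / ay)^2 <= 1
  as.integer((g$c[keep] - 1L) * IMG_NROW + g$r[keep])
}

# pixel indices of a capsule (segment with round caps), body coords
capsule_idx <- function(x1, y1, x2, y2, halfwidth, s = 1) {
  p1 <- scale_pt(x1, y1, s)
  p2 <- scale_pt(x2, y2, s)
  hw <- halfwidth * s
  rs <- max(1L, floor(min(p1$y, p2$y) - hw)):min(IMG_NROW, ceiling(max(p1$y, p2$y) + hw))
  cs <- max(1L, floor(min(p1$x, p2$x) - hw)):min(IMG_NCOL, ceiling(max(p1$x, p2$x) + hw))
  g <- expand.grid(r = rs, c = cs)
  dx <- p2$x - p1$x
  dy <- p2$y - p1$y
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, nrow(g)) else
    pmin(pmax(((g$c - p1$x) * dx + (g$r - p1$y) * dy) / len2, 0), 1)
  d2 <- (g$c - (p1$x + t * dx))^2 + (g$r - (p1$y + t * dy))^2
  keep <- d2 <= hw^2
  as.integer((g$c[keep] - 1L) * IMG_NROW + g$r[keep])
}

# Shape list per region. Sex differences: women get narrower shoulders and a
# wider pelvis; uptake differences live in the uptake table.
skeleton_shapes <- function(sex) {
  sh_off <- if (sex == "male") 52 else 48      # scapula lateral offset
  hu_off <- if (sex == "male") 77 else 72      # humerus lateral offset
  pe_off <- if (sex == "male") 31 else 35      # iliac wing offset
  pe_ax  <- if (sex == "male") 30 else 34
  mid <- 128.5

  rib_shapes <- function(side) {
    sgn <- if (side == "left") -1 else 1
    lapply(0:5, function(i) {
      list(kind = "capsule",
           x1 = mid + sgn * 14, y1 = 272 + 28 * i,
           x2 = mid + sgn * 72, y2 = 294 + 28 * i, hw = 4.5)
    })
  }

  list(
    skull = list(list(kind = "ellipse", cx = mid, cy = 145, ax = 36, ay = 46)),
    cervical_spine = list(list(kind = "capsule", x1 = mid, y1 = 195, x2 = mid, y2 = 255, hw = 9)),
    thoracic_spine = list(list(kind = "capsule", x1 = mid, y1 = 255, x2 = mid, y2 = 455, hw = 11)),
    lumbar_spine = list(list(kind = "capsule", x1 = mid, y1 = 455, x2 = mid, y2 = 565, hw = 14)),
    sternum = list(list(kind = "capsule", x1 = mid, y1 = 285, x2 = mid, y2 = 390, hw = 8)),
    clavicle_left = list(list(kind = "capsule", x1 = mid - 12, y1 = 262, x2 = mid - (hu_off - 14), y2 = 252, hw = 5)),
    clavicle_right = list(list(kind = "capsule", x1 = mid + 12, y1 = 262, x2 = mid + (hu_off - 14), y2 = 252, hw = 5)),
    scapula_left = list(list(kind = "ellipse", cx = mid - sh_off, cy = 310, ax = 20, ay = 38)),
    scapula_right = list(list(kind = "ellipse", cx = mid + sh_off, cy = 310, ax = 20, ay = 38)),
    ribs_left = rib_shapes("left"),
    ribs_right = rib_shapes("right"),
    humerus_left = list(list(kind = "capsule", x1 = mid - hu_off, y1 = 275, x2 = mid - (hu_off + 7), y2 = 470, hw = 9)),
    humerus_right = list(list(kind = "capsule", x1 = mid + hu_off, y1 = 275, x2 = mid + (hu_off + 7), y2 = 470, hw = 9)),
    pelvis = list(
      list(kind = "ellipse", cx = mid - pe_off, cy = 610, ax = pe_ax, ay = 45),
      list(kind = "ellipse", cx = mid + pe_off, cy = 610, ax = pe_ax, ay = 45),
      list(kind = "capsule", x1 = mid, y1 = 570, x2 = mid, y2 = 650, hw = 16)
    ),
    femur_left = list(list(kind = "capsule", x1 = mid - 38, y1 = 655, x2 = mid - 30, y2 = 900, hw = 11)),
    femur_right = list(list(kind = "capsule", x1 = mid + 38, y1 = 655, x2 = mid + 30, y2 = 900, hw = 11))
  )
}

shapes_to_idx <- function(shapes, s) {
  idx <- lapply(shapes, function(sh) {
    if (sh$kind == "ellipse") ellipse_idx(sh$cx, sh$cy, sh$ax, sh$ay, s)
    else capsule_idx(sh$x1, sh$y1, sh$x2, sh$y2, sh$hw, s)
  })
  sort(unique(unlist(idx)))
}

# soft-tissue body silhouette (not skeleton): head, torso, arms, legs
silhouette_idx <- function(sex, s) {
  mid <- 128.5
  hu_off <- if (sex == "male") 77 else 72
  parts <- c(
    list(ellipse_idx(mid, 145, 44, 54, s)),                      # head
    list(capsule_idx(mid, 190, mid, 260, 26, s)),                # neck
    list(ellipse_idx(mid, 440, 84, 215, s)),                     # torso
    list(ellipse_idx(mid, 625, 72, 85, s)),                      # hips
    list(capsule_idx(mid - hu_off, 268, mid - hu_off - 9, 500, 16, s)),  # arms
    list(capsule_idx(mid + hu_off, 268, mid + hu_off + 9, 500, 16, s)),
    list(capsule_idx(mid - 38, 650, mid - 28, 920, 22, s)),      # legs
    list(capsule_idx(mid + 38, 650, mid + 28, 920, 22, s))
  )
  sort(unique(unlist(parts)))
}

# physiological (non-skeletal) tracer pools: kidneys and bladder
physiology_blobs <- function(s) {
  mid <- 128.5
  list(
    list(idx = ellipse_idx(mid - 34, 505, 14, 22, s), anterior = 0.27, posterior = 0.90),
    list(idx = ellipse_idx(mid + 34, 505, 14, 22, s), anterior = 0.27, posterior = 0.90),
    list(idx = ellipse_idx(mid, 682, 11, 13, s), anterior = 1.00, posterior = 0.50)
  )
}

# candidate sites for benign degenerative lesions: joints and vertebral margins
benign_candidate_sites <- function(sex) {
  mid <- 128.5
  hu_off <- if (sex == "male") 77 else 72
  tibble::tibble(
    x = c(mid - hu_off, mid + hu_off,                     # shoulder joints
          mid - 9, mid + 9, mid - 9, mid + 9, mid - 9, mid + 9,   # thoracic margins
          mid - 12, mid + 12, mid - 12, mid + 12,          # lumbar margins
          mid - 16, mid + 16,                              # sacroiliac
          mid - (hu_off + 7), mid + (hu_off + 7),          # elbows
          mid - 30, mid + 30),                             # knees
    y = c(280, 280,
          320, 320, 380, 380, 430, 430,
          480, 480, 540, 540,
          595, 595,
          462, 462,
          893, 893),
    region = c("humerus_left", "humerus_right",
               "thoracic_spine", "thoracic_spine", "thoracic_spine", "thoracic_spine",
               "thoracic_spine", "thoracic_spine",
               "lumbar_spine", "lumbar_spine", "lumbar_spine", "lumbar_spine",
               "pelvis", "pelvis",
               "humerus_left", "humerus_right",
               "femur_left", "femur_right")
  )
}

# paint order per view: later regions overwrite earlier ones where shapes
# overlap in projection, so each view's label map favours the structures that
# view sees best (sternum/clavicles anteriorly, spine/scapulae posteriorly)
paint_order <- function(view) {
  if (view == "anterior") {
    c("scapula_left", "scapula_right", "cervical_spine", "thoracic_spine",
      "lumbar_spine", "ribs_left", "ribs_right", "humerus_left", "humerus_right",
      "pelvis", "femur_left", "femur_right", "skull",
      "clavicle_left", "clavicle_right", "sternum")
  } else {
    c("sternum", "clavicle_left", "clavicle_right", "humerus_left", "humerus_right",
      "ribs_left", "ribs_right", "scapula_left", "scapula_right", "skull",
      "pelvis", "femur_left", "femur_right",
      "cervical_spine", "thoracic_spine", "lumbar_spine")
  }
}

SOFT_TISSUE_UPTAKE <- 0.12
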