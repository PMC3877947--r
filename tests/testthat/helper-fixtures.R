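# shared small fixtures, built once per test run

fixture_atlas <- local({
  cache <- new.env(parent = emptyenv())
  function(sex = "male") {
    key <- sex
    if (!exists(key, envir = cache)) assign(key, load_atlas(sex), envir = cache)
    get(key, envir = cache)
  }
})

fixture_template <- local({
  cache <- new.env(parent = emptyenv())
  function(sex = "male", stature = 1) {
    key <- paste(sex, stature)
    if (!exists(key, envir = cache))
      assign(key, render_template(sex, stature), envir = cache)
    get(key, envir = cache)
  }
})

# brute-force flood-fill connected components (recursive oracle, small images)
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] != 0 && lab[r, c] == 0) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force O(n^2) AUC by concordant-pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force optimal cutoff: maximize sens - (1 - spec) over all thresholds,
# ties toward higher specificity
oracle_cutoff <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens - (1 - spec)
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

ann_example_tables <- function() {
  read_reclassification_table(
    system.file("extdata", "reclass_ann_example.csv", package = "bsiquant"),
    scheme = "ANN")
}

bsi_example_tables <- function() {
  read_reclassification_table(
    system.file("extdata", "reclass_bsi_example.csv", package = "bsiquant"),
    scheme = "BSI")
}
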