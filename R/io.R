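# Scintigram I/O: 16-bit portable graymap (PGM, P5/P2) per view plus a JSON
# metadata sidecar, and cohort/score-table readers for the statistics module.

write_pgm <- function(M, path, maxval = 65535L) {
  stopifnot(is.matrix(M), all(M >= 0), all(M <= maxval), all(M == round(M)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(M), nrow(M)), as.character(maxval)), con)
  vals <- as.integer(t(M))                       # raster order: rows top-down
  if (maxval > 255) {
    writeBin(as.raw(c(rbind(vals %/% 256L, vals %% 256L))), con)  # big-endian
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header: magic, width, height, maxval; '#' starts a comment to end of line
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("unreadable PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      word <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
        word <- paste0(word, ch)
      }
      tok <- c(tok, word)
    }
  }
  magic <- tok[1]
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic ", magic, "): ", path, call. = FALSE)
  w <- as.integer(tok[2])
  h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255) {
      raw2 <- readBin(con, "raw", 2L * n)
      if (length(raw2) < 2L * n) stop("truncated PGM: ", path, call. = FALSE)
      ints <- as.integer(raw2)
      vals <- ints[seq(1, 2 * n, 2)] * 256L + ints[seq(2, 2 * n, 2)]
    } else {
      vals <- as.integer(readBin(con, "raw", n))
      if (length(vals) < n) stop("truncated PGM: ", path, call. = FALSE)
    }
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (maxval <= 255)
    warning("8-bit PGM promoted to 16-bit counts: ", basename(path), call. = FALSE)
  list(image = t(matrix(vals, nrow = w)), maxval = maxval)   # back to R layout
}

#' Write a scintigram pair to disk
#'
#' Two 16-bit binary PGM rasters (one per view) plus a JSON metadata sidecar
#' (`sex`, pixel spacing, free-form annotations). Round-trips bit-exactly
#' through [read_scintigram()].
#'
#' @param pair a `scintigram_pair`.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<stem>_anterior.pgm`,
#'   `<stem>_posterior.pgm`, `<stem>_meta.json`.
#' @return invisible named vector of the three paths.
#' @export
write_scintigram <- function(pair, dir, basename = "scan") {
  stopifnot(inherits(pair, "scintigram_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(anterior = file.path(dir, paste0(basename, "_anterior.pgm")),
             posterior = file.path(dir, paste0(basename, "_posterior.pgm")),
             meta = file.path(dir, paste0(basename, "_meta.json")))
  write_pgm(pair$anterior, paths[["anterior"]])
  write_pgm(pair$posterior, paths[["posterior"]])
  jsonlite::write_json(list(sex = pair$sex,
                            pixel_spacing_mm = pair$pixel_spacing_mm,
                            meta = pair$meta),
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a scintigram pair
#'
#' Reads two 16-bit (or 8-bit, promoted with a warning) PGM rasters and
#' validates the 256 x 1024 acquisition matrix. Pass the metadata JSON written
#' by [write_scintigram()] as `meta`, or give `sex` explicitly.
#'
#' @param anterior,posterior PGM paths.
#' @param sex patient sex, required when `meta` is absent.
#' @param meta optional metadata JSON path.
#' @param allow_any_dims keep images whose dimensions differ from the
#'   256 x 1024 acquisition matrix (otherwise a dimension error).
#' @return a `scintigram_pair`.
#' @export
read_scintigram <- function(anterior, posterior, sex = NULL, meta = NULL,
                            allow_any_dims = FALSE) {
  a <- read_pgm(anterior)
  p <- read_pgm(posterior)
  md <- if (!is.null(meta)) jsonlite::read_json(meta, simplifyVector = TRUE) else NULL
  if (is.null(sex)) sex <- md$sex
  if (is.null(sex)) stop("sex is required (argument or metadata)", call. = FALSE)
  for (img in list(a$image, p$image)) {
    if (!identical(dim(img), c(IMG_NROW, IMG_NCOL)) && !allow_any_dims)
      stop("image is ", dim(img)[2], " x ", dim(img)[1],
           "; expected 256 x 1024 (use allow_any_dims to override)",
           call. = FALSE)
  }
  if (allow_any_dims) {
    return(structure(list(anterior = a$image, posterior = p$image, sex = sex,
                          pixel_spacing_mm = md$pixel_spacing_mm %||% 2.2,
                          meta = md$meta %||% list()),
                     class = "scintigram_pair"))
  }
  new_scintigram_pair(a$image, p$image, sex = sex,
                      pixel_spacing_mm = md$pixel_spacing_mm %||% 2.2,
                      meta = if (is.null(md$meta)) list() else md$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scored cohort table
#'
#' CSV with one row per patient: an outcome column (values
#' `metastasis`/`no_metastasis` or 1/0) and one or more score columns.
#'
#' @param path CSV path.
#' @param label name of the outcome column.
#' @return tibble.
#' @export
read_cohort <- function(path, label = "label") {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!label %in% names(df))
    stop("cohort file lacks outcome column '", label, "'", call. = FALSE)
  check_binary_labels(df[[label]])
  df
}

#' Write phantom ground truth as JSON
#'
#' @param truth lesion truth tibble from [generate_phantom()].
#' @param path output JSON path.
#' @return invisible `path`.
#' @export
write_truth <- function(truth, path) {
  recs <- purrr::map(seq_len(nrow(truth)), function(i) {
    r <- as.list(truth[i, setdiff(names(truth), "mask")])
    r$mask <- truth$mask[[i]]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
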