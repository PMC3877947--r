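# Per-region, sex-specific hot-spot classifiers: a single-hidden-layer
# network (8 sigmoidal units, logistic output) per anatomical region, trained
# on featurized hot spots with per-feature standardization frozen at training
# time. Regions with too few training lesions fall back to pooled
# axial/appendicular classifiers.

region_group <- function(region) {
  ifelse(region %in% c("humerus_left", "humerus_right", "femur_left", "femur_right"),
         "appendicular", "axial")
}

#' Train a hot-spot classifier for one region
#'
#' Fits a single-hidden-layer neural network (logistic output, cross-entropy
#' loss, weight decay) to labelled hot-spot feature vectors. Features are
#' standardized with statistics frozen into the classifier. Deterministic
#' under a fixed seed.
#'
#' @param training data frame with the [feature_names()] columns and a `label`
#'   column with values `"metastatic"` / `"non_metastatic"`.
#' @param region region identifier (or a pooled group name).
#' @param sex `"male"` or `"female"`.
#' @param seed integer seed for weight initialization.
#' @param size hidden units.
#' @param maxit training iterations.
#' @param decay L2 weight decay.
#' @param min_per_class minimum examples required per class.
#' @return a `region_classifier`.
#' @export
train_region_classifier <- function(training, region, sex, seed = 1L,
                                    size = 8L, maxit = 300L, decay = 1e-3,
                                    min_per_class = 10L) {
  feats <- feature_names()
  missing_cols <- setdiff(c(feats, "label"), names(training))
  if (length(missing_cols))
    stop("training set lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- training$label
  if (!all(y %in% c("metastatic", "non_metastatic")))
    stop("labels must be 'metastatic' or 'non_metastatic'", call. = FALSE)
  counts <- table(factor(y, levels = c("metastatic", "non_metastatic")))
  if (any(counts == 0))
    stop("single-class training set for region '", region,
         "' (", sex, "): need both classes", call. = FALSE)
  if (any(counts < min_per_class))
    stop("region '", region, "' (", sex, "): fewer than ", min_per_class,
         " examples in class ", names(counts)[which.min(counts)], call. = FALSE)

  X <- as.matrix(training[, feats])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  yn <- as.numeric(y == "metastatic")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- nnet::nnet(Xs, yn, size = size, entropy = TRUE, decay = decay,
                    maxit = maxit, trace = FALSE)
  structure(list(
    region = region, sex = sex,
    wts = fit$wts, n = c(ncol(Xs), size, 1L),
    feature_names = feats, center = mu, scale = sc,
    meta = list(seed = seed, maxit = maxit, decay = decay,
                n_train = nrow(training),
                n_metastatic = unname(counts[["metastatic"]]),
                final_loss = fit$value)
  ), class = "region_classifier")
}

#' @export
print.region_classifier <- function(x, ...) {
  cat("region_classifier: ", x$sex, "/", x$region, " (", x$meta$n_train,
      " examples, ", x$meta$n_metastatic, " metastatic)\n", sep = "")
  invisible(x)
}

# forward pass through the stored single-hidden-layer weights (nnet layout:
# per hidden unit [bias, w_1..w_p], then output [bias, v_1..v_h])
nn_forward <- function(clf, X) {
  p <- clf$n[1]
  h <- clf$n[2]
  W <- matrix(clf$wts[seq_len((p + 1) * h)], nrow = p + 1)
  vout <- clf$wts[(p + 1) * h + seq_len(h + 1)]
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(cbind(1, X) %*% W)
  as.numeric(sig(cbind(1, H) %*% vout))
}

#' Classify hot spots with a region classifier
#'
#' @param classifier a `region_classifier`.
#' @param features data frame (or single named vector) carrying the
#'   classifier's feature columns.
#' @return numeric vector of metastasis probabilities in `[0, 1]`.
#' @export
classify_hotspot <- function(classifier, features) {
  stopifnot(inherits(classifier, "region_classifier"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- tibble::as_tibble(as.list(features))
  miss <- setdiff(classifier$feature_names, names(features))
  if (length(miss))
    stop("feature schema mismatch: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(features[, classifier$feature_names])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  Xs <- sweep(sweep(X, 2, classifier$center), 2, classifier$scale, "/")
  p <- nn_forward(classifier, Xs)
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' Train the full classifier registry from labelled hot spots
#'
#' Trains one classifier per (sex, region) that has at least `min_per_class`
#' hot spots in each class; sparser regions fall back to pooled axial or
#' appendicular classifiers trained on all hot spots of that skeletal
#' division (and, as a last resort, to a whole-skeleton classifier per sex).
#' Male and female registries are disjoint.
#'
#' @param training data frame of featurized hot spots with `sex`, `region`,
#'   `label` and the [feature_names()] columns.
#' @param seed integer seed.
#' @param min_per_class minimum per-class examples for a region-specific net.
#' @return a `classifier_registry`.
#' @export
train_classifiers <- function(training, seed = 1L, min_per_class = 10L) {
  stopifnot(all(c("sex", "region", "label") %in% names(training)))
  registry <- list()
  log <- list()
  for (sx in sort(unique(training$sex))) {
    dat <- training[training$sex == sx, ]
    models <- list()
    pooled <- list()
    for (grp in c("axial", "appendicular", "skeleton")) {
      sub <- if (grp == "skeleton") dat else dat[region_group(dat$region) == grp, ]
      ok <- nrow(sub) > 0 &&
        all(table(factor(sub$label, levels = c("metastatic", "non_metastatic"))) >= min_per_class)
      if (ok) pooled[[grp]] <- train_region_classifier(sub, grp, sx, seed = seed,
                                                       min_per_class = min_per_class)
    }
    for (rg in sort(unique(dat$region))) {
      sub <- dat[dat$region == rg, ]
      tab <- table(factor(sub$label, levels = c("metastatic", "non_metastatic")))
      if (all(tab >= min_per_class)) {
        models[[rg]] <- train_region_classifier(sub, rg, sx, seed = seed,
                                                min_per_class = min_per_class)
      } else {
        log[[length(log) + 1L]] <- tibble::tibble(
          sex = sx, region = rg, n_metastatic = unname(tab[1]),
          n_non_metastatic = unname(tab[2]),
          fallback = region_group(rg))
      }
    }
    registry[[sx]] <- list(models = models, pooled = pooled)
  }
  structure(list(by_sex = registry,
                 fallback_log = if (length(log)) dplyr::bind_rows(log) else NULL,
                 seed = seed),
            class = "classifier_registry")
}

#' @export
print.classifier_registry <- function(x, ...) {
  for (sx in names(x$by_sex)) {
    cat(sx, ": ", length(x$by_sex[[sx]]$models), " region classifiers, pooled: ",
        paste(names(x$by_sex[[sx]]$pooled), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$fallback_log))
    cat(nrow(x$fallback_log), "region(s) using pooled fallback\n")
  invisible(x)
}

# resolve the classifier for one (sex, region)
lookup_classifier <- function(registry, sex, region) {
  stopifnot(inherits(registry, "classifier_registry"))
  entry <- registry$by_sex[[sex]]
  if (is.null(entry))
    stop("no classifiers trained for sex '", sex, "'", call. = FALSE)
  clf <- entry$models[[region]]
  if (is.null(clf)) clf <- entry$pooled[[region_group(region)]]
  if (is.null(clf)) clf <- entry$pooled[["skeleton"]]
  if (is.null(clf))
    stop("no classifier available for ", sex, "/", region, call. = FALSE)
  clf
}

#' Score a table of hot spots
#'
#' Adds a metastasis `probability` column to a featurized hot-spot table,
#' dispatching each hot spot to its region's classifier (with pooled
#' fallback).
#'
#' @param hotspots tibble from [extract_features()] / [detect_scan()].
#' @param registry a `classifier_registry`.
#' @param sex patient sex; must be present in the registry.
#' @return `hotspots` with a `probability` column.
#' @export
classify_hotspots <- function(hotspots, registry, sex) {
  if (nrow(hotspots) == 0L)
    return(dplyr::mutate(hotspots, probability = numeric(0)))
  probs <- vapply(seq_len(nrow(hotspots)), function(i) {
    clf <- lookup_classifier(registry, sex, hotspots$region[i])
    classify_hotspot(clf, hotspots[i, ])
  }, numeric(1))
  dplyr::mutate(hotspots, probability = probs)
}

#' Patient-level abnormality score
#'
#' Aggregates hot-spot metastasis probabilities into one patient-level value:
#' the maximum probability (a patient is abnormal if any single hot spot is),
#' 0 when there are no hot spots.
#'
#' @param probabilities numeric vector of per-hot-spot probabilities.
#' @return value in `[0, 1]`.
#' @examples
#' patient_ann_value(c(0.2, 0.9, 0.4))  # 0.9
#' patient_ann_value(numeric(0))        # 0
#' @export
patient_ann_value <- function(probabilities) {
  if (length(probabilities) == 0L) return(0)
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  max(probabilities)
}

#' Save / load a classifier registry as a JSON bundle
#'
#' @param registry a `classifier_registry`.
#' @param path file path for the JSON bundle.
#' @return `save_classifier_bundle` returns `path` invisibly;
#'   `load_classifier_bundle` returns the restored `classifier_registry`.
#' @export
save_classifier_bundle <- function(registry, path) {
  stopifnot(inherits(registry, "classifier_registry"))
  ser_clf <- function(clf) {
    clf <- unclass(clf)
    clf$wts <- as.numeric(clf$wts)
    clf
  }
  payload <- list(
    format = "bsiquant-classifier-bundle",
    version = 1L,
    seed = registry$seed,
    by_sex = lapply(registry$by_sex, function(e) list(
      models = lapply(e$models, ser_clf),
      pooled = lapply(e$pooled, ser_clf)
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier_bundle
#' @export
load_classifier_bundle <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "bsiquant-classifier-bundle"))
    stop("not a classifier bundle: ", path, call. = FALSE)
  de_clf <- function(l) {
    l$wts <- as.numeric(l$wts)
    l$n <- as.integer(l$n)
    l$center <- stats::setNames(as.numeric(l$center), l$feature_names)
    l$scale <- stats::setNames(as.numeric(l$scale), l$feature_names)
    structure(l, class = "region_classifier")
  }
  by_sex <- lapply(payload$by_sex, function(e) list(
    models = lapply(e$models, de_clf),
    pooled = lapply(e$pooled, de_clf)
  ))
  structure(list(by_sex = by_sex, fallback_log = NULL,
                 seed = payload$seed),
            class = "classifier_registry")
}
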