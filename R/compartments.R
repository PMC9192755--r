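## Tumor-vs-stroma cell classification learned from analyst-circled training
## polygons, with inclusion/exclusion annotation handling. Precedence is
## exclude > train > include, centroid-based, even-odd rule, strictly inside.

polygons_with_role <- function(annotations, role)
  Filter(function(p) p$role == role, annotations$polygons)

in_any_polygon <- function(x, y, polys) {
  hit <- rep(FALSE, length(x))
  for (p in polys) hit <- hit | points_in_polygon(x, y, p$coords)
  hit
}

#' Harvest labeled training cells from annotation polygons
#'
#' Cells whose centroid falls strictly inside a `train_tumor` /
#' `train_stroma` polygon are labeled with that compartment; cells inside
#' any `exclude` polygon are dropped first (exclusion wins over training).
#'
#' @param cells table from [build_cells()].
#' @param annotations an [annotation_set()] with at least one polygon of
#'   each training role.
#' @return the labeled subset of `cells` with a `label` factor column
#'   (levels tumor, stroma).
#' @export
harvest_training_cells <- function(cells, annotations) {
  tt <- polygons_with_role(annotations, "train_tumor")
  ts <- polygons_with_role(annotations, "train_stroma")
  if (length(tt) == 0 || length(ts) == 0)
    stop("need at least one train_tumor and one train_stroma polygon")
  excl <- in_any_polygon(cells$x, cells$y,
                         polygons_with_role(annotations, "exclude"))
  in_t <- in_any_polygon(cells$x, cells$y, tt) & !excl
  in_s <- in_any_polygon(cells$x, cells$y, ts) & !excl
  a <- cells[in_t & !in_s, , drop = FALSE]
  b <- cells[in_s & !in_t, , drop = FALSE]
  a$label <- rep("tumor", nrow(a))
  b$label <- rep("stroma", nrow(b))
  out <- rbind(a, b)
  if (sum(out$label == "tumor") == 0)
    stop("no tumor cells harvested from training polygons")
  if (sum(out$label == "stroma") == 0)
    stop("no stroma cells harvested from training polygons")
  out$label <- factor(out$label, levels = c("tumor", "stroma"))
  out
}

fit_classifier <- function(x, y, family, seed) {
  set.seed(seed)
  if (family == "rf") {
    ## stratified balanced sampling: rare classes (immune cells) would
    ## otherwise be under-called at the 0.5 vote threshold
    nmin <- min(table(y))
    randomForest::randomForest(x, y, ntree = 200, strata = y,
                               sampsize = rep(nmin, nlevels(y)))
  } else if (family == "lda") {
    MASS::lda(x, grouping = y, prior = rep(1 / nlevels(y), nlevels(y)))
  } else if (family == "glm") {
    df <- data.frame(x, .y = y)
    ## separable training data provokes harmless convergence warnings
    suppressWarnings(stats::glm(.y ~ ., data = df,
                                family = stats::binomial()))
  } else if (family == "constant") {
    structure(list(level = levels(y)[1]), class = "constant_classifier")
  } else stop("unknown classifier family: ", family)
}

predict_classifier <- function(model, x, family, levels) {
  if (family == "rf") {
    ## vote fractions with a fixed tie rule: class-label prediction would
    ## break ties through the RNG, making inference state-dependent
    pr <- stats::predict(model, x, type = "prob")
    colnames(pr)[max.col(pr, ties.method = "first")]
  } else if (family == "lda") {
    as.character(stats::predict(model, x)$class)
  } else if (family == "glm") {
    p <- stats::predict(model, newdata = data.frame(x), type = "response")
    levels[1 + (p > 0.5)]
  } else if (family == "constant") {
    rep(model$level, nrow(x))
  } else stop("unknown classifier family: ", family)
}

#' Fit the tumor/stroma compartment model
#'
#' Fits the configured classifier family on the harvested feature table,
#' reporting held-out accuracy from a stratified 70/30 split before
#' refitting on all rows. Deterministic given the seed.
#'
#' @param labeled output of [harvest_training_cells()].
#' @param seed RNG seed.
#' @param family classifier family: `"rf"` (random forest, default),
#'   `"lda"` or `"glm"`.
#' @param min_per_class minimum training cells per class.
#' @return object of class `compartment_model`.
#' @export
fit_compartment_model <- function(labeled, seed = 1L, family = "rf",
                                  min_per_class = 20L) {
  counts <- table(labeled$label)
  if (length(counts) < 2 || any(counts < min_per_class))
    stop("class starvation: need >= ", min_per_class,
         " cells per class, got ", paste(counts, collapse = "/"))
  x <- as.matrix(labeled[, FEATURE_NAMES])
  y <- labeled$label
  set.seed(seed)
  hold <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1, round(0.3 * length(ix))))))
  m0 <- fit_classifier(x[-hold, , drop = FALSE], droplevels(y[-hold]),
                       family, seed)
  acc <- mean(predict_classifier(m0, x[hold, , drop = FALSE], family,
                                 levels(y)) == as.character(y[hold]))
  final <- fit_classifier(x, y, family, seed)
  structure(list(classifier = final, family = family,
                 feature_hash = feature_hash(),
                 holdout_accuracy = acc,
                 n_per_class = as.integer(counts), seed = as.integer(seed)),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("compartment_model (%s): %s cells/class, held-out accuracy %.3f\n",
              x$family, paste(x$n_per_class, collapse = "/"),
              x$holdout_accuracy))
  invisible(x)
}

#' Assign compartments to all cells
#'
#' Cells outside every inclusion polygon or inside any exclusion polygon are
#' marked `excluded`; the rest are classified tumor or stroma by the model.
#' With `annotations = NULL` the whole frame is included.
#'
#' @param cells table from [build_cells()].
#' @param model a fitted [fit_compartment_model()].
#' @param annotations optional [annotation_set()].
#' @return `cells` with the `compartment` column set.
#' @export
assign_compartments <- function(cells, model, annotations = NULL) {
  if (!inherits(model, "compartment_model"))
    stop("model is not a fitted compartment_model")
  if (!identical(model$feature_hash, feature_hash()))
    stop("feature order hash mismatch between model and cell table")
  if (nrow(cells) == 0) return(cells)
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(annotations)) {
    inc <- polygons_with_role(annotations, "include")
    if (length(inc) > 0)
      keep <- in_any_polygon(cells$x, cells$y, inc)
    keep <- keep & !in_any_polygon(cells$x, cells$y,
                                   polygons_with_role(annotations, "exclude"))
  }
  pred <- predict_classifier(model$classifier,
                             as.matrix(cells[, FEATURE_NAMES]),
                             model$family, c("tumor", "stroma"))
  cells$compartment <- ifelse(keep, pred, "excluded")
  cells
}
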