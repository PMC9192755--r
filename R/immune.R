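## Macrophage and lymphocyte recognition: blob detection in dual-IF images,
## rigid co-registration of IF to brightfield coordinates, cell-to-cell label
## transfer, model selection against a verification set, and deployment on
## PD-L1 slides with per-cell PD-L1 status retained.

#' Detect stained blobs in an IF channel
#'
#' Local-maximum detection on the lightly smoothed channel: a pixel is a
#' blob centre if it is the maximum of its 5x5 neighbourhood and exceeds the
#' intensity threshold (an Otsu-style split would land between the additive
#' background and the blob amplitudes; a fixed floor is used because the
#' synthetic background is calibrated well below it).
#'
#' @param if_img an `if_image`.
#' @param channel marker name (e.g. `"CD68"`) or `"both"` for the
#'   de-duplicated union of the two channels.
#' @param threshold minimum blob intensity.
#' @param dedup_dist blobs from the two channels closer than this (px) are
#'   merged (double-positive cells count once).
#' @return data frame with `x`, `y`, `intensity`, `channel`.
#' @export
if_blobs <- function(if_img, channel = "both", threshold = 0.15,
                     dedup_dist = 3) {
  stopifnot(inherits(if_img, "if_image"))
  detect_one <- function(mk) {
    ch <- if_img$channels[[mk]]
    img <- EBImage::Image(t(ch))
    sm <- EBImage::gblur(img, sigma = 1)
    mx <- EBImage::dilate(sm, EBImage::makeBrush(5, shape = "box"))
    peaks <- which(EBImage::imageData(sm) >= EBImage::imageData(mx) - 1e-9 &
                     EBImage::imageData(sm) > threshold, arr.ind = TRUE)
    if (nrow(peaks) == 0)
      return(data.frame(x = numeric(), y = numeric(),
                        intensity = numeric(), channel = character()))
    df <- data.frame(x = peaks[, 1] - 1, y = peaks[, 2] - 1,  # [x, y] layout
                     intensity = EBImage::imageData(sm)[peaks],
                     channel = mk)
    ## collapse plateau peaks within 2 px
    keep <- rep(TRUE, nrow(df))
    o <- order(-df$intensity)
    for (i in o) {
      if (!keep[i]) next
      close <- keep & abs(df$x - df$x[i]) <= 2 & abs(df$y - df$y[i]) <= 2
      close[i] <- FALSE
      keep[close & df$intensity <= df$intensity[i]] <- FALSE
    }
    df[keep, , drop = FALSE]
  }
  if (channel %in% if_img$markers) return(detect_one(channel))
  if (channel != "both")
    stop("unknown channel '", channel, "'; available: ",
         paste(c(if_img$markers, "both"), collapse = ", "))
  a <- detect_one(if_img$markers[1])
  b <- detect_one(if_img$markers[2])
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  m <- match_points(a[, c("x", "y")], b[, c("x", "y")], max_dist = dedup_dist)
  dup_b <- if (nrow(m$pairs) > 0) m$pairs[, 2] else integer()
  out <- rbind(a, b[setdiff(seq_len(nrow(b)), dup_b), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Count stain-identified cells in an IF image
#'
#' The de-duplicated union across the two channels is the "stain-identified"
#' ground-truth count used in the accuracy statistics.
#'
#' @inheritParams if_blobs
#' @return integer count.
#' @export
count_if_positive_cells <- function(if_img, channel = "both",
                                    threshold = 0.15) {
  nrow(if_blobs(if_img, channel, threshold))
}

## Coarse translation between two point sets via cross-correlation of
## Gaussian-smoothed density rasters (bin = 4 px). The search is restricted
## to shifts below max_frac of the image extent: serial-section mounting
## offsets are small, and an unrestricted search can lock a sparse marker
## distribution onto an unrelated dense region.
coarse_translation <- function(from, to, width, height, bin = 4,
                               max_frac = 0.15) {
  nx <- ceiling(width / bin); ny <- ceiling(height / bin)
  rasterize <- function(p) {
    m <- matrix(0, ny, nx)
    ix <- pmin(pmax(floor(p[, 1] / bin) + 1, 1), nx)
    iy <- pmin(pmax(floor(p[, 2] / bin) + 1, 1), ny)
    for (k in seq_len(nrow(p))) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
    t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = 1.5)))
  }
  A <- rasterize(from); B <- rasterize(to)
  cc <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(A)), inverse = TRUE))
  sy_all <- c(0:(ny - 1)); sy_all[sy_all > ny / 2] <- sy_all[sy_all > ny / 2] - ny
  sx_all <- c(0:(nx - 1)); sx_all[sx_all > nx / 2] <- sx_all[sx_all > nx / 2] - nx
  lim_y <- max_frac * height / bin; lim_x <- max_frac * width / bin
  cc[abs(sy_all) > lim_y, ] <- -Inf
  cc[, abs(sx_all) > lim_x] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sy <- unname(pk[1]) - 1; sx <- unname(pk[2]) - 1
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  c(dx = sx * bin, dy = sy * bin)
}

## Optimal rigid alignment (Kabsch) of paired points: returns R, t with
## q ~= R p + t.
kabsch2d <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- t(sweep(p, 2, cp)) %*% sweep(q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

#' Register an IF image to brightfield cell coordinates
#'
#' Fine cell-to-cell alignment: blob centroids are extracted from the IF
#' image, a coarse translation is found by cross-correlation of density
#' maps, and the transform is refined by trimmed iterative-closest-point
#' with a closed-form rigid update. The result maps IF coordinates into
#' brightfield coordinates.
#'
#' @param if_img an `if_image`.
#' @param bf_cells brightfield cell table (uses `x`, `y`).
#' @param max_residual mean matched-point distance (px) above which the
#'   registration is declared failed.
#' @return a [rigid_transform()] (rotation expressed about the image
#'   centre) with the achieved `residual`.
#' @export
register_if_to_brightfield <- function(if_img, bf_cells, max_residual = 3) {
  blobs <- if_blobs(if_img, "both")
  if (nrow(blobs) < 10)
    stop("need >= 10 detectable IF blobs for registration, got ", nrow(blobs))
  p <- as.matrix(blobs[, c("x", "y")])          # IF
  q <- as.matrix(bf_cells[, c("x", "y")])       # brightfield
  sh <- coarse_translation(p, q, if_img$width, if_img$height)
  R <- diag(2); tvec <- unname(c(sh["dx"], sh["dy"]))
  trim <- c(20, 15, 12, 10, rep(8, 4), rep(6, 8))
  res <- NA_real_
  for (it in seq_along(trim)) {
    pt <- sweep(p %*% t(R), 2, tvec, "+")
    d2 <- outer(pt[, 1], q[, 1], "-")^2 + outer(pt[, 2], q[, 2], "-")^2
    nn <- apply(d2, 1, which.min)
    dist <- sqrt(d2[cbind(seq_len(nrow(pt)), nn)])
    sel <- dist <= trim[it]
    if (sum(sel) < 5) next
    kb <- kabsch2d(p[sel, , drop = FALSE], q[nn[sel], , drop = FALSE])
    R <- kb$R; tvec <- kb$t
    res <- mean(dist[sel])
  }
  if (!is.finite(res) || res > max_residual)
    stop(sprintf("registration failed to converge: residual %.2f px exceeds %.2f",
                 res, max_residual))
  ## express as rotation about the image centre
  theta <- atan2(R[2, 1], R[1, 1])
  ctr <- c((if_img$width - 1) / 2, (if_img$height - 1) / 2)
  shift <- as.numeric(R %*% ctr) + tvec - ctr
  rigid_transform(dx = shift[1], dy = shift[2], rotation = theta,
                  centre = ctr, residual = res)
}

#' Match brightfield cells to IF blobs one-to-one
#'
#' Mutual-nearest-neighbour pairing after mapping IF blobs into brightfield
#' coordinates.
#'
#' @param bf_cells brightfield cell table.
#' @param blobs data frame from [if_blobs()].
#' @param transform IF-to-brightfield [rigid_transform()].
#' @param max_dist maximum pair distance in pixels.
#' @return list with `pairs` (data frame `cell_id`, `blob`),
#'   `unmatched_cells` (cell ids), `unmatched_blobs` (blob row indices).
#' @export
match_cells <- function(bf_cells, blobs, transform = rigid_transform(),
                        max_dist = 6) {
  pb <- if (nrow(blobs) > 0)
    apply_transform(transform, as.matrix(blobs[, c("x", "y")]))
  else matrix(numeric(), 0, 2)
  m <- match_points(as.matrix(bf_cells[, c("x", "y")]), pb, max_dist)
  pairs <- data.frame(cell_id = bf_cells$cell_id[m$pairs[, 1]],
                      blob = m$pairs[, 2])
  list(pairs = pairs,
       unmatched_cells = bf_cells$cell_id[m$unmatched_a],
       unmatched_blobs = m$unmatched_b)
}

#' Build an immune training table by IF label transfer
#'
#' Under the macrophage panel, brightfield cells matched to a CD68 or CD163
#' blob are labeled `macrophage` and all others `other`; the lymphocyte
#' panel labels CD3/CD20-matched cells `lymphocyte`. Labels attach to the
#' brightfield feature vectors.
#'
#' @param cells brightfield cell table.
#' @param matching output of [match_cells()].
#' @param panel `"CD68_CD163"` or `"CD3_CD20"`.
#' @return `cells` with a `label` factor column (positive class first).
#' @export
label_from_if <- function(cells, matching, panel = c("CD68_CD163", "CD3_CD20")) {
  panel <- match.arg(panel)
  positive <- if (panel == "CD68_CD163") "macrophage" else "lymphocyte"
  lab <- ifelse(cells$cell_id %in% matching$pairs$cell_id, positive, "other")
  cells$label <- factor(lab, levels = c(positive, "other"))
  cells
}

#' Run the full IF label-transfer path for one sample
#'
#' Convenience composition: detect cells on the brightfield slide (unless a
#' cell table is supplied), register the IF image, match cells to blobs and
#' attach transferred labels.
#'
#' @param img a [slide_image()] or an already-built cell table.
#' @param if_img the paired `if_image`.
#' @param panel `"CD68_CD163"` or `"CD3_CD20"`.
#' @param max_dist matching radius in pixels.
#' @return labeled cell table as from [label_from_if()].
#' @export
label_slide_from_if <- function(img, if_img, panel, max_dist = 6) {
  cells <- if (inherits(img, "slide_image")) {
    planes <- separate_stains(img)
    build_cells(planes, detect_nuclei(planes), slide_id = img$slide_id)
  } else img
  tf <- register_if_to_brightfield(if_img, cells)
  blobs <- if_blobs(if_img, "both")
  mm <- match_cells(cells, blobs, tf, max_dist = max_dist)
  label_from_if(cells, mm, panel)
}

predict_classifier_prob <- function(model, x, family, positive) {
  if (family == "rf") {
    stats::predict(model, x, type = "prob")[, positive]
  } else if (family == "lda") {
    stats::predict(model, x)$posterior[, positive]
  } else if (family == "glm") {
    ## glm models P(second level); positive class is the first level
    1 - stats::predict(model, newdata = data.frame(x), type = "response")
  } else if (family == "constant") {
    rep(as.numeric(model$level == positive), nrow(x))
  } else stop("unknown classifier family: ", family)
}

#' Fit an immune-cell classifier with model selection
#'
#' Each candidate family is fitted on the training table and scored on a
#' disjoint verification set by count agreement: the mean absolute percent
#' error between predicted and known cell counts. The most accurate
#' candidate is selected. If the training table carries a `subtype_label`
#' column (tissue/alveolar, available for macrophages from
#' pathologist-style annotation), a subtype head is fitted on the positive
#' rows.
#'
#' @param train labeled table from [label_from_if()].
#' @param verification list of `list(cells = <cell table>, true_count = n)`.
#' @param families candidate classifier families (>= 2), from
#'   `"rf"`, `"lda"`, `"glm"`, `"constant"`.
#' @param seed RNG seed (training determinism).
#' @return object of class `immune_model` with a `selection_report`.
#' @export
fit_immune_model <- function(train, verification,
                             families = c("rf", "lda"), seed = 1L) {
  if (length(families) < 2)
    stop("need at least 2 candidate families for model selection")
  if (length(verification) == 0) stop("verification set is empty")
  positive <- levels(train$label)[1]
  x <- as.matrix(train[, FEATURE_NAMES])
  y <- train$label
  report <- data.frame(family = families, count_ape = NA_real_)
  fits <- list()
  for (k in seq_along(families)) {
    fam <- families[k]
    fits[[fam]] <- fit_classifier(x, y, fam, seed)
    apes <- vapply(verification, function(v) {
      pred <- predict_classifier(fits[[fam]],
                                 as.matrix(v$cells[, FEATURE_NAMES]),
                                 fam, levels(y))
      n <- sum(pred == positive)
      100 * abs(n - v$true_count) / max(v$true_count, 1)
    }, numeric(1))
    report$count_ape[k] <- mean(apes)
  }
  best <- which.min(report$count_ape)
  sub <- NULL
  if ("subtype_label" %in% names(train)) {
    rows <- !is.na(train$subtype_label) & train$label == positive
    if (sum(rows) >= 10 && length(unique(train$subtype_label[rows])) == 2) {
      sub <- fit_classifier(as.matrix(train[rows, FEATURE_NAMES]),
                            factor(train$subtype_label[rows]), "rf", seed)
    }
  }
  structure(list(task = positive, classifier = fits[[best]],
                 family = families[best], selection_report = report,
                 subtype_classifier = sub, feature_hash = feature_hash(),
                 seed = as.integer(seed)),
            class = "immune_model")
}

#' @export
print.immune_model <- function(x, ...) {
  cat(sprintf("immune_model (%s): selected %s; verification count APE:\n",
              x$task, x$family))
  print(x$selection_report)
  invisible(x)
}

#' Predict immune cell classes on a PD-L1 slide
#'
#' Applies the macrophage and/or lymphocyte models to the cell table;
#' conflicts (both positive) resolve to the higher posterior. Macrophages
#' are sub-typed tissue/alveolar when the model carries a subtype head. The
#' `pdl1_bin` column is never touched, so PD-L1 +/- immune tallies remain
#' reportable.
#'
#' @param cells cell table with features (and typically `pdl1_bin` set).
#' @param models list with optional `macrophage` and `lymphocyte`
#'   `immune_model`s.
#' @return `cells` with `cell_class` (macrophage/lymphocyte/other) and
#'   `subtype` set.
#' @export
predict_immune_cells <- function(cells, models) {
  if (inherits(models, "immune_model")) {
    models <- stats::setNames(list(models), models$task)
  }
  x <- as.matrix(cells[, FEATURE_NAMES])
  prob <- matrix(0, nrow(cells), 2,
                 dimnames = list(NULL, c("macrophage", "lymphocyte")))
  for (task in c("macrophage", "lymphocyte")) {
    m <- models[[task]]
    if (is.null(m)) next
    if (!identical(m$feature_hash, feature_hash()))
      stop("feature order hash mismatch for ", task, " model")
    prob[, task] <- predict_classifier_prob(m$classifier, x, m$family, m$task)
  }
  cls <- rep("other", nrow(cells))
  best <- max.col(prob, ties.method = "first")
  bp <- prob[cbind(seq_len(nrow(cells)), best)]
  cls[bp >= 0.5] <- colnames(prob)[best[bp >= 0.5]]
  cells$cell_class <- cls
  cells$subtype <- NA_character_
  msub <- models$macrophage$subtype_classifier
  if (!is.null(msub) && any(cls == "macrophage")) {
    sel <- cls == "macrophage"
    cells$subtype[sel] <- as.character(
      stats::predict(msub, x[sel, , drop = FALSE]))
  }
  cells
}

#' Tabulate immune counts by class, compartment and PD-L1 status
#'
#' @param cells cell table after [predict_immune_cells()].
#' @return data frame of counts per (cell_class, compartment, pdl1_status).
#' @export
immune_counts <- function(cells) {
  df <- cells[!is.na(cells$cell_class), ]
  status <- ifelse(df$pdl1_bin >= 1, "pdl1_positive", "pdl1_negative")
  out <- as.data.frame(table(cell_class = df$cell_class,
                             compartment = df$compartment,
                             pdl1_status = status))
  names(out)[4] <- "n"
  out
}
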