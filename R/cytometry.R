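## Cell-level cytometry on brightfield IHC: color deconvolution into
## hematoxylin/DAB optical-density planes, nucleus detection by smoothing +
## thresholding + watershed, and extraction of the fixed-order "cellular
## biofeature" vector every downstream classifier consumes.

#' Names and order of the per-cell feature vector
#'
#' The order is fixed; classifier models store a hash of it and refuse to
#' predict when it differs.
#' @export
FEATURE_NAMES <- c("nucleus_area", "equiv_diameter", "eccentricity",
                   "solidity", "h_mean", "h_var", "dab_ring_mean",
                   "dab_ring_p90", "dab_cyto_mean", "ring_completeness",
                   "local_density")

feature_hash <- function(names = FEATURE_NAMES)
  paste(names, collapse = "|")

#' Separate an RGB slide into hematoxylin / DAB / residual OD planes
#'
#' Converts to optical density (`OD = -log10((pixel+1)/256)`) and solves the
#' per-pixel linear decomposition onto the stain basis, clipping negative
#' hematoxylin/DAB loadings at zero. The residual plane keeps its sign: it
#' absorbs quantization error of the 8-bit encoding, which is what makes the
#' reconstruction round-trip tight.
#'
#' @param img a [slide_image()].
#' @param basis 3x3 stain matrix (rows hematoxylin/dab/residual), as
#'   [hdab_basis()].
#' @return object of class `stain_planes`: matrices `h`, `dab`, `res`
#'   (`[height, width]`), with the basis attached.
#' @export
separate_stains <- function(img, basis = hdab_basis()) {
  stopifnot(inherits(img, "slide_image"))
  if (abs(det(basis)) < 1e-6)
    stop("stain basis is singular; vectors must be linearly independent")
  d <- dim(img$pixels)
  od <- matrix(od_from_u8(as.numeric(img$pixels)), d[1] * d[2], 3)
  coef <- od %*% solve(basis)          # od_i = c_i %*% basis
  coef[, 1:2][coef[, 1:2] < 0] <- 0
  structure(list(h = matrix(coef[, 1], d[1], d[2]),
                 dab = matrix(coef[, 2], d[1], d[2]),
                 res = matrix(coef[, 3], d[1], d[2])),
            basis = basis, class = "stain_planes")
}

#' Reconstruct the OD image from stain planes
#'
#' Used by the round-trip property: at zero noise the reconstruction matches
#' the original OD image up to the non-negativity clipping.
#' @param planes a `stain_planes` object.
#' @return array `[height, width, 3]` of reconstructed OD.
#' @export
reconstruct_od <- function(planes) {
  basis <- attr(planes, "basis")
  d <- dim(planes$h)
  out <- array(0, c(d, 3))
  for (k in 1:3)
    out[, , k] <- planes$h * basis[1, k] + planes$dab * basis[2, k] +
      planes$res * basis[3, k]
  out
}

#' Nucleus detection parameters
#'
#' @param smooth_sigma Gaussian smoothing of the hematoxylin plane (px).
#' @param h_threshold OD threshold on the smoothed plane.
#' @param min_area,max_area area gate in px^2 after the watershed split.
#' @param watershed_tolerance minimum peak-separation depth (OD units).
#' @export
detect_params <- function(smooth_sigma = 1.5, h_threshold = 0.15,
                          min_area = 12, max_area = 600,
                          watershed_tolerance = 0.05) {
  if (min_area >= max_area) stop("degenerate params: min_area >= max_area")
  list(smooth_sigma = smooth_sigma, h_threshold = h_threshold,
       min_area = min_area, max_area = max_area,
       watershed_tolerance = watershed_tolerance)
}

#' Detect nuclei in the hematoxylin plane
#'
#' Smoothing, fixed OD threshold, hole filling, then a watershed on the
#' smoothed hematoxylin intensity (nuclei are intensity domes, so peaks
#' separate touching nuclei more reliably than the distance transform),
#' followed by an area gate. Fully deterministic.
#'
#' @param planes a `stain_planes` object.
#' @param params a [detect_params()].
#' @return integer label matrix `[height, width]`; 0 = background, labels
#'   are disjoint nucleus masks numbered 1..n.
#' @export
detect_nuclei <- function(planes, params = detect_params()) {
  stopifnot(inherits(planes, "stain_planes"))
  himg <- EBImage::Image(t(planes$h))    # EBImage wants [x, y]
  hs <- EBImage::gblur(himg, sigma = params$smooth_sigma)
  mask <- hs > params$h_threshold
  if (sum(mask) == 0) return(matrix(0L, nrow(planes$h), ncol(planes$h)))
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::watershed(hs * mask,
                               tolerance = params$watershed_tolerance,
                               ext = 1)
  lab <- t(EBImage::imageData(labels))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  storage.mode(lab) <- "integer"
  lab
}

#' Cell geometry parameters
#' @param ring_width membrane-ring width in pixels (dilation of the nucleus).
#' @param cyto_width additional cytoplasm-annulus width beyond the ring.
#' @param density_radius neighbourhood radius for the local-density feature.
#' @export
cell_params <- function(ring_width = 2, cyto_width = 3, density_radius = 40) {
  if (ring_width <= 0) stop("ring_width must be > 0")
  list(ring_width = ring_width, cyto_width = cyto_width,
       density_radius = density_radius)
}

## Label-constrained outward expansion of nuclei: Voronoi-style propagation
## inside a dilated mask so neighbouring rings never overlap.
expand_labels <- function(lab, width) {
  labi <- EBImage::Image(t(lab))
  brush <- EBImage::makeBrush(2 * ceiling(width) + 1, shape = "disc")
  dil <- EBImage::dilate(labi > 0, brush)
  ex <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labi), ncol(labi))),
                           seeds = labi, mask = dil)
  t(EBImage::imageData(ex))
}

#' Build the per-cell feature table
#'
#' Each nucleus is dilated by `ring_width` to form a membrane ring (clipped
#' at neighbours via a label-constrained partition) and by a further
#' `cyto_width` for a cytoplasm annulus; the fixed-order feature vector is
#' computed from the masks and OD planes. Rows are ordered by (y, x).
#'
#' @param planes a `stain_planes` object.
#' @param nuclei integer label matrix from [detect_nuclei()].
#' @param params a [cell_params()].
#' @param slide_id identifier copied into the table.
#' @return data frame with columns `cell_id`, `x`, `y`, the features of
#'   [FEATURE_NAMES], and placeholder `compartment`/`pdl1_bin`/`cell_class`
#'   columns; label matrices for nucleus/ring/cytoplasm are attached as
#'   attributes `nucleus_labels`, `ring_labels`, `cyto_labels`.
#' @export
build_cells <- function(planes, nuclei, params = cell_params(),
                        slide_id = "slide") {
  stopifnot(inherits(planes, "stain_planes"))
  n <- max(nuclei)
  empty <- data.frame(cell_id = integer(), x = numeric(), y = numeric())
  if (n == 0) {
    for (f in FEATURE_NAMES) empty[[f]] <- numeric()
    empty$compartment <- character(); empty$pdl1_bin <- integer()
    empty$cell_class <- character(); empty$slide_id <- character()
    return(empty)
  }
  ring_lab <- expand_labels(nuclei, params$ring_width)
  cyto_lab <- expand_labels(nuclei, params$ring_width + params$cyto_width)
  ring_only <- ring_lab; ring_only[nuclei > 0] <- 0L
  cyto_only <- cyto_lab; cyto_only[ring_lab > 0] <- 0L

  labi <- EBImage::Image(t(nuclei))
  sh <- EBImage::computeFeatures.shape(labi)
  mo <- EBImage::computeFeatures.moment(labi)

  idx_n <- split(which(nuclei > 0), nuclei[nuclei > 0])
  idx_r <- split(which(ring_only > 0), ring_only[ring_only > 0])
  idx_c <- split(which(cyto_only > 0), cyto_only[cyto_only > 0])
  h <- planes$h; dab <- planes$dab
  nr <- nrow(h)

  cx <- mo[, "m.cx"] - 1; cy <- mo[, "m.cy"] - 1  # 0-based pixel centres
  area <- sh[, "s.area"]

  feats <- matrix(NA_real_, n, length(FEATURE_NAMES),
                  dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    pn <- idx_n[[as.character(i)]]
    pr <- idx_r[[as.character(i)]]
    pc <- idx_c[[as.character(i)]]
    hv <- h[pn]
    ## solidity: nucleus area / convex-hull area of its pixel centres
    yy <- (pn - 1) %% nr; xx <- (pn - 1) %/% nr
    sol <- 1
    if (length(pn) >= 3) {
      ch <- grDevices::chull(xx, yy)
      hx <- xx[ch]; hy <- yy[ch]
      ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      ## add ~perimeter/2 + 1 to account for pixel extent of the hull
      ha <- ha + length(ch) * 0.5 + 1
      sol <- min(1, length(pn) / max(ha, 1))
    }
    rv <- if (length(pr) > 0) dab[pr] else 0
    cv <- if (length(pc) > 0) dab[pc] else 0
    ## ring completeness: fraction of 16 angular sectors containing ring px
    comp <- 0
    if (length(pr) > 0) {
      ry <- (pr - 1) %% nr; rx <- (pr - 1) %/% nr
      ang <- atan2(ry - cy[i], rx - cx[i])
      comp <- length(unique(floor((ang + pi) / (2 * pi) * 16))) / 16
    }
    feats[i, ] <- c(area[i], 2 * sqrt(area[i] / pi),
                    mo[i, "m.eccentricity"], sol,
                    mean(hv), if (length(hv) > 1) stats::var(hv) else 0,
                    mean(rv), as.numeric(stats::quantile(rv, 0.9, names = FALSE)),
                    mean(cv), comp, 0)
  }
  ## local density: neighbours within density_radius px
  d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
  feats[, "local_density"] <- rowSums(d2 <= params$density_radius^2) - 1

  ord <- order(round(cy, 3), round(cx, 3))
  cells <- data.frame(cell_id = seq_len(n), x = cx[ord], y = cy[ord])
  fo <- feats[ord, , drop = FALSE]
  for (f in FEATURE_NAMES) cells[[f]] <- fo[, f]
  cells$compartment <- NA_character_
  cells$pdl1_bin <- NA_integer_
  cells$cell_class <- NA_character_
  cells$slide_id <- slide_id
  ## remap label matrices to the (y, x) ordering so label == cell_id
  remap <- integer(n); remap[ord] <- seq_len(n)
  re <- function(m) { m[m > 0] <- remap[m[m > 0]]; storage.mode(m) <- "integer"; m }
  attr(cells, "nucleus_labels") <- re(nuclei)
  attr(cells, "ring_labels") <- re(ring_only)
  attr(cells, "cyto_labels") <- re(cyto_only)
  attr(cells, "feature_hash") <- feature_hash()
  cells
}

#' Measure diffuse DAB background outside cells
#'
#' Mean DAB OD over pixels not belonging to any cell (nucleus, ring or
#' cytoplasm annulus) and inside the inclusion regions. The slide background
#' is acceptable when this mean sits below the 1+ positivity cut point
#' (background must stay below 1+ staining intensity).
#'
#' @param planes a `stain_planes` object.
#' @param cells table from [build_cells()] (mask attributes are used).
#' @param annotations optional [annotation_set()]; default whole frame.
#' @param od_1plus the 1+ OD cut point.
#' @return list `(mean_dab_od, acceptable, n_pixels)`.
#' @export
measure_background <- function(planes, cells, annotations = NULL,
                               od_1plus = score_config()$od_cuts[1]) {
  dab <- planes$dab
  mask <- attr(cells, "cyto_labels")
  incell <- attr(cells, "nucleus_labels") > 0 |
    attr(cells, "ring_labels") > 0 | mask > 0
  sel <- !incell
  if (!is.null(annotations)) {
    nr <- nrow(dab); nc <- ncol(dab)
    xx <- rep(0:(nc - 1), each = nr); yy <- rep(0:(nr - 1), nc)
    inc <- rep(FALSE, length(xx))
    has_inc <- FALSE
    for (p in annotations$polygons) {
      if (p$role == "include") {
        has_inc <- TRUE
        inc <- inc | points_in_polygon(xx, yy, p$coords)
      }
    }
    for (p in annotations$polygons)
      if (p$role == "exclude") inc <- inc & !points_in_polygon(xx, yy, p$coords)
    if (!has_inc) stop("annotations contain no inclusion region")
    sel <- sel & matrix(inc, nr, nc)
  }
  if (sum(sel) == 0) stop("no background pixels inside the inclusion region")
  m <- mean(dab[sel])
  list(mean_dab_od = m, acceptable = m < od_1plus, n_pixels = sum(sel))
}
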