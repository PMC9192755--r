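## Readers/writers for every artifact format (PNG/TIFF rasters, 2-page TIFF
## IF pairs, GeoJSON annotations, CSV cell and score tables) plus the image
## quality check that gates analysis.

ANNOTATION_ROLES <- c("include", "exclude", "train_tumor", "train_stroma")

#' Brightfield slide image container
#'
#' @param pixels integer array `[height, width, 3]`, 8-bit RGB (0-255).
#' @param microns_per_pixel physical pixel size (> 0).
#' @param slide_id identifier string.
#' @export
slide_image <- function(pixels, microns_per_pixel = 0.5, slide_id = "slide") {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("slide image must have 3 channels (RGB)")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be > 0")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 slide_id = slide_id),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slide_image '%s': %d x %d px, %.3f um/px\n",
              x$slide_id, d[2], d[1], x$microns_per_pixel))
  invisible(x)
}

#' Write a slide image to PNG or TIFF
#' @param img a [slide_image()].
#' @param path output path; format chosen by extension (.png/.tif/.tiff).
#' @export
write_slide_image <- function(img, path) {
  stopifnot(inherits(img, "slide_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path,
                                                      bits.per.sample = 8L)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a slide image from PNG or TIFF
#' @param path input file.
#' @param microns_per_pixel pixel size to attach (rasters carry none).
#' @param slide_id identifier; defaults to the file stem.
#' @export
read_slide_image <- function(path, microns_per_pixel = 0.5,
                             slide_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    stop("expected an RGB image, got ", paste(dim(arr), collapse = "x"),
         " (grayscale and indexed inputs are not supported)")
  px <- array(as.integer(round(arr[, , 1:3] * 255)), c(dim(arr)[1:2], 3))
  slide_image(px, microns_per_pixel, slide_id)
}

#' Write / read a two-channel IF image as a 2-page TIFF
#' @param ifimg an `if_image` from [generate_if_pair()].
#' @param path .tif/.tiff path.
#' @export
write_if_image <- function(ifimg, path) {
  stopifnot(inherits(ifimg, "if_image"))
  tiff::writeTIFF(ifimg$channels, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_if_image
#' @param panel panel name to attach on read.
#' @export
read_if_image <- function(path, panel = "CD68_CD163") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) stop("expected a 2-page TIFF, got ", length(pages))
  markers <- IF_PANELS[[panel]]
  if (is.null(markers)) stop("unknown panel: ", panel)
  channels <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  names(channels) <- markers
  structure(list(channels = channels, panel = panel, markers = markers,
                 width = ncol(channels[[1]]), height = nrow(channels[[1]]),
                 transform = NULL),
            class = "if_image")
}

#' Annotation set: role-tagged polygons for one slide
#'
#' @param slide_id slide identifier.
#' @param polygons list of `list(role, coords)` where `coords` is an n x 2
#'   matrix of (x, y) vertices (open ring, >= 3 vertices) and `role` is one
#'   of include, exclude, train_tumor, train_stroma.
#' @export
annotation_set <- function(slide_id, polygons) {
  for (p in polygons) {
    if (is.null(p$role) || !p$role %in% ANNOTATION_ROLES)
      stop("unknown annotation role '", p$role, "'; must be one of: ",
           paste(ANNOTATION_ROLES, collapse = ", "))
    if (is.null(dim(p$coords)) || nrow(p$coords) < 3)
      stop("annotation polygon must have at least 3 vertices")
  }
  structure(list(slide_id = slide_id, polygons = polygons),
            class = "annotation_set")
}

#' Write / read annotations as GeoJSON
#' @param set an [annotation_set()].
#' @param path .geojson/.json output path.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  feats <- lapply(set$polygons, function(p) {
    ring <- rbind(unname(as.matrix(p$coords)), unname(p$coords[1, , drop = FALSE]))
    list(type = "Feature",
         properties = list(role = p$role, slide_id = set$slide_id),
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.numeric,
                                                  simplify = FALSE))))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  sid <- NULL
  polys <- lapply(obj$features, function(f) {
    role <- f$properties$role
    if (is.null(role) || !role %in% ANNOTATION_ROLES)
      stop("unknown annotation role '", role, "'; vocabulary: ",
           paste(ANNOTATION_ROLES, collapse = ", "))
    sid <<- f$properties$slide_id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    if (nrow(ring) < 3) stop("annotation polygon must have at least 3 vertices")
    colnames(ring) <- c("x", "y")
    list(role = role, coords = ring)
  })
  annotation_set(if (is.null(sid)) "unknown" else sid, polys)
}

CELL_TABLE_COLUMNS <- c("cell_id", "x", "y", "slide_id")

#' Write / read a cell table as CSV
#'
#' The cell table is the data-frame output of [build_cells()] (plus any
#' columns added downstream: `compartment`, `pdl1_bin`, `cell_class`,
#' `subtype`). Round-trips losslessly apart from mask references, which are
#' in-memory attributes only.
#'
#' @param cells cell data frame.
#' @param path CSV path.
#' @export
write_cell_table <- function(cells, path) {
  miss <- setdiff(c("cell_id", "x", "y"), names(cells))
  if (length(miss) > 0)
    stop("cell table missing required columns: ", paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "x", "y"), names(df))
  if (length(miss) > 0)
    stop("cell table missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("cell ids must be unique per slide")
  df
}

#' Quality-check thresholds
#'
#' Defaults are calibrated on clean vs degraded synthetic slides: the focus
#' metric (variance of the Laplacian of the grayscale image, on the 0-1
#' scale) drops by orders of magnitude under a sigma = 8 px blur, and the
#' blank-tile fraction flags large constant (white/black) areas that the
#' stain model never produces.
#'
#' @param focus_min minimum variance-of-Laplacian.
#' @param blank_tile_max maximum fraction of near-constant 32x32 tiles.
#' @param saturation_max maximum fraction of fully saturated pixels.
#' @export
qc_config <- function(focus_min = 1e-4, blank_tile_max = 0.30,
                      saturation_max = 0.25) {
  list(focus_min = focus_min, blank_tile_max = blank_tile_max,
       saturation_max = saturation_max)
}

#' Image quality check
#'
#' Fails a slide for poor focus (low variance of Laplacian), excessive
#' near-constant area (scanning/glass artifacts, blank regions) or excessive
#' saturation. Always returns a report; never errors.
#'
#' @param img a [slide_image()].
#' @param thresholds a [qc_config()].
#' @return list with `pass`, `reasons` (character), `metrics`.
#' @export
quality_check_image <- function(img, thresholds = qc_config()) {
  stopifnot(inherits(img, "slide_image"))
  g <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / (3 * 255)
  h <- nrow(g); w <- ncol(g)
  ## Laplacian via shifted differences (interior pixels)
  ic <- 2:(h - 1); jc <- 2:(w - 1)
  lap <- 4 * g[ic, jc] - g[ic - 1, jc] - g[ic + 1, jc] -
    g[ic, jc - 1] - g[ic, jc + 1]
  focus <- stats::var(as.numeric(lap))

  ts <- 32L
  ti <- floor(h / ts); tj <- floor(w / ts)
  blank <- 0L; ntile <- ti * tj
  for (a in seq_len(ti)) for (b in seq_len(tj)) {
    tile <- g[((a - 1) * ts + 1):(a * ts), ((b - 1) * ts + 1):(b * ts)]
    if (stats::sd(tile) < 1 / 255) blank <- blank + 1L
  }
  blank_frac <- if (ntile > 0) blank / ntile else 0

  sat <- mean((img$pixels[, , 1] == 255L & img$pixels[, , 2] == 255L &
                 img$pixels[, , 3] == 255L) |
                (img$pixels[, , 1] == 0L & img$pixels[, , 2] == 0L &
                   img$pixels[, , 3] == 0L))

  reasons <- character()
  if (focus < thresholds$focus_min) reasons <- c(reasons, "focus")
  if (blank_frac > thresholds$blank_tile_max || sat > thresholds$saturation_max)
    reasons <- c(reasons, "blank/artifact area")
  list(pass = length(reasons) == 0, reasons = reasons,
       metrics = list(focus = focus, blank_tile_fraction = blank_frac,
                      saturation_fraction = sat))
}

#' Write / read a reader-score table as CSV
#' @param scores data frame `(sample, reader, read, score)`.
#' @param path CSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) utils::read.csv(path)
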